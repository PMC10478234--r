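test_that("tree sampling is deterministic with the expected topology", {
  sp <- phantom_spec(seed = 3, n_trees = 2, max_bifurcations = 0)
  tr <- sample_tree(sp)
  expect_length(tr, 2L)   # one segment per tree

  sp2 <- phantom_spec(seed = 9, max_bifurcations = 2)
  t1 <- sample_tree(sp2); t2 <- sample_tree(sp2)
  expect_identical(t1, t2)

  # radius decays geometrically with generation
  sp3 <- phantom_spec(seed = 4, n_trees = 1, max_bifurcations = 3,
                      root_radius = 2, radius_decay = 0.7,
                      shape = c(64, 64, 64))
  tr3 <- sample_tree(sp3)
  gens <- vapply(tr3, function(s) s$gen, integer(1))
  radii <- vapply(tr3, function(s) s$radius[1], numeric(1))
  expect_true(any(gens == 3L))
  expect_equal(unique(radii[gens == 3L]), 2 * 0.7^3, tolerance = 1e-12)
  expect_equal(unique(radii[gens == 0L]), 2)
})

test_that("rasterization matches a brute-force distance oracle on a straight tube", {
  # single segment along the depth axis, constant radius 1.4
  pts <- cbind(4:11, 8, 8)
  tree <- list(list(points = pts, radius = rep(1.4, 8),
                    arc = 0:7, tree = 1L, gen = 0L))
  attr(tree, "max_arc") <- 7
  m <- rasterize_mask(tree, c(16, 16, 16))
  # oracle: distance from each voxel centre to the segment
  seg_dist <- function(v) {
    a <- c(4, 8, 8); b <- c(11, 8, 8)
    ab <- b - a
    t0 <- min(1, max(0, sum((v - a) * ab) / sum(ab^2)))
    sqrt(sum((v - (a + t0 * ab))^2))
  }
  oracle <- array(0L, c(16, 16, 16))
  for (i in 0:15) for (j in 0:15) for (k in 0:15)
    if (seg_dist(c(i, j, k)) <= 1.4) oracle[i + 1, j + 1, k + 1] <- 1L
  expect_identical(m$voxels, oracle)
  # every centreline voxel plus its in-plane 4-neighbours is foreground
  for (z in 4:11) {
    expect_equal(m$voxels[z + 1, 9, 9], 1L)
    expect_equal(m$voxels[z + 1, 10, 9] + m$voxels[z + 1, 8, 9] +
                 m$voxels[z + 1, 9, 10] + m$voxels[z + 1, 9, 8], 4L)
    expect_equal(m$voxels[z + 1, 10, 10], 0L)  # diagonal sqrt(2) > 1.4
  }
})

test_that("empty trees rasterize to empty masks", {
  m <- rasterize_mask(list(), c(8, 8, 8))
  expect_true(all(m$voxels == 0L))
})

test_that("default phantoms have a small tubular foreground", {
  m <- rasterize_mask(sample_tree(phantom_spec(seed = 1)), c(32, 64, 64))
  frac <- mean(m$voxels)
  expect_gt(frac, 0)
  expect_lt(frac, 0.05)
})

test_that("rendering applies contrast, distractor and seeded noise correctly", {
  sp <- phantom_spec(seed = 11, noise_sd = 0, distal_contrast_drop = 0,
                     distractor = FALSE)
  tr <- sample_tree(sp)
  mk <- rasterize_mask(tr, sp$shape)
  vol <- render_volume(sp, tr, mk)
  fg <- mk$voxels == 1L
  expect_true(all(vol$voxels[fg] == sp$vessel_hu))
  expect_true(all(vol$voxels[!fg] == sp$background_hu))

  # linear distal attenuation reaches vessel_hu * (1 - drop) at the tips
  sp2 <- phantom_spec(seed = 11, noise_sd = 0, distal_contrast_drop = 0.4,
                      distractor = FALSE)
  vol2 <- render_volume(sp2, tr, mk)
  iv <- vol2$voxels[fg]
  expect_true(all(iv <= sp2$vessel_hu & iv >= 0.6 * sp2$vessel_hu - 1e-9))
  expect_lt(min(iv), 0.65 * sp2$vessel_hu)  # attenuation actually happens

  # distractor: bright voxel outside the labeled mask, never overlapping it
  sp3 <- phantom_spec(seed = 11, noise_sd = 0, distractor = TRUE)
  tr3 <- sample_tree(sp3)
  mk3 <- rasterize_mask(tr3, sp3$shape)
  vol3 <- render_volume(sp3, tr3, mk3)
  distr <- vol3$voxels >= 250 & mk3$voxels == 0L
  expect_true(any(distr))

  # mask is a subset of the bright set without noise
  expect_true(all(vol3$voxels[mk3$voxels == 1L] > sp3$background_hu))

  # toggling noise does not change the geometry
  spn <- phantom_spec(seed = 11, noise_sd = 25)
  expect_identical(generate_case(spn)$mask$voxels,
                   generate_case(phantom_spec(seed = 11, noise_sd = 0))$mask$voxels)
})

test_that("case generation is a pure function of the spec", {
  c1 <- generate_case(phantom_spec(seed = 1, shape = c(16, 24, 24)))
  c1b <- generate_case(phantom_spec(seed = 1, shape = c(16, 24, 24)))
  c2 <- generate_case(phantom_spec(seed = 2, shape = c(16, 24, 24)))
  expect_identical(c1$volume$voxels, c1b$volume$voxels)
  expect_identical(c1$mask$voxels, c1b$mask$voxels)
  expect_false(identical(c1$mask$voxels, c2$mask$voxels))
})
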