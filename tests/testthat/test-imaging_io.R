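test_that("NIfTI round trip preserves voxels, spacing and mask values", {
  tmp <- tempfile(fileext = ".nii.gz")
  arr <- array(rnorm(8^3, 100, 300), c(8, 8, 8))
  vol <- ct_volume(arr, spacing = c(0.45, 0.4, 0.4))
  write_volume(vol, tmp)
  back <- read_volume(tmp)
  expect_equal(back$voxels, arr, ignore_attr = TRUE)
  expect_equal(back$spacing, c(0.45, 0.4, 0.4), tolerance = 1e-6)

  m <- label_mask(rand_mask(c(8, 8, 8)), spacing = c(0.45, 0.4, 0.4))
  tmp2 <- tempfile(fileext = ".nii.gz")
  write_volume(m, tmp2)
  back2 <- read_mask(tmp2)
  expect_identical(back2$voxels, m$voxels)
  unlink(c(tmp, tmp2))
})

test_that("read_volume raises typed errors on bad inputs", {
  expect_error(read_volume(tempfile()), class = "corovox_error_missing_file")
  tmp4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), tmp4)
  expect_error(read_volume(tmp4), class = "corovox_error_not_3d")
  unlink(tmp4)
  bad <- tempfile(fileext = ".nii")
  writeLines("not a nifti header", bad)
  expect_error(read_volume(bad), class = "corovox_error_bad_header")
  unlink(bad)
  expect_error(write_volume(ct_volume(array(0, c(2, 2, 2))),
                            file.path(tempfile(), "x.nii")),
               class = "corovox_error_unwritable")
})

test_that("phantom cases survive the NIfTI round trip", {
  cs <- generate_case(phantom_spec(seed = 42, shape = c(16, 16, 16)))
  d <- tempfile(); dir.create(d)
  write_volume(cs$volume, file.path(d, "v.nii.gz"))
  write_volume(cs$mask, file.path(d, "m.nii.gz"))
  expect_equal(read_volume(file.path(d, "v.nii.gz"))$voxels, cs$volume$voxels,
               ignore_attr = TRUE)
  expect_identical(read_mask(file.path(d, "m.nii.gz"))$voxels, cs$mask$voxels)
  unlink(d, recursive = TRUE)
})

test_that("HU windowing clamps and rescales linearly", {
  arr <- array(c(-500, 1000, 250, -260, 760, 0), c(6, 1, 1))
  nv <- window_and_normalize(ct_volume(arr))
  expect_equal(nv$voxels[1, 1, 1], 0)
  expect_equal(nv$voxels[2, 1, 1], 1)
  expect_equal(nv$voxels[3, 1, 1], 0.5)
  expect_equal(nv$voxels[4, 1, 1], 0)
  expect_equal(nv$voxels[5, 1, 1], 1)
  expect_equal(nv$voxels[6, 1, 1], 260 / 1020)
  expect_error(window_and_normalize(ct_volume(arr), 100, 100),
               class = "corovox_error_window")
  # monotone in input HU
  set.seed(1)
  v <- sort(rnorm(100, 200, 500))
  out <- window_and_normalize(ct_volume(array(v, c(100, 1, 1))))$voxels
  expect_true(all(diff(as.vector(out)) >= 0))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("block planning clamps the final start and covers every slice", {
  expect_identical(plan_blocks(40)$starts, c(0L, 8L, 16L, 24L))
  expect_identical(plan_blocks(16)$starts, 0L)
  expect_identical(plan_blocks(20)$starts, c(0L, 4L))
  expect_error(plan_blocks(10, stride = 0), class = "corovox_error_bad_plan")
  expect_error(plan_blocks(10, block_depth = 8, stride = 9),
               class = "corovox_error_bad_plan")
  for (depth in 1:64) {
    pl <- plan_blocks(depth, 16, 8)
    covered <- logical(pl$padded_depth)
    for (s in pl$starts) covered[(s + 1):(s + pl$block_depth)] <- TRUE
    expect_true(all(covered[seq_len(depth)]))
    expect_true(all(diff(pl$starts) > 0) || length(pl$starts) == 1)
  }
})

test_that("stitching averages overlaps and strips padding", {
  # non-overlapping plan concatenates
  pl <- plan_blocks(32, 16, 16)
  b1 <- array(0.2, c(2, 16, 4, 4)); b2 <- array(0.6, c(2, 16, 4, 4))
  out <- stitch_blocks(pl, list(b1, b2))
  expect_equal(dim(out), c(2, 32, 4, 4))
  expect_equal(out[1, 1, 1, 1], 0.2)
  expect_equal(out[1, 20, 1, 1], 0.6)

  # two blocks overlapping on 8 slices average to 0.4 there
  pl2 <- plan_blocks(24, 16, 8)
  out2 <- stitch_blocks(pl2, list(b1, b2))
  expect_equal(out2[1, 12, 2, 2], 0.4)

  # against an accumulate-and-divide oracle on random seeded blocks
  set.seed(7)
  pl3 <- plan_blocks(21, 8, 3)
  blocks <- lapply(pl3$starts, function(s) array(runif(2 * 8 * 3 * 3), c(2, 8, 3, 3)))
  got <- stitch_blocks(pl3, blocks)
  acc <- array(0, c(2, pl3$padded_depth, 3, 3)); cnt <- numeric(pl3$padded_depth)
  for (i in seq_along(blocks)) {
    sl <- (pl3$starts[i] + 1):(pl3$starts[i] + 8)
    acc[, sl, , ] <- acc[, sl, , ] + blocks[[i]]
    cnt[sl] <- cnt[sl] + 1
  }
  for (s in seq_len(pl3$padded_depth)) acc[, s, , ] <- acc[, s, , ] / cnt[s]
  expect_equal(got, acc[, 1:21, , , drop = FALSE], tolerance = 1e-12)
  expect_error(stitch_blocks(pl3, blocks[-1]), class = "corovox_error_bad_blocks")

  # constant probability field stays constant
  plc <- plan_blocks(19, 16, 8)
  cblocks <- lapply(plc$starts, function(s) array(0.3, c(2, 16, 2, 2)))
  expect_true(all(abs(stitch_blocks(plc, cblocks) - 0.3) < 1e-15))
})
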