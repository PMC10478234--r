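test_that("confusion counts match direct enumeration", {
  g <- array(0L, c(3, 3, 3)); g[1:5] <- 1L
  expect_equal(unclass(confusion(g, g))[c("tp", "fp", "fn")],
               list(tp = 5L, fp = 0L, fn = 0L), ignore_attr = TRUE)

  # gt = {a, b}, pred = {b, c}
  gt <- array(0L, c(2, 2, 2)); gt[1] <- 1L; gt[2] <- 1L
  pr <- array(0L, c(2, 2, 2)); pr[2] <- 1L; pr[3] <- 1L
  cc <- confusion(pr, gt)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(1, 1, 1))

  set.seed(1)
  a <- rand_mask(c(8, 8, 8)); b <- rand_mask(c(8, 8, 8))
  o <- oracle_confusion(a, b)
  cc2 <- confusion(a, b)
  expect_equal(c(cc2$tp, cc2$fp, cc2$fn), c(o$tp, o$fp, o$fn))
  expect_error(confusion(a, rand_mask(c(4, 4, 4))),
               class = "corovox_error_shape_mismatch")
})

test_that("overlap ratios follow their defining formulas", {
  cc <- structure(list(tp = 1, fp = 1, fn = 1), class = "confusion_counts")
  expect_equal(dsc(cc), 0.5)
  expect_equal(recall(cc), 0.5)
  expect_equal(precision(cc), 0.5)

  cc2 <- structure(list(tp = 3, fp = 1, fn = 2), class = "confusion_counts")
  expect_equal(dsc(cc2), 6 / 9)
  expect_equal(recall(cc2), 0.6)
  expect_equal(precision(cc2), 0.75)

  empty <- structure(list(tp = 0, fp = 0, fn = 0), class = "confusion_counts")
  expect_error(dsc(empty), class = "corovox_error_undefined_metric")
  expect_error(recall(empty), class = "corovox_error_undefined_metric")
  expect_error(precision(empty), class = "corovox_error_undefined_metric")

  # DSC is the harmonic mean of recall and precision
  set.seed(2)
  for (i in 1:100) {
    cc3 <- structure(list(tp = sample(1:50, 1), fp = sample(0:50, 1),
                          fn = sample(0:50, 1)), class = "confusion_counts")
    hm <- 2 / (1 / recall(cc3) + 1 / precision(cc3))
    expect_equal(dsc(cc3), hm, tolerance = 1e-12)
  }
})

test_that("surface extraction finds exactly the 6-connectivity boundary", {
  cube <- array(0L, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- 1L
  s <- extract_surface(cube)
  expect_equal(nrow(s), 26)            # all but the centre voxel
  expect_false(any(s[, 1] == 2 & s[, 2] == 2 & s[, 3] == 2))

  single <- array(0L, c(3, 3, 3)); single[2, 2, 2] <- 1L
  s1 <- extract_surface(single)
  expect_equal(unclass(s1)[1, ], c(slice = 1, row = 1, col = 1), ignore_attr = TRUE)
  expect_equal(nrow(s1), 1)

  line <- array(0L, c(6, 3, 3)); line[, 2, 2] <- 1L
  expect_equal(nrow(extract_surface(line)), 6)  # thin line: all surface

  expect_equal(nrow(extract_surface(array(0L, c(3, 3, 3)))), 0)
})

test_that("surface distances match hand-worked values", {
  s_of <- function(coords) {
    m <- matrix(as.integer(coords), ncol = 3, byrow = TRUE)
    colnames(m) <- c("slice", "row", "col")
    structure(m, class = c("surface_set", class(m)))
  }
  a <- s_of(c(0, 0, 0))
  b <- s_of(c(3, 0, 0))
  expect_equal(assd(a, b), 3)
  expect_equal(hausdorff(a, b), 3)

  c2 <- s_of(c(0, 0, 0, 0, 0, 4))
  expect_equal(assd(a, c2), 4 / 3)   # (0 + (0 + 4)) / (1 + 2)
  expect_equal(hausdorff(a, c2), 4)

  expect_equal(assd(c2, c2), 0)
  expect_equal(hausdorff(c2, c2), 0)
  expect_error(assd(a, extract_surface(array(0L, c(2, 2, 2)))),
               class = "corovox_error_undefined_metric")

  # spacing scales per axis before distances
  expect_equal(assd(a, b, spacing = c(2, 1, 1)), 6)
})

test_that("distances agree with the all-pairs oracle and are symmetric", {
  set.seed(3)
  for (i in 1:10) {
    a <- extract_surface(rand_mask(c(12, 12, 12), 0.25))
    b <- extract_surface(rand_mask(c(12, 12, 12), 0.25))
    o <- oracle_surface_dists(corovox:::surface_coords(a),
                              corovox:::surface_coords(b))
    expect_equal(assd(a, b), o$assd, tolerance = 1e-9)
    expect_equal(hausdorff(a, b), o$hd, tolerance = 1e-9)
    expect_equal(assd(a, b), assd(b, a))
    expect_equal(hausdorff(a, b), hausdorff(b, a))
    expect_lte(assd(a, b), hausdorff(a, b))
  }
})

test_that("all five metrics are translation invariant", {
  set.seed(4)
  base_p <- array(0L, c(10, 10, 10)); base_p[2:4, 2:5, 3:4] <- 1L
  base_g <- array(0L, c(10, 10, 10)); base_g[3:5, 2:4, 3:5] <- 1L
  r0 <- evaluate_case(base_p, base_g)
  sh_p <- array(0L, c(10, 10, 10)); sh_p[2:4 + 3, 2:5 + 2, 3:4 + 1] <- 1L
  sh_g <- array(0L, c(10, 10, 10)); sh_g[3:5 + 3, 2:4 + 2, 3:5 + 1] <- 1L
  r1 <- evaluate_case(sh_p, sh_g)
  for (f in c("dsc", "recall", "precision", "assd", "hd"))
    expect_equal(r0[[f]], r1[[f]])
})

test_that("whole-case evaluation aggregates and degrades gracefully", {
  g <- array(0L, c(6, 6, 6)); g[2:4, 2:4, 2:4] <- 1L
  r <- evaluate_case(g, g)
  expect_equal(unlist(r[c("dsc", "recall", "precision", "assd", "hd")]),
               c(dsc = 1, recall = 1, precision = 1, assd = 0, hd = 0))

  p <- array(0L, c(6, 6, 6)); p[6, 6, 6] <- 1L
  r2 <- evaluate_case(p, g)
  expect_equal(r2$dsc, 0)

  empty <- array(0L, c(6, 6, 6))
  r3 <- evaluate_case(empty, g)
  expect_true(is.na(r3$precision))
  expect_true(is.na(r3$assd))
  expect_true(is.na(r3$hd))
  expect_equal(r3$dsc, 0)
})
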