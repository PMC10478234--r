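test_that("soft Dice loss matches its closed form", {
  g <- array(0, c(4, 4, 4)); g[2:3, 2:3, 2:3] <- 1
  expect_lte(dice_loss(g, g), 1e-5)

  p2 <- array(0, c(4, 4, 4)); p2[1, 1, 1] <- 1
  expect_gte(dice_loss(p2, g), 1 - 1e-4)

  # pred uniform 0.5 over gt's support only, |gt| = 8
  p3 <- 0.5 * g
  s <- 1e-5
  expect_equal(dice_loss(p3, g), 1 - (8 + s) / (1.5 * 8 + s), tolerance = 1e-12)

  expect_error(dice_loss(array(0, c(2, 2, 2)), g),
               class = "corovox_error_shape_mismatch")

  # symmetric for binary arguments; complement of the overlap DSC
  set.seed(1)
  for (i in 1:20) {
    a <- rand_mask(c(5, 5, 5)); b <- rand_mask(c(5, 5, 5))
    expect_equal(dice_loss(a, b), dice_loss(b, a))
    expect_equal(1 - dice_loss(a, b), dsc(confusion(a, b)), tolerance = 1e-4)
  }
})

test_that("the composite deep-supervision loss weights the auxiliaries", {
  expect_equal(deep_supervision_loss(c(0.4, 0.1, 0.1, 0.1), 0.8), 0.64)
  expect_equal(deep_supervision_loss(c(0.4, 0.1, 0.1, 0.1), 1), 0.7)
  expect_equal(deep_supervision_loss(c(0.3, 0, 0, 0), 0.5), 0.3)
  expect_equal(deep_supervision_loss(0.7, 0.8), 0.7)
  expect_error(deep_supervision_loss(c(-0.1, 0, 0, 0), 0.8),
               class = "corovox_error_bad_loss")
  expect_error(deep_supervision_loss(c(0.1, 0, 0, 0), 0),
               class = "corovox_error_bad_loss")
})

test_that("the default schedules reproduce the published recipe exactly", {
  sc <- schedule_config()
  expect_identical(sc$epochs, 180L)
  expect_equal(alpha_at_epoch(10, sc), 1)
  expect_equal(alpha_at_epoch(50, sc), 0.8)
  expect_equal(alpha_at_epoch(100, sc), 0.8^2)
  expect_equal(alpha_at_epoch(170, sc), 0.8^4)
  expect_equal(lr_at_epoch(50, sc), 1e-5)
  expect_equal(lr_at_epoch(120, sc), 1e-6)
  expect_equal(lr_at_epoch(170, sc), 1e-7)
  # boundary epochs switch on the left-closed side
  expect_equal(alpha_at_epoch(40, sc), 0.8)
  expect_equal(alpha_at_epoch(39, sc), 1)
  expect_equal(lr_at_epoch(100, sc), 1e-6)
  expect_equal(lr_at_epoch(160, sc), 1e-7)
  expect_error(alpha_at_epoch(181, sc), class = "corovox_error_epoch_range")
  expect_error(lr_at_epoch(-1, sc), class = "corovox_error_epoch_range")
})

test_that("both schedules are non-increasing over the whole run", {
  sc <- schedule_config()
  al <- vapply(0:180, alpha_at_epoch, numeric(1), sched = sc)
  lr <- vapply(0:180, lr_at_epoch, numeric(1), sched = sc)
  expect_true(all(diff(al) <= 0))
  expect_true(all(diff(lr) <= 0))
  # scaled-down schedules keep the structure
  sc20 <- schedule_config(epochs = 20, lr_scale = 100)
  al20 <- vapply(0:20, alpha_at_epoch, numeric(1), sched = sc20)
  expect_true(all(diff(al20) <= 0))
  expect_equal(lr_at_epoch(1, sc20), 1e-3)
})
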