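test_that("variant presets map onto the ablation rows", {
  v <- make_variant("unet")
  expect_equal(c(v$block, v$skip), c("plain", "identity"))
  v <- make_variant("sa")
  expect_equal(c(v$block, v$skip), c("plain", "self_attention"))
  v <- make_variant("lct")
  expect_equal(c(v$block, v$skip), c("plain", "lct"))
  v <- make_variant("r")
  expect_equal(c(v$block, v$skip), c("residual", "identity"))
  v <- make_variant("dr")
  expect_equal(c(v$block, v$skip), c("dense_residual", "identity"))
  v <- make_variant("dr_lct")
  expect_equal(c(v$block, v$skip), c("dense_residual", "lct"))
  expect_error(make_variant("vnet"), class = "corovox_error_unknown_variant")
})

test_that("building is deterministic and validates its configuration", {
  cfg <- make_variant("dr_lct", base_channels = 8)
  n1 <- build_network(cfg, seed = 5)
  n2 <- build_network(cfg, seed = 5)
  expect_identical(n1$params, n2$params)
  expect_error(network_config(base_channels = 6, skip = "lct", lct_groups = 4),
               class = "corovox_error_bad_config")
  expect_error(network_config(levels = 1), class = "corovox_error_bad_config")
})

test_that("forward output obeys the probability and shape contracts", {
  cfg <- make_variant("dr_lct", base_channels = 4)
  net <- build_network(cfg, seed = 1)
  set.seed(2)
  x <- array(runif(16 * 16 * 16), c(1, 16, 16, 16))
  out <- network_forward(net, x)
  expect_equal(dim(out$main), c(2, 16, 16, 16))
  expect_length(out$aux, 3)
  for (a in out$aux) {
    expect_equal(dim(a), c(2, 16, 16, 16))
    expect_true(max(abs(apply(a, 2:4, sum) - 1)) < 1e-6)
    expect_true(all(a >= -1e-12))
  }
  expect_true(max(abs(apply(out$main, 2:4, sum) - 1)) < 1e-6)
  expect_error(network_forward(net, array(0, c(1, 16, 12, 12))),
               class = "corovox_error_bad_input")

  # deep supervision off drops the auxiliary outputs
  net2 <- build_network(make_variant("dr_lct", base_channels = 4,
                                     deep_supervision = FALSE), seed = 1)
  expect_null(network_forward(net2, x)$aux)
})

test_that("the plain-skip network matches an independently coded U-Net", {
  # 3-level plain U-Net, no normalisation, reproduced step by step with the
  # gather-oracle convolution and hand-coded pooling/upsampling.
  cfg <- network_config(levels = 3, base_channels = 2, block = "plain",
                        skip = "identity", deep_supervision = FALSE,
                        norm = FALSE)
  net <- build_network(cfg, seed = 9)
  set.seed(10)
  x <- array(runif(1 * 8 * 8 * 8), c(1, 8, 8, 8))

  P <- net$params
  o_unit <- function(u, xx) oracle_relu(oracle_conv3d(xx, u$w, u$b))
  o_block <- function(bp, xx) o_unit(bp$u2, o_unit(bp$u1, xx))
  o_pool <- function(xx) {
    d <- dim(xx)
    y <- array(0, c(d[1], d[2] / 2, d[3] / 2, d[4] / 2))
    for (c in seq_len(d[1])) for (i in seq_len(d[2] / 2))
      for (j in seq_len(d[3] / 2)) for (k in seq_len(d[4] / 2))
        y[c, i, j, k] <- max(xx[c, (2 * i - 1):(2 * i), (2 * j - 1):(2 * j),
                                (2 * k - 1):(2 * k)])
    y
  }
  o_up <- function(up, xx) {
    d <- dim(xx); cout <- dim(up$w)[2]
    y <- array(0, c(cout, 2 * d[2], 2 * d[3], 2 * d[4]))
    for (oc in seq_len(cout)) for (i in seq_len(d[2])) for (j in seq_len(d[3]))
      for (k in seq_len(d[4])) for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
        y[oc, 2 * i - 1 + dz, 2 * j - 1 + dy, 2 * k - 1 + dx] <-
          sum(up$w[, oc, dz + 1, dy + 1, dx + 1] * xx[, i, j, k]) + up$b[oc]
    y
  }
  o_cat <- function(a, b) {
    y <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2:4]))
    y[seq_len(dim(a)[1]), , , ] <- a
    y[dim(a)[1] + seq_len(dim(b)[1]), , , ] <- b
    y
  }
  e1 <- o_block(P$enc[[1]], x)
  e2 <- o_block(P$enc[[2]], o_pool(e1))
  e3 <- o_block(P$enc[[3]], o_pool(e2))
  d2 <- o_block(P$dec[[2]], o_cat(e2, o_up(P$up[[2]], e3)))
  d1 <- o_block(P$dec[[1]], o_cat(e1, o_up(P$up[[1]], d2)))
  z <- oracle_conv3d(d1, P$head_main$w, P$head_main$b)
  want <- oracle_softmax_c(z)

  got <- network_forward(net, x)$main
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("parameter counts order the module variants consistently", {
  for (base in c(8, 16)) {
    cnt <- vapply(c("unet", "sa", "lct", "r", "dr", "dr_lct"), function(v)
      count_params(build_network(make_variant(v, base_channels = base), seed = 1)),
      numeric(1))
    expect_lt(cnt[["unet"]], cnt[["sa"]])
    expect_lt(cnt[["sa"]], cnt[["lct"]])
    expect_lt(cnt[["r"]], cnt[["dr"]])
    expect_lt(cnt[["dr"]], cnt[["dr_lct"]])
    # the cost of adding LCT skips decomposes exactly: it is the same for
    # both block families except that the dense-residual decoder projections
    # must widen with the three-part concatenation (one extra pointwise
    # width^2 per decoder stage)
    widths <- base * 2^(0:2)
    expect_equal((cnt[["dr_lct"]] - cnt[["dr"]]) - (cnt[["lct"]] - cnt[["unet"]]),
                 sum(widths^2))
  }
})
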