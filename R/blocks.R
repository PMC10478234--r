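# Local Contextual Transformer (LCT) skip-attention block and the Dense
# Residual (DR) / plain residual convolution blocks.

#' Parameters of an LCT attention block
#'
#' The block embeds an input feature map X into queries, keys and values:
#' Q keeps a pointwise (1x1x1) embedding so each location's own information
#' is retained, while K and V use k x k x k *grouped* convolutions so every
#' key/value summarises its local k^3 neighbourhood. K and Q are concatenated
#' (in that order) and fused by a pointwise convolution with ReLU into the
#' attention map R1; R1 gates V element-wise (R2 = R1 * V); a softmax over
#' the channel axis yields the output.
#'
#' @param channels Number of feature channels C.
#' @param k Odd kernel size of the key/value context convolutions
#'   (default 3).
#' @param groups Group count of the context convolutions; must divide
#'   `channels` (default 4).
#' @return An object of class `lct_params`.
#' @export
lct_params <- function(channels, k = 3L, groups = 4L) {
  channels <- as.integer(channels); k <- as.integer(k); groups <- as.integer(groups)
  if (k %% 2L == 0L) cx_stop("bad_kernel", "k must be odd")
  if (channels %% groups != 0L)
    cx_stop("bad_groups", "groups must divide the channel count")
  structure(list(
    channels = channels, k = k, groups = groups,
    wq = list(w = init_conv_w(channels, channels, 1L), b = numeric(channels)),
    wk = list(w = init_conv_w(channels, channels, k, groups), b = numeric(channels)),
    wv = list(w = init_conv_w(channels, channels, k, groups), b = numeric(channels)),
    fuse = list(w = init_conv_w(2L * channels, channels, 1L), b = numeric(channels))
  ), class = "lct_params")
}

# Metadata (channel count, kernel, groups, block type) lives as a list
# element on the public objects but as an attribute on the parameter trees
# inside a built network, so optimisers and parameter counting only ever see
# numeric leaves.
meta_get <- function(p, nm) {
  v <- attr(p, nm, exact = TRUE)
  if (is.null(v)) v <- p[[nm]]
  v
}

strip_meta <- function(p, fields) {
  pl <- unclass(p)
  for (f in fields) {
    attr(pl, f) <- pl[[f]]
    pl[[f]] <- NULL
  }
  pl
}

lct_fwd_cache <- function(p, x, pad = "zero") {
  grp <- meta_get(p, "groups")
  if (dim(x)[1] != meta_get(p, "channels"))
    cx_stop("channel_mismatch", "input channels do not match params")
  q <- conv_fwd(x, p$wq$w, p$wq$b, 1L, pad, FALSE)
  k <- conv_fwd(x, p$wk$w, p$wk$b, grp, pad, FALSE)
  v <- conv_fwd(x, p$wv$w, p$wv$b, grp, pad, FALSE)
  kq <- cat_c(k, q)
  r1 <- conv_fwd(kq, p$fuse$w, p$fuse$b, 1L, pad, TRUE)
  r2 <- r1 * v
  dim(r2) <- dim(x)
  y <- cv_softmax_c(r2)
  list(y = y, cache = list(x = x, kq = kq, r1 = r1, v = v, y = y, pad = pad))
}

lct_bwd <- function(p, cache, gy) {
  pad <- pad_code(cache$pad)
  grp <- meta_get(p, "groups")
  g_r2 <- cv_softmax_c_bwd(cache$y, gy)
  g_r1 <- g_r2 * cache$v
  g_v <- g_r2 * cache$r1
  dim(g_r1) <- dim(gy); dim(g_v) <- dim(gy)
  g_r1 <- g_r1 * (cache$r1 > 0)  # fuse's ReLU
  dim(g_r1) <- dim(gy)
  bf <- cv_conv3d_bwd(cache$kq, p$fuse$w, g_r1, 1L, pad)
  C <- meta_get(p, "channels")
  parts <- split_c(bf$gx, c(C, C))
  bk <- cv_conv3d_bwd(cache$x, p$wk$w, parts[[1]], grp, pad)
  bq <- cv_conv3d_bwd(cache$x, p$wq$w, parts[[2]], 1L, pad)
  bv <- cv_conv3d_bwd(cache$x, p$wv$w, g_v, grp, pad)
  gx <- bk$gx + bq$gx + bv$gx
  dim(gx) <- dim(cache$x)
  list(gx = gx,
       g = list(wq = list(w = bq$gw, b = bq$gb),
                wk = list(w = bk$gw, b = bk$gb),
                wv = list(w = bv$gw, b = bv$gb),
                fuse = list(w = bf$gw, b = bf$gb)))
}

#' Forward pass of the LCT attention block
#'
#' @param x `(C, D, H, W)` feature array.
#' @param p An [lct_params()] whose channel count matches `x`.
#' @param pad `"zero"` (default) or `"circular"` padding for all
#'   convolutions; circular padding makes the block exactly translation
#'   equivariant on the torus.
#' @return `(C, D, H, W)` array; each voxel's channel vector is a softmax
#'   distribution (non-negative, sums to 1).
#' @export
lct_forward <- function(x, p, pad = "zero") {
  stopifnot(inherits(p, "lct_params"))
  lct_fwd_cache(p, x, pad)$y
}

#' Forward pass of the plain self-attention ablation block
#'
#' Identical pipeline to [lct_forward()] but with all three embeddings
#' pointwise (`k = 1`, `groups = 1`): the attention is computed from
#' isolated query-key pairs with no neighbourhood context.
#'
#' @param x `(C, D, H, W)` feature array.
#' @param p An [lct_params()] built with `k = 1, groups = 1`.
#' @param pad Padding mode (immaterial for pointwise kernels).
#' @return `(C, D, H, W)` array of per-voxel channel distributions.
#' @export
sa_forward <- function(x, p, pad = "zero") {
  stopifnot(inherits(p, "lct_params"))
  if (p$k != 1L || p$groups != 1L)
    cx_stop("bad_kernel", "self-attention variant requires k = 1 and groups = 1")
  lct_fwd_cache(p, x, pad)$y
}

# ---------------------------------------------------------------------------

#' Parameters of a plain / residual / dense-residual convolution block
#'
#' All block types share the convolution unit H (3x3x3 convolution, same
#' padding, ReLU; optional per-channel instance normalisation in between for
#' training). `plain` is H2(H1(x)); `residual` adds the (projected) input:
#' P(x) + H2(H1(x)); `dense_residual` runs a third unit on the first
#' residual sum and then sums every intermediate map:
#' Y = P(x) + H1(x) + H2(H1(x)) + H3(P(x) + H2(H1(x))).
#' P is a pointwise projection when input and output widths differ and the
#' identity otherwise.
#'
#' @param cin,cout Input/output channel widths.
#' @param type `"plain"`, `"residual"` or `"dense_residual"`.
#' @param norm Use instance normalisation inside each unit (default `FALSE`,
#'   the bare conv+ReLU unit).
#' @return An object of class `dr_params`.
#' @export
dr_params <- function(cin, cout, type = c("dense_residual", "residual", "plain"),
                      norm = FALSE) {
  type <- match.arg(type)
  p <- list(type = type,
            u1 = cu_new(cin, cout, 3L, norm),
            u2 = cu_new(cout, cout, 3L, norm))
  if (type == "dense_residual") p$u3 <- cu_new(cout, cout, 3L, norm)
  if (type != "plain" && cin != cout)
    p$p <- list(w = init_conv_w(cin, cout, 1L), b = numeric(cout))
  structure(p, class = "dr_params")
}

block_fwd_cache <- function(bp, x) {
  type <- meta_get(bp, "type")
  r1 <- cu_fwd(bp$u1, x)
  r2 <- cu_fwd(bp$u2, r1$y)
  if (type == "plain")
    return(list(y = r2$y, cache = list(c1 = r1$cache, c2 = r2$cache)))
  px <- if (!is.null(bp$p)) conv_fwd(x, bp$p$w, bp$p$b, 1L, "zero", FALSE) else x
  if (type == "residual") {
    y <- px + r2$y
    dim(y) <- dim(r2$y)
    return(list(y = y, cache = list(c1 = r1$cache, c2 = r2$cache, x = x)))
  }
  rsum <- px + r2$y
  dim(rsum) <- dim(r2$y)
  r3 <- cu_fwd(bp$u3, rsum)
  y <- px + r1$y + r2$y + r3$y
  dim(y) <- dim(r2$y)
  list(y = y, cache = list(c1 = r1$cache, c2 = r2$cache, c3 = r3$cache, x = x))
}

proj_bwd <- function(bp, x, g) {
  if (!is.null(bp$p)) {
    r <- cv_conv3d_bwd(x, bp$p$w, g, 1L, 0L)
    list(gx = r$gx, g = list(w = r$gw, b = r$gb))
  } else list(gx = g, g = NULL)
}

block_bwd <- function(bp, cache, gy) {
  type <- meta_get(bp, "type")
  if (type == "plain") {
    b2 <- cu_bwd(bp$u2, cache$c2, gy)
    b1 <- cu_bwd(bp$u1, cache$c1, b2$gx)
    return(list(gx = b1$gx, g = list(u1 = b1$g, u2 = b2$g)))
  }
  if (type == "residual") {
    b2 <- cu_bwd(bp$u2, cache$c2, gy)
    b1 <- cu_bwd(bp$u1, cache$c1, b2$gx)
    pb <- proj_bwd(bp, cache$x, gy)
    gx <- b1$gx + pb$gx
    dim(gx) <- dim(cache$x)
    g <- list(u1 = b1$g, u2 = b2$g)
    if (!is.null(pb$g)) g$p <- pb$g
    return(list(gx = gx, g = g))
  }
  # dense residual: Y = P(x) + A1 + A2 + A3, A3 = H3(R), R = P(x) + A2
  b3 <- cu_bwd(bp$u3, cache$c3, gy)
  g_r <- b3$gx
  g_a2 <- gy + g_r
  dim(g_a2) <- dim(gy)
  b2 <- cu_bwd(bp$u2, cache$c2, g_a2)
  g_a1 <- gy + b2$gx
  dim(g_a1) <- dim(gy)
  b1 <- cu_bwd(bp$u1, cache$c1, g_a1)
  g_px <- gy + g_r
  dim(g_px) <- dim(gy)
  pb <- proj_bwd(bp, cache$x, g_px)
  gx <- b1$gx + pb$gx
  dim(gx) <- dim(cache$x)
  g <- list(u1 = b1$g, u2 = b2$g, u3 = b3$g)
  if (!is.null(pb$g)) g$p <- pb$g
  list(gx = gx, g = g)
}

#' Forward pass of the plain residual block
#'
#' `Y = P(x) + H2(H1(x))`.
#'
#' @param x `(C_in, D, H, W)` feature array.
#' @param p A [dr_params()] of type `"residual"`.
#' @return `(C_out, D, H, W)` array.
#' @export
residual_forward <- function(x, p) {
  stopifnot(inherits(p, "dr_params"), p$type == "residual")
  block_fwd_cache(p, x)$y
}

#' Forward pass of the dense residual block
#'
#' `Y = P(x) + H1(x) + H2(H1(x)) + H3(P(x) + H2(H1(x)))`: a first residual
#' sum after the second convolution, a third convolution on that sum, and a
#' second residual connection that adds up the input and every intermediate
#' feature map.
#'
#' @param x `(C_in, D, H, W)` feature array.
#' @param p A [dr_params()] of type `"dense_residual"`.
#' @return `(C_out, D, H, W)` array.
#' @export
dr_forward <- function(x, p) {
  stopifnot(inherits(p, "dr_params"), p$type == "dense_residual")
  block_fwd_cache(p, x)$y
}
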