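# Independent oracles used across the test files. These deliberately avoid
# the package's compiled kernels: convolutions are evaluated by explicit
# neighbourhood gathering, distances by all-pairs scans, counts by loops.

# Explicit-gather 3-D convolution (stride 1, zero same-padding, optional
# groups): plain R loops over output voxels and kernel taps.
oracle_conv3d <- function(x, w, b, groups = 1L) {
  d <- dim(x)
  K <- dim(w)[2]; cout <- dim(w)[5]; cing <- dim(w)[1]
  p <- (K - 1) / 2
  coutg <- cout / groups
  y <- array(0, c(cout, d[2:4]))
  for (oc in seq_len(cout)) {
    g <- (oc - 1) %/% coutg
    for (dv in seq_len(d[2])) for (hv in seq_len(d[3])) for (wv in seq_len(d[4])) {
      acc <- b[oc]
      for (icg in seq_len(cing)) {
        ic <- g * cing + icg
        for (dz in 0:(K - 1)) for (dy in 0:(K - 1)) for (dx in 0:(K - 1)) {
          iz <- dv + dz - p; iy <- hv + dy - p; ix <- wv + dx - p
          if (iz >= 1 && iz <= d[2] && iy >= 1 && iy <= d[3] && ix >= 1 && ix <= d[4])
            acc <- acc + w[icg, dz + 1, dy + 1, dx + 1, oc] * x[ic, iz, iy, ix]
        }
      }
      y[oc, dv, hv, wv] <- acc
    }
  }
  y
}

oracle_relu <- function(x) { y <- pmax(x, 0); dim(y) <- dim(x); y }

oracle_softmax_c <- function(x) {
  d <- dim(x)
  y <- x
  for (dv in seq_len(d[2])) for (hv in seq_len(d[3])) for (wv in seq_len(d[4])) {
    v <- x[, dv, hv, wv]
    e <- exp(v - max(v))
    y[, dv, hv, wv] <- e / sum(e)
  }
  y
}

# Step-by-step LCT evaluation from the same parameter object.
oracle_lct <- function(x, p) {
  q <- oracle_conv3d(x, p$wq$w, p$wq$b)
  k <- oracle_conv3d(x, p$wk$w, p$wk$b, groups = p$groups)
  v <- oracle_conv3d(x, p$wv$w, p$wv$b, groups = p$groups)
  C <- dim(x)[1]
  kq <- array(0, c(2 * C, dim(x)[2:4]))
  kq[1:C, , , ] <- k
  kq[(C + 1):(2 * C), , , ] <- q
  r1 <- oracle_relu(oracle_conv3d(kq, p$fuse$w, p$fuse$b))
  oracle_softmax_c(r1 * v)
}

# Term-by-term dense-residual evaluation (conv unit = conv + ReLU, no norm).
oracle_dr <- function(x, p) {
  H <- function(u, xx) oracle_relu(oracle_conv3d(xx, u$w, u$b))
  px <- if (!is.null(p$p)) oracle_conv3d(x, p$p$w, p$p$b) else x
  a1 <- H(p$u1, x)
  a2 <- H(p$u2, a1)
  a3 <- H(p$u3, px + a2)
  px + a1 + a2 + a3
}

# Direct triple-loop confusion counts.
oracle_confusion <- function(pred, gt) {
  d <- dim(pred)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- pred[i, j, k] != 0; g <- gt[i, j, k] != 0
    if (p && g) tp <- tp + 1L
    else if (p) fp <- fp + 1L
    else if (g) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn)
}

# All-pairs surface distances from two coordinate matrices.
oracle_surface_dists <- function(a, b) {
  dm <- sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b))
  dm[dm < 0 | is.nan(dm)] <- 0
  dab <- apply(dm, 1, min)
  dba <- apply(dm, 2, min)
  list(assd = (sum(dab) + sum(dba)) / (nrow(a) + nrow(b)),
       hd = max(max(dab), max(dba)))
}

# Random binary mask helper.
rand_mask <- function(dims, p = 0.3) {
  m <- array(as.integer(runif(prod(dims)) < p), dims)
  m
}

# Configure a conv unit as the identity on non-negative input: centre-one
# kernels wiring channel i to channel i, zero bias.
identity_unit <- function(u) {
  u$w[] <- 0
  K <- dim(u$w)[2]
  ctr <- (K + 1) / 2
  for (c in seq_len(dim(u$w)[5])) u$w[c, ctr, ctr, ctr, c] <- 1
  u$b[] <- 0
  u
}

count_leaves <- function(p) {
  if (is.numeric(p)) return(length(p))
  if (!is.list(p)) return(0)
  sum(vapply(p, count_leaves, numeric(1)))
}

# Circular shift of a (C, D, H, W) array along the spatial axes.
circ_shift <- function(x, s) {
  d <- dim(x)
  idx <- function(n, by) ((seq_len(n) - 1 - by) %% n) + 1
  x[, idx(d[2], s[1]), idx(d[3], s[2]), idx(d[4], s[3]), drop = FALSE]
}
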