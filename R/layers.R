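# Internal layer primitives. Feature maps are (C, D, H, W) double arrays.
# Every layer exposes a *_fwd returning list(y, cache) and a *_bwd returning
# list(gx, g = <gradients mirroring the parameter list>). Backprop is
# hand-wired: the network topology is fixed, so a tape is unnecessary.

pad_code <- function(pad) if (identical(pad, "circular")) 1L else 0L

conv_fwd <- function(x, w, b, groups = 1L, pad = "zero", relu = FALSE) {
  cv_conv3d_fwd(x, w, b, as.integer(groups), pad_code(pad), isTRUE(relu))
}

# He-normal initialised convolution weight (cin_per_group, k, k, k, cout).
init_conv_w <- function(cin, cout, k, groups = 1L, gain = 2) {
  cing <- cin %/% groups
  fan <- cing * k^3
  array(rnorm(cing * k^3 * cout, 0, sqrt(gain / fan)), c(cing, k, k, k, cout))
}

# --- conv unit: conv (stride 1, same padding) -> optional instance norm ->
# --- optional ReLU. The canonical unit H(X) is conv+ReLU (norm = FALSE);
# --- training presets switch per-channel instance normalisation on.
cu_new <- function(cin, cout, k = 3L, norm = FALSE, groups = 1L) {
  p <- list(w = init_conv_w(cin, cout, k, groups), b = numeric(cout))
  if (norm) { p$gamma <- rep(1, cout); p$beta <- numeric(cout) }
  p
}

inorm_fwd <- function(z, gamma, beta, eps = 1e-5) {
  d <- dim(z)
  m <- matrix(z, d[1])
  mu <- rowMeans(m)
  xc <- m - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- gamma * xhat + beta
  dim(y) <- d
  list(y = y, xhat = xhat, inv = inv)
}

inorm_bwd <- function(gy, gamma, xhat, inv, d) {
  g <- matrix(gy, d[1])
  ggamma <- rowSums(g * xhat)
  gbeta <- rowSums(g)
  gxh <- g * gamma
  gx <- inv * (gxh - rowMeans(gxh) - xhat * rowMeans(gxh * xhat))
  dim(gx) <- d
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

cu_fwd <- function(p, x, groups = 1L, pad = "zero", relu = TRUE) {
  if (is.null(p$gamma)) {
    y <- conv_fwd(x, p$w, p$b, groups, pad, relu)
    list(y = y, cache = list(x = x, y = y, relu = relu, groups = groups, pad = pad))
  } else {
    z <- conv_fwd(x, p$w, p$b, groups, pad, FALSE)
    nr <- inorm_fwd(z, p$gamma, p$beta)
    y <- nr$y
    if (relu) { y <- y * (y > 0); dim(y) <- dim(z) }
    list(y = y, cache = list(x = x, y = y, xhat = nr$xhat, inv = nr$inv,
                             relu = relu, groups = groups, pad = pad))
  }
}

cu_bwd <- function(p, cache, gy) {
  if (cache$relu) gy <- gy * (cache$y > 0)
  if (!is.null(p$gamma)) {
    d <- dim(cache$y)
    nb <- inorm_bwd(gy, p$gamma, cache$xhat, cache$inv, d)
    gy <- nb$gx
  }
  dim(gy) <- dim(cache$y)
  r <- cv_conv3d_bwd(cache$x, p$w, gy, as.integer(cache$groups),
                     pad_code(cache$pad))
  g <- list(w = r$gw, b = r$gb)
  if (!is.null(p$gamma)) { g$gamma <- nb$ggamma; g$beta <- nb$gbeta }
  list(gx = r$gx, g = g)
}

# --- transposed convolution, kernel 2 stride 2 ---
up_new <- function(cin, cout) {
  list(w = array(rnorm(cin * cout * 8, 0, sqrt(2 / (cin * 8))), c(cin, cout, 2, 2, 2)),
       b = numeric(cout))
}

up_fwd <- function(p, x) list(y = cv_upconv_fwd(x, p$w, p$b), cache = list(x = x))

up_bwd <- function(p, cache, gy) {
  r <- cv_upconv_bwd(cache$x, p$w, gy)
  list(gx = r$gx, g = list(w = r$gw, b = r$gb))
}

# --- channel concatenation and its split ---
cat_c <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 1L) return(parts[[1]])
  ds <- lapply(parts, dim)
  cs <- vapply(ds, `[`, integer(1), 1L)
  out <- array(0, c(sum(cs), ds[[1]][2:4]))
  at <- 0L
  for (i in seq_along(parts)) {
    out[(at + 1):(at + cs[i]), , , ] <- parts[[i]]
    at <- at + cs[i]
  }
  out
}

split_c <- function(g, widths) {
  at <- 0L
  out <- vector("list", length(widths))
  for (i in seq_along(widths)) {
    out[[i]] <- g[(at + 1):(at + widths[i]), , , , drop = FALSE]
    at <- at + widths[i]
  }
  out
}

# --- parameter-tree utilities (params, grads, Adam moments all share the
# --- same nested-list shape with numeric leaves) ---
tree_count <- function(p) {
  if (is.numeric(p)) return(length(p))
  if (is.list(p)) return(sum(vapply(p, tree_count, numeric(1))))
  0
}

tree_map2 <- function(f, a, b) {
  if (is.numeric(a)) return(f(a, b))
  if (!is.list(a)) return(a)
  out <- a
  for (nm in seq_along(a)) {
    if (is.null(a[[nm]])) next
    out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
  }
  out
}

tree_zero <- function(p) {
  if (is.numeric(p)) { z <- p; z[] <- 0; return(z) }
  if (!is.list(p)) return(p)
  lapply(p, function(e) if (is.null(e)) NULL else tree_zero(e))
}

# Adam with decoupled-from-schedule L2 weight decay applied to convolution
# weights (names "w"), not to biases or norm parameters.
adam_new <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v, decay) {
    if (!is.list(p) && !is.numeric(p)) return(list(p = p, m = m, v = v))
    if (is.numeric(p)) {
      if (decay > 0) g <- g + decay * p
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      p <- p - lr * mh / (sqrt(vh) + eps)
      return(list(p = p, m = m, v = v))
    }
    nms <- names(p)
    for (i in seq_along(p)) {
      if (is.null(p[[i]])) next
      nm <- if (is.null(nms)) "" else nms[i]
      dec <- if (is.numeric(p[[i]]) && nm != "w") 0 else weight_decay
      sub <- walk(p[[i]], g[[i]], m[[i]], v[[i]], dec)
      p[[i]] <- sub$p; m[[i]] <- sub$m; v[[i]] <- sub$v
    }
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v, weight_decay)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
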