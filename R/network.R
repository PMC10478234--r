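#' Network architecture configuration
#'
#' A U-shaped 3-D segmentation network with `levels` encoder stages (channel
#' width doubling per stage), 2x2x2 max-pool downsampling between them, and
#' `levels - 1` decoder stages fed by a three-part concatenation: the skip
#' block's output at that resolution, the raw encoder features, and the
#' transposed-convolution upsampling of the previous decoder stage. Deep
#' supervision attaches a softmax head to every deeper decoder stage and to
#' the bottleneck, each trilinearly upsampled to input size.
#'
#' @param levels Number of encoder stages (default 4: three downsamplings
#'   plus a bottleneck).
#' @param base_channels Channel width of the first stage (default 16;
#'   the CPU desk preset uses 8). Doubles at every level.
#' @param block Convolution block used in every encoder/decoder stage:
#'   `"plain"`, `"residual"` or `"dense_residual"`.
#' @param skip Skip-connection transform: `"identity"` (plain 3D-UNet
#'   concatenation), `"self_attention"` (pointwise attention) or `"lct"`
#'   (local contextual transformer).
#' @param lct_k Kernel size of the LCT context convolutions (default 3).
#' @param lct_groups Group count of the LCT context convolutions; must
#'   divide every level's width (default 4).
#' @param in_channels Input channels (default 1).
#' @param n_classes Output classes (default 2: background/vessel).
#' @param deep_supervision Attach auxiliary supervision heads
#'   (default `TRUE`).
#' @param norm Use instance normalisation inside the convolution units
#'   (default `TRUE`; switch off for algebraic analyses of the bare blocks).
#' @return An object of class `network_config`.
#' @export
network_config <- function(levels = 4L, base_channels = 16L,
                           block = c("dense_residual", "residual", "plain"),
                           skip = c("lct", "self_attention", "identity"),
                           lct_k = 3L, lct_groups = 4L, in_channels = 1L,
                           n_classes = 2L, deep_supervision = TRUE,
                           norm = TRUE) {
  block <- match.arg(block)
  skip <- match.arg(skip)
  levels <- as.integer(levels); base_channels <- as.integer(base_channels)
  if (levels < 2L) cx_stop("bad_config", "levels must be >= 2")
  if (base_channels < 2L) cx_stop("bad_config", "base_channels must be >= 2")
  widths <- base_channels * 2L^(0:(levels - 1L))
  if (skip == "lct" && any(widths %% lct_groups != 0L))
    cx_stop("bad_config", "lct_groups must divide every level's channel width")
  structure(list(levels = levels, base_channels = base_channels,
                 widths = widths, block = block, skip = skip,
                 lct_k = as.integer(lct_k), lct_groups = as.integer(lct_groups),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 deep_supervision = isTRUE(deep_supervision),
                 norm = isTRUE(norm)),
            class = "network_config")
}

#' Ablation variant configurations
#'
#' Named presets for the ablation rows: `"unet"` (plain blocks, identity
#' skips), `"sa"` (+ pointwise self-attention skips), `"lct"` (+ local
#' contextual transformer skips), `"r"` (residual blocks), `"dr"` (dense
#' residual blocks), `"dr_lct"` (dense residual blocks + LCT skips, the full
#' model).
#'
#' @param name One of `"unet"`, `"sa"`, `"lct"`, `"r"`, `"dr"`, `"dr_lct"`.
#' @param ... Further arguments passed to [network_config()] (e.g.
#'   `base_channels`).
#' @return A [network_config()].
#' @export
make_variant <- function(name, ...) {
  tab <- list(
    unet = list(block = "plain", skip = "identity"),
    sa = list(block = "plain", skip = "self_attention"),
    lct = list(block = "plain", skip = "lct"),
    r = list(block = "residual", skip = "identity"),
    dr = list(block = "dense_residual", skip = "identity"),
    dr_lct = list(block = "dense_residual", skip = "lct")
  )
  if (!name %in% names(tab)) cx_stop("unknown_variant", paste0("unknown variant: ", name))
  do.call(network_config, c(tab[[name]], list(...)))
}

#' Build a network from a configuration
#'
#' Initialises all trainable parameters (He-normal convolution weights,
#' zero biases, unit/zero normalisation scales) under the given seed;
#' deterministic given `(config, seed)`.
#'
#' @param config A [network_config()].
#' @param seed Integer RNG seed for initialisation.
#' @return An object of class `corovox_net`: list with `config` and the
#'   nested parameter list `params`.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  set.seed(as.integer(seed))
  L <- config$levels
  w <- config$widths
  nrm <- config$norm
  mkblock <- function(cin, cout)
    strip_meta(dr_params(cin, cout, config$block, norm = nrm), "type")
  mkskip <- function(ci) {
    if (config$skip == "identity") return(NULL)
    p <- if (config$skip == "self_attention") lct_params(ci, 1L, 1L)
         else lct_params(ci, config$lct_k, config$lct_groups)
    strip_meta(p, c("channels", "k", "groups"))
  }
  params <- list(
    enc = lapply(seq_len(L), function(i)
      mkblock(if (i == 1L) config$in_channels else w[i - 1L], w[i])),
    skip = lapply(seq_len(L - 1L), function(i) mkskip(w[i])),
    up = lapply(seq_len(L - 1L), function(i) up_new(w[i + 1L], w[i])),
    dec = lapply(seq_len(L - 1L), function(i) {
      parts <- if (config$skip == "identity") 2L else 3L
      mkblock(parts * w[i], w[i])
    }),
    head_main = list(w = init_conv_w(w[1L], config$n_classes, 1L),
                     b = numeric(config$n_classes))
  )
  if (config$deep_supervision) {
    aux <- list()
    if (L > 2L) for (i in 2L:(L - 1L))
      aux[[paste0("d", i)]] <- list(w = init_conv_w(w[i], config$n_classes, 1L),
                                    b = numeric(config$n_classes))
    aux[["bott"]] <- list(w = init_conv_w(w[L], config$n_classes, 1L),
                          b = numeric(config$n_classes))
    params$aux <- aux
  }
  structure(list(config = config, params = params), class = "corovox_net")
}

#' Count trainable parameters
#'
#' @param net A [build_network()] result.
#' @return Total number of trainable scalar parameters.
#' @export
count_params <- function(net) {
  stopifnot(inherits(net, "corovox_net"))
  tree_count(net$params)
}

# Restore 4-D dims dropped by arithmetic on arrays.
as4 <- function(x, d) { dim(x) <- d; x }

head_fwd <- function(hp, x, out_dims = NULL) {
  z <- conv_fwd(x, hp$w, hp$b, 1L, "zero", FALSE)
  probs <- cv_softmax_c(z)
  up <- if (is.null(out_dims)) probs else cv_resize3(probs, out_dims[1], out_dims[2], out_dims[3])
  list(probs_low = probs, y = up, x = x)
}

head_bwd <- function(hp, cache, g_up) {
  d_low <- dim(cache$probs_low)
  g_low <- if (identical(dim(g_up), d_low)) g_up
           else cv_resize3_adj(g_up, d_low[2], d_low[3], d_low[4])
  gz <- cv_softmax_c_bwd(cache$probs_low, g_low)
  r <- cv_conv3d_bwd(cache$x, hp$w, gz, 1L, 0L)
  list(gx = r$gx, g = list(w = r$gw, b = r$gb))
}

# Full forward pass; when `train` is TRUE all caches needed for
# backpropagation are retained and returned.
net_forward_full <- function(net, x, train = FALSE) {
  cfg <- net$config
  P <- net$params
  L <- cfg$levels
  in_dims <- dim(x)[2:4]
  e <- vector("list", L)
  enc_cache <- vector("list", L)
  pool_cache <- vector("list", L - 1L)
  cur <- x
  for (i in seq_len(L)) {
    bf <- block_fwd_cache(P$enc[[i]], cur)
    e[[i]] <- bf$y
    if (train) enc_cache[[i]] <- bf$cache
    if (i < L) {
      mp <- cv_maxpool_fwd(bf$y)
      cur <- mp$y
      if (train) pool_cache[[i]] <- list(idx = mp$idx, xdim = dim(bf$y))
    }
  }
  d <- vector("list", L)
  d[[L]] <- e[[L]]
  up_cache <- vector("list", L - 1L)
  skip_cache <- vector("list", L - 1L)
  dec_cache <- vector("list", L - 1L)
  cat_widths <- vector("list", L - 1L)
  for (i in (L - 1L):1L) {
    uf <- up_fwd(P$up[[i]], d[[i + 1L]])
    if (train) up_cache[[i]] <- uf$cache
    if (is.null(P$skip[[i]])) {
      catx <- cat_c(e[[i]], uf$y)
      cat_widths[[i]] <- c(dim(e[[i]])[1], dim(uf$y)[1])
    } else {
      sf <- lct_fwd_cache(P$skip[[i]], e[[i]])
      if (train) skip_cache[[i]] <- sf$cache
      catx <- cat_c(sf$y, e[[i]], uf$y)
      cat_widths[[i]] <- c(dim(sf$y)[1], dim(e[[i]])[1], dim(uf$y)[1])
    }
    bf <- block_fwd_cache(P$dec[[i]], catx)
    d[[i]] <- bf$y
    if (train) dec_cache[[i]] <- bf$cache
  }
  hm <- head_fwd(P$head_main, d[[1L]])
  aux <- NULL
  aux_cache <- NULL
  if (cfg$deep_supervision) {
    aux <- list(); aux_cache <- list()
    if (L > 2L) for (i in 2L:(L - 1L)) {
      hf <- head_fwd(P$aux[[paste0("d", i)]], d[[i]], in_dims)
      aux[[paste0("d", i)]] <- hf$y
      aux_cache[[paste0("d", i)]] <- hf
    }
    hb <- head_fwd(P$aux$bott, e[[L]], in_dims)
    aux$bott <- hb$y
    aux_cache$bott <- hb
  }
  out <- list(main = hm$y, aux = aux)
  if (train)
    out$caches <- list(enc = enc_cache, pool = pool_cache, up = up_cache,
                       skip = skip_cache, dec = dec_cache,
                       main_head = hm, aux_head = aux_cache,
                       e = e, d = d)
  out
}

#' Forward pass of the network
#'
#' @param net A [build_network()] result.
#' @param x Input block, `(in_channels, depth, H, W)` array with `H`, `W`
#'   (and depth, unless >= `2^(levels-1)`) divisible by `2^(levels-1)`.
#' @return List with `main` — a `(n_classes, depth, H, W)` grid of class
#'   probabilities — and `aux`, a list of auxiliary probability grids
#'   upsampled to input size (`NULL` when deep supervision is off).
#' @export
network_forward <- function(net, x) {
  stopifnot(inherits(net, "corovox_net"))
  d <- dim(x)
  if (length(d) != 4L || d[1] != net$config$in_channels)
    cx_stop("bad_input", "input must be (in_channels, D, H, W)")
  f <- 2L^(net$config$levels - 1L)
  if (any(d[2:4] %% f != 0L))
    cx_stop("bad_input", sprintf("spatial dims must be divisible by %d", f))
  net_forward_full(net, x, train = FALSE)[c("main", "aux")]
}

# Forward + loss + full gradient for one sample. gt is the binary
# ground-truth grid at input resolution. Returns the per-head Dice losses,
# the composite loss, and gradients mirroring net$params.
net_train_step <- function(net, x, gt, alpha) {
  cfg <- net$config
  L <- cfg$levels
  P <- net$params
  fw <- net_forward_full(net, x, train = TRUE)
  cs <- fw$caches
  g <- vox(gt)

  fg_grad <- function(probs) {
    # dice loss + gradient w.r.t. the 2-channel probability grid
    p_fg <- probs[2, , , , drop = TRUE]
    dim(p_fg) <- dim(probs)[2:4]
    loss <- dice_loss(p_fg, g)
    garr <- array(0, dim(probs))
    garr[2, , , ] <- dice_loss_grad(p_fg, g)
    list(loss = loss, g = garr)
  }

  m <- fg_grad(fw$main)
  losses <- c(L1 = m$loss)
  grads <- list(enc = vector("list", L), skip = vector("list", L - 1L),
                up = vector("list", L - 1L), dec = vector("list", L - 1L))

  hb <- head_bwd(P$head_main, cs$main_head, m$g)
  grads$head_main <- hb$g
  g_d <- vector("list", L)   # gradient w.r.t. decoder outputs
  g_e <- vector("list", L)   # gradient w.r.t. encoder outputs
  g_d[[1L]] <- hb$gx

  addg <- function(a, b) if (is.null(a)) b else as4(a + b, dim(b))

  if (cfg$deep_supervision) {
    grads$aux <- list()
    k <- 2L
    if (L > 2L) for (i in 2L:(L - 1L)) {
      nm <- paste0("d", i)
      af <- fg_grad(fw$aux[[nm]])
      losses[paste0("L", k)] <- af$loss
      ab <- head_bwd(P$aux[[nm]], cs$aux_head[[nm]], alpha * af$g)
      grads$aux[[nm]] <- ab$g
      g_d[[i]] <- addg(g_d[[i]], ab$gx)
      k <- k + 1L
    }
    bf <- fg_grad(fw$aux$bott)
    losses[paste0("L", k)] <- bf$loss
    bb <- head_bwd(P$aux$bott, cs$aux_head$bott, alpha * bf$g)
    grads$aux$bott <- bb$g
    g_e[[L]] <- addg(g_e[[L]], bb$gx)
  }

  # decoder chain, full resolution downwards
  for (i in seq_len(L - 1L)) {
    db <- block_bwd(P$dec[[i]], cs$dec[[i]], g_d[[i]])
    grads$dec[[i]] <- db$g
    parts <- split_c(db$gx, net_cat_widths(cfg, i))
    if (is.null(P$skip[[i]])) {
      g_e[[i]] <- addg(g_e[[i]], parts[[1L]])
      g_up_out <- parts[[2L]]
    } else {
      sb <- lct_bwd(P$skip[[i]], cs$skip[[i]], parts[[1L]])
      grads$skip[[i]] <- sb$g
      g_e[[i]] <- addg(addg(g_e[[i]], sb$gx), parts[[2L]])
      g_up_out <- parts[[3L]]
    }
    ub <- up_bwd(P$up[[i]], cs$up[[i]], g_up_out)
    grads$up[[i]] <- ub$g
    if (i + 1L < L) g_d[[i + 1L]] <- addg(g_d[[i + 1L]], ub$gx)
    else g_e[[L]] <- addg(g_e[[L]], ub$gx)
  }

  # encoder chain, bottleneck upwards
  for (i in L:1L) {
    eb <- block_bwd(P$enc[[i]], cs$enc[[i]], g_e[[i]])
    grads$enc[[i]] <- eb$g
    if (i > 1L) {
      gp <- cv_maxpool_bwd(eb$gx, cs$pool[[i - 1L]]$idx, dim(cs$e[[i - 1L]]))
      g_e[[i - 1L]] <- addg(g_e[[i - 1L]], gp)
    }
  }

  total <- deep_supervision_loss(unname(losses), alpha)
  list(losses = losses, total = total, grads = grads, main = fw$main)
}

net_cat_widths <- function(cfg, i) {
  wi <- cfg$widths[i]
  if (cfg$skip == "identity") c(wi, wi) else c(wi, wi, wi)
}
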