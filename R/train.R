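#' Training configuration
#'
#' Bundles the network architecture, the learning-rate / supervision-weight
#' schedule, the data source and the sampling strategy of one training run.
#' Data can be an in-memory case list or a phantom generator specification
#' plus a case count; phantom cases are regenerated deterministically from
#' the run seed whenever needed, so a run object stays lightweight.
#'
#' @param network A [network_config()].
#' @param schedule A [schedule_config()].
#' @param data Either `list(spec = <phantom_spec>, n_cases = <int>)` or
#'   `list(cases = <list of list(volume, mask)>)`.
#' @param split Train/validation/test fractions summing to 1
#'   (default `c(0.6, 0.1, 0.3)`).
#' @param seed Master seed; fixes the case split, the weight initialisation
#'   and all sampling.
#' @param crop Training crop `(depth, height, width)`, each divisible by
#'   `2^(levels-1)`; `NULL` trains on full-width blocks of depth 16.
#' @param fg_crop_prob Probability that a training crop is centred on a
#'   random foreground voxel (default 0.8; vessels occupy so few voxels that
#'   uniform crops would mostly be background).
#' @param block_depth,stride Sliding-block parameters used for validation
#'   and test inference.
#' @param window HU window applied to volumes before the network.
#' @return An object of class `train_config`.
#' @export
train_config <- function(network = network_config(), schedule = schedule_config(),
                         data, split = c(0.6, 0.1, 0.3), seed = 1L,
                         crop = c(16L, 32L, 32L), fg_crop_prob = 0.8,
                         block_depth = 16L, stride = 8L,
                         window = c(-260, 760)) {
  if (abs(sum(split) - 1) > 1e-9) cx_stop("bad_config", "split fractions must sum to 1")
  structure(list(network = network, schedule = schedule, data = data,
                 split = split, seed = as.integer(seed), crop = crop,
                 fg_crop_prob = fg_crop_prob, block_depth = as.integer(block_depth),
                 stride = as.integer(stride), window = window),
            class = "train_config")
}

#' Desk-scale training preset
#'
#' A configuration small enough to train on one CPU in minutes: 8 base
#' channels, 100 synthetic phantoms of 32 x 64 x 64 voxels split 6:1:3
#' (60 train / 10 validation / 30 test), 20 epochs with the schedule
#' boundaries compressed proportionally and the learning rates scaled up by
#' 30 (3e-4 -> 3e-6) so the short run converges, batch size 2, and random
#' 8 x 32 x 32 foreground-biased training crops.
#'
#' @param seed Master seed.
#' @param variant Ablation variant name passed to [make_variant()]
#'   (default `"dr_lct"`, the full model).
#' @param epochs Training epochs (default 20).
#' @param n_cases Number of phantoms (default 100).
#' @param deep_supervision Use deep supervision (default `TRUE`).
#' @return A [train_config()].
#' @export
desk_preset <- function(seed = 1L, variant = "dr_lct", epochs = 20L,
                        n_cases = 100L, deep_supervision = TRUE) {
  train_config(
    network = make_variant(variant, base_channels = 8L,
                           deep_supervision = deep_supervision),
    schedule = schedule_config(epochs = epochs, lr_scale = 30, batch_size = 2L),
    data = list(spec = phantom_spec(shape = c(32L, 64L, 64L)), n_cases = as.integer(n_cases)),
    seed = seed, crop = c(8L, 32L, 32L)
  )
}

# Materialise the configured cases: returns list of list(volume, mask) with
# volumes already windowed to [0, 1] arrays.
resolve_cases <- function(cfg) {
  raw <- if (!is.null(cfg$data$cases)) {
    cfg$data$cases
  } else {
    lapply(seq_len(cfg$data$n_cases), function(i) {
      sp <- cfg$data$spec
      sp$seed <- cx_subseed(cfg$seed, 1000L + i)
      generate_case(sp)
    })
  }
  lapply(raw, function(cs) {
    nv <- if (inherits(cs$volume, "normalized_volume")) cs$volume
          else window_and_normalize(cs$volume, cfg$window[1], cfg$window[2])
    list(x = vox(nv), y = vox(cs$mask))
  })
}

split_cases <- function(n, split, seed) {
  set.seed(cx_subseed(seed, 11L))
  idx <- sample.int(n)
  ntr <- round(n * split[1])
  nva <- round(n * split[2])
  list(train = idx[seq_len(ntr)],
       val = idx[ntr + seq_len(nva)],
       test = idx[(ntr + nva + 1):n])
}

sample_crop <- function(x, y, crop, fg_prob) {
  d <- dim(x)
  center <- if (runif(1) < fg_prob && any(y == 1L)) {
    fg <- which(y == 1L)
    arrayInd(fg[sample.int(length(fg), 1L)], d)[1, ]
  } else {
    c(sample.int(d[1], 1L), sample.int(d[2], 1L), sample.int(d[3], 1L))
  }
  lo <- pmin(pmax(center - crop %/% 2L, 1L), d - crop + 1L)
  hi <- lo + crop - 1L
  list(x = x[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       y = y[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
}

# Sliding-block class probabilities for a whole (D, H, W) array in [0, 1].
infer_probs <- function(net, xarr, block_depth, stride) {
  plan <- plan_blocks(dim(xarr)[1], block_depth, stride)
  blocks <- extract_blocks(xarr, plan)
  outs <- lapply(blocks, function(b) {
    xb <- array(b, c(1L, dim(b)))
    net_forward_full(net, xb, train = FALSE)$main
  })
  stitch_blocks(plan, outs)
}

pred_mask_from_probs <- function(probs) {
  p_fg <- probs[2, , , , drop = TRUE]
  dim(p_fg) <- dim(probs)[2:4]
  m <- array(0L, dim(p_fg))
  m[p_fg > 0.5] <- 1L   # exact ties resolve to background
  m
}

# Validation mean DSC on a fixed subset of the validation cases, scored on
# the centre block of each volume (one forward pass per case): cheap enough
# to run after every epoch while still tracking whole-network quality.
val_dsc_of <- function(net, cases, idx, block_depth, max_cases = 5L) {
  idx <- idx[seq_len(min(max_cases, length(idx)))]
  vals <- vapply(idx, function(i) {
    x <- cases[[i]]$x
    d <- dim(x)
    s <- max(0L, (d[1] - block_depth) %/% 2L)
    bd <- min(block_depth, d[1])
    sl <- (s + 1):(s + bd)
    xb <- x[sl, , , drop = FALSE]
    if (bd < block_depth)
      xb <- xb[c(seq_len(bd), rep(bd, block_depth - bd)), , , drop = FALSE]
    out <- net_forward_full(net, array(xb, c(1L, dim(xb))), train = FALSE)$main
    pm <- pred_mask_from_probs(out[, seq_len(bd), , , drop = FALSE])
    tryCatch(dsc(confusion(pm, cases[[i]]$y[sl, , , drop = FALSE])),
             corovox_error_undefined_metric = function(e) 0)
  }, numeric(1))
  mean(vals)
}

#' Train a segmentation network
#'
#' Optimises the deep-supervision Dice objective with Adam under the
#' configured piecewise learning-rate and alpha schedules. Each epoch visits
#' every training case once, drawing one (foreground-biased) random crop per
#' case; validation mean DSC is computed after every epoch with sliding-block
#' inference, and the best-validation parameters are kept.
#'
#' @param cfg A [train_config()].
#' @param stop_after Optionally stop after this many epochs (the schedules
#'   are still those of the full configured run).
#' @param quiet Suppress the per-epoch progress line.
#' @param cases Optional pre-resolved case list (as returned by the internal
#'   resolver) to avoid regenerating phantoms when several runs share the
#'   same data seed.
#' @return An object of class `corovox_run`: list with `net` (best-validation
#'   network), `final_net`, `log` (one row per epoch: epoch, lr, alpha,
#'   train_loss, val_dsc), `cfg` and `split_idx`. A non-finite training loss
#'   aborts with a `corovox_error_divergence` condition.
#' @export
train <- function(cfg, stop_after = NULL, quiet = TRUE, cases = NULL) {
  stopifnot(inherits(cfg, "train_config"))
  if (is.null(cases)) cases <- resolve_cases(cfg)
  sp <- split_cases(length(cases), cfg$split, cfg$seed)
  sched <- cfg$schedule
  net <- build_network(cfg$network, seed = cx_subseed(cfg$seed, 13L))
  opt <- adam_new(net$params)
  n_epochs <- if (is.null(stop_after)) sched$epochs else min(stop_after, sched$epochs)
  log <- data.frame()
  best <- list(dsc = -Inf, params = net$params)

  for (epoch in seq_len(n_epochs)) {
    lr <- lr_at_epoch(epoch, sched)
    al <- alpha_at_epoch(epoch, sched)
    set.seed(cx_subseed(cfg$seed, 100L + epoch))
    order_idx <- sp$train[sample.int(length(sp$train))]
    tot_loss <- 0; nseen <- 0L
    bs <- sched$batch_size
    for (b0 in seq(1L, length(order_idx), by = bs)) {
      batch <- order_idx[b0:min(b0 + bs - 1L, length(order_idx))]
      gsum <- NULL
      for (ci in batch) {
        cs <- cases[[ci]]
        cr <- if (is.null(cfg$crop)) {
          pl <- plan_blocks(dim(cs$x)[1], cfg$block_depth, cfg$block_depth)
          s <- pl$starts[sample.int(length(pl$starts), 1L)]
          bl <- extract_blocks(cs$x, pl)
          ml <- extract_blocks(cs$y, pl)
          k <- which(pl$starts == s)[1]
          list(x = bl[[k]], y = ml[[k]])
        } else sample_crop(cs$x, cs$y, as.integer(cfg$crop), cfg$fg_crop_prob)
        xb <- array(cr$x, c(1L, dim(cr$x)))
        st <- net_train_step(net, xb, cr$y, al)
        if (!is.finite(st$total))
          cx_stop("divergence", sprintf("non-finite loss at epoch %d", epoch))
        tot_loss <- tot_loss + st$total; nseen <- nseen + 1L
        gsum <- if (is.null(gsum)) st$grads
                else tree_map2(`+`, gsum, st$grads)
      }
      gavg <- tree_map2(function(a, b) a / length(batch), gsum, gsum)
      stepr <- adam_step(net$params, gavg, opt, lr, sched$weight_decay)
      net$params <- stepr$params
      opt <- stepr$state
    }
    vd <- val_dsc_of(net, cases, sp$val, cfg$block_depth)
    log <- rbind(log, data.frame(epoch = epoch, lr = lr, alpha = al,
                                 train_loss = tot_loss / nseen, val_dsc = vd))
    if (vd >= best$dsc) best <- list(dsc = vd, params = net$params)
    if (!quiet)
      message(sprintf("epoch %3d  lr %.1e  alpha %.4f  loss %.4f  val DSC %.4f",
                      epoch, lr, al, tot_loss / nseen, vd))
  }
  best_net <- net; best_net$params <- best$params
  structure(list(net = best_net, final_net = net, log = log, cfg = cfg,
                 split_idx = sp), class = "corovox_run")
}

#' Predict a mask for a volume
#'
#' Applies HU windowing, plans half-overlapping fixed-depth blocks, runs the
#' network on each block, averages the stitched class probabilities and
#' thresholds the foreground channel (ties resolve to background).
#'
#' @param net A [build_network()] result or trained run's `net`.
#' @param vol A [ct_volume] (windowed internally), [normalized_volume] or
#'   plain array already in `[0, 1]`.
#' @param block_depth,stride Sliding-block parameters (defaults 16 / 8).
#' @param window HU window used when `vol` holds raw HU values.
#' @return A [label_mask] of the input shape.
#' @export
predict_volume <- function(net, vol, block_depth = 16L, stride = 8L,
                           window = c(-260, 760)) {
  stopifnot(inherits(net, "corovox_net"))
  nv <- if (inherits(vol, "normalized_volume") ||
            (is.array(vol) && max(vol) <= 1 && min(vol) >= 0)) vol
        else window_and_normalize(vol, window[1], window[2])
  xarr <- vox(nv)
  probs <- infer_probs(net, xarr, block_depth, stride)
  m <- pred_mask_from_probs(probs)
  label_mask(m,
             spacing = if (is.list(vol) && !is.null(vol$spacing)) vol$spacing else c(0.45, 0.35, 0.35),
             header = if (is.list(vol)) vol$header else NULL)
}

#' Evaluate a trained run on its held-out test cases
#'
#' @param run A [train()] result.
#' @param which Case subset: `"test"` (default), `"val"` or `"train"`.
#' @return A data frame with one row per case (dsc, recall, precision, assd,
#'   hd) plus a final `mean` row.
#' @export
evaluate_run <- function(run, which = c("test", "val", "train")) {
  which <- match.arg(which)
  cases <- resolve_cases(run$cfg)
  idx <- run$split_idx[[which]]
  rows <- lapply(idx, function(i) {
    probs <- infer_probs(run$net, cases[[i]]$x, run$cfg$block_depth, run$cfg$stride)
    pm <- pred_mask_from_probs(probs)
    r <- evaluate_case(pm, cases[[i]]$y)
    data.frame(case = i, dsc = r$dsc, recall = r$recall, precision = r$precision,
               assd = r$assd, hd = r$hd)
  })
  df <- do.call(rbind, rows)
  means <- colMeans(df[, -1], na.rm = TRUE)
  rbind(df, data.frame(case = NA, t(means)))
}

#' Train and compare ablation variants
#'
#' Trains each named variant with the identical seed and data, evaluates the
#' held-out test cases, and tabulates the five metrics plus parameter
#' counts.
#'
#' @param variants Character vector of [make_variant()] names.
#' @param cfg A [train_config()] whose network settings (base channels,
#'   deep supervision, ...) are shared by all variants.
#' @param ... Passed to [train()] (e.g. `stop_after`).
#' @return Data frame with columns variant, params, dsc, recall, precision,
#'   assd, hd.
#' @export
run_ablation <- function(variants, cfg, ...) {
  rows <- lapply(variants, function(vn) {
    cfg_v <- cfg
    cfg_v$network <- make_variant(vn,
      base_channels = cfg$network$base_channels,
      deep_supervision = cfg$network$deep_supervision,
      lct_k = cfg$network$lct_k, lct_groups = cfg$network$lct_groups)
    run <- train(cfg_v, ...)
    ev <- evaluate_run(run)
    m <- ev[nrow(ev), ]
    data.frame(variant = vn, params = count_params(run$net),
               dsc = m$dsc, recall = m$recall, precision = m$precision,
               assd = m$assd, hd = m$hd)
  })
  do.call(rbind, rows)
}

#' Save / load a network checkpoint
#'
#' Checkpoints are R serialisations holding the parameter tree and the
#' architecture configuration as plain metadata.
#'
#' @param net A `corovox_net`.
#' @param path Destination file.
#' @return `save_checkpoint` invisibly returns `path`; `load_checkpoint`
#'   returns the restored `corovox_net`.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "corovox_net"))
  saveRDS(list(config = unclass(net$config), params = net$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) cx_stop("missing_file", paste0("no such file: ", path))
  obj <- readRDS(path)
  cfgl <- obj$config
  structure(list(config = structure(cfgl, class = "network_config"),
                 params = obj$params), class = "corovox_net")
}
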