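#' Specification of a synthetic vascular phantom
#'
#' Parameterises a seeded generator of CCTA-like volumes with ground-truth
#' tubular tree masks. The defaults emulate the difficulties of coronary
#' segmentation: a small bright foreground (well under 5% of voxels), a
#' branching tree whose radius shrinks at every bifurcation, contrast that
#' falls off towards the distal tips, an unlabeled bright distractor tube
#' (vein/aorta-like) of similar intensity, and additive Gaussian noise.
#'
#' @param seed Integer master seed; identical specs give bit-identical cases.
#'   The seed drives three independent sub-streams (tree topology, distractor
#'   placement, noise), so toggling noise does not change the geometry.
#' @param shape Integer `(depth, height, width)`, each >= 8.
#' @param n_trees Number of independent trees (default 2: left/right
#'   coronary-style).
#' @param max_bifurcations Generations of branching below the root
#'   (default 3).
#' @param root_radius Root tube radius in voxels (default 2.2).
#' @param radius_decay Child/parent radius ratio in `(0, 1)` (default 0.75),
#'   giving sub-voxel distal branches after a few generations.
#' @param segment_length Length range (voxels) of one segment between
#'   bifurcations (default `c(8, 16)`).
#' @param branch_angle_sd SD (radians) of the angular perturbation applied to
#'   child directions (default 0.4).
#' @param vessel_hu Peak vessel intensity in HU at the tree root
#'   (default 350, a typical contrast-filled lumen).
#' @param distal_contrast_drop Fractional intensity loss at the most distal
#'   tip, linear in arc length (default 0.4).
#' @param background_hu Background intensity (default 40, soft-tissue-like).
#' @param distractor Add an unlabeled bright tube (default `TRUE`).
#' @param distractor_hu Distractor intensity (default 300, deliberately close
#'   to the vessel range).
#' @param distractor_radius Distractor tube radius in voxels (default 4,
#'   aorta/vein-like, thicker than the tree).
#' @param noise_sd SD of additive zero-mean Gaussian noise in HU
#'   (default 20).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, shape = c(32L, 64L, 64L), n_trees = 2L,
                         max_bifurcations = 3L, root_radius = 2.2,
                         radius_decay = 0.75, segment_length = c(8, 16),
                         branch_angle_sd = 0.4, vessel_hu = 350,
                         distal_contrast_drop = 0.4, background_hu = 40,
                         distractor = TRUE, distractor_hu = 300,
                         distractor_radius = 4, noise_sd = 20) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    cx_stop("bad_spec", "shape must be three integers >= 8")
  if (root_radius <= 0 || distractor_radius <= 0)
    cx_stop("bad_spec", "radii must be positive")
  if (radius_decay <= 0 || radius_decay >= 1)
    cx_stop("bad_spec", "radius_decay must be in (0, 1)")
  if (n_trees < 1L) cx_stop("bad_spec", "n_trees must be >= 1")
  if (distal_contrast_drop < 0 || distal_contrast_drop > 1)
    cx_stop("bad_spec", "distal_contrast_drop must be in [0, 1]")
  structure(list(seed = as.integer(seed), shape = shape,
                 n_trees = as.integer(n_trees),
                 max_bifurcations = as.integer(max_bifurcations),
                 root_radius = root_radius, radius_decay = radius_decay,
                 segment_length = as.numeric(segment_length),
                 branch_angle_sd = branch_angle_sd, vessel_hu = vessel_hu,
                 distal_contrast_drop = distal_contrast_drop,
                 background_hu = background_hu, distractor = isTRUE(distractor),
                 distractor_hu = distractor_hu,
                 distractor_radius = distractor_radius, noise_sd = noise_sd),
            class = "phantom_spec")
}

unit3 <- function(v) v / sqrt(sum(v * v))

# A unit vector perpendicular to d, rotated by a random angle phi about d.
rand_perp <- function(d, phi) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- unit3(pracma_cross(d, ref))
  p2 <- pracma_cross(d, p1)
  unit3(cos(phi) * p1 + sin(phi) * p2)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Sample a bifurcating centerline tree
#'
#' Grows `n_trees` recursive binary trees of polyline segments. Each child
#' segment's radius is the parent radius times `radius_decay`; child
#' directions are the parent direction tilted to either side by an angle
#' drawn around `branch_angle_sd`; segments take unit-length steps with
#' small directional jitter and stop at the volume boundary. Deterministic
#' given the spec (topology sub-stream of the seed).
#'
#' @param spec A [phantom_spec].
#' @return A list of segments, each a list with `points` (n x 3 matrix of
#'   0-based continuous voxel coordinates), `radius` (per-point, constant
#'   within a segment), `arc` (per-point arc length from the tree root) and
#'   `tree` (tree id). The attribute `max_arc` holds the per-tree maximum arc
#'   length used to normalise contrast falloff.
#' @export
sample_tree <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(cx_subseed(spec$seed, 1L))
  sh <- spec$shape
  margin <- spec$root_radius + 1.5
  segs <- list()

  grow <- function(p0, dir, radius, gen, arc0, tree_id) {
    len <- runif(1, spec$segment_length[1], spec$segment_length[2])
    n <- max(2L, ceiling(len))
    pts <- matrix(0, n, 3)
    arcs <- numeric(n)
    pts[1, ] <- p0; arcs[1] <- arc0
    d <- dir
    for (i in 2:n) {
      d <- unit3(d + rnorm(3, 0, spec$branch_angle_sd * 0.15))
      cand <- pts[i - 1, ] + d
      low <- c(0, 0, 0) + (radius + 0.5)
      hi <- sh - 1 - (radius + 0.5)
      cand <- pmin(pmax(cand, low), hi)
      if (all(cand == pts[i - 1, ])) { n <- i - 1L; break }
      pts[i, ] <- cand
      arcs[i] <- arcs[i - 1] + sqrt(sum((cand - pts[i - 1, ])^2))
    }
    pts <- pts[seq_len(n), , drop = FALSE]
    arcs <- arcs[seq_len(n)]
    segs[[length(segs) + 1L]] <<- list(points = pts,
                                       radius = rep(radius, n),
                                       arc = arcs, tree = tree_id, gen = gen)
    if (gen < spec$max_bifurcations && n >= 2L) {
      tip <- pts[n, ]
      d_end <- unit3(pts[n, ] - pts[max(1, n - 1), ])
      for (s in c(-1, 1)) {
        ang <- abs(rnorm(1, spec$branch_angle_sd, spec$branch_angle_sd / 2))
        perp <- rand_perp(d_end, runif(1, 0, 2 * pi))
        child_dir <- unit3(d_end + s * tan(ang) * perp)
        grow(tip, child_dir, radius * spec$radius_decay, gen + 1L, arcs[n], tree_id)
      }
    }
  }

  for (t in seq_len(spec$n_trees)) {
    p0 <- c(runif(1, margin, sh[1] - 1 - margin),
            runif(1, margin, sh[2] - 1 - margin),
            runif(1, margin, sh[3] - 1 - margin))
    dir <- unit3(rnorm(3))
    grow(p0, dir, spec$root_radius, 0L, 0, t)
  }
  max_arc <- vapply(seq_len(spec$n_trees), function(t) {
    max(unlist(lapply(segs, function(s) if (s$tree == t) max(s$arc) else 0)))
  }, numeric(1))
  attr(segs, "max_arc") <- pmax(max_arc, 1e-9)
  segs
}

# Mark all voxels whose center lies within `radius` of a centerline sample
# point; record the (normalised-later) arc length of the closest-to-root
# sample touching each voxel. Samples are spaced 0.25 voxels along each
# polyline so the swept-sphere union tracks the tube surface closely, and a
# 6-connected voxel walk along the centerline guarantees connectivity even
# for sub-voxel radii.
rasterize_tree <- function(tree, shape) {
  mask <- array(0L, shape)
  arcm <- array(Inf, shape)
  mark_sphere <- function(p, r, arc) {
    lo <- pmax(ceiling(p - r), 0)
    hi <- pmin(floor(p + r), shape - 1)
    if (any(lo > hi)) {
      v <- round(p)
      if (all(v >= 0 & v <= shape - 1)) {
        i <- cbind(v[1] + 1, v[2] + 1, v[3] + 1)
        mask[i] <<- 1L
        arcm[i] <<- pmin(arcm[i], arc)
        return(invisible())
      }
      return(invisible())
    }
    zs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; xs <- lo[3]:hi[3]
    g <- expand.grid(z = zs, y = ys, x = xs)
    d2 <- (g$z - p[1])^2 + (g$y - p[2])^2 + (g$x - p[3])^2
    keep <- d2 <= r * r
    if (any(keep)) {
      idx <- cbind(g$z[keep] + 1, g$y[keep] + 1, g$x[keep] + 1)
      mask[idx] <<- 1L
      arcm[idx] <<- pmin(arcm[idx], arc)
    }
    invisible()
  }
  walk6 <- function(a, b, r_arc) {
    # 6-connected integer walk from voxel a to voxel b, marking every voxel
    cur <- a
    mark1 <- function(v) {
      if (all(v >= 0 & v <= shape - 1)) {
        i <- cbind(v[1] + 1, v[2] + 1, v[3] + 1)
        mask[i] <<- 1L
        arcm[i] <<- pmin(arcm[i], r_arc)
      }
    }
    mark1(cur)
    for (ax in 1:3) {
      while (cur[ax] != b[ax]) {
        cur[ax] <- cur[ax] + sign(b[ax] - cur[ax])
        mark1(cur)
      }
    }
  }
  for (seg in tree) {
    pts <- seg$points
    n <- nrow(pts)
    prev_vox <- round(pts[1, ])
    for (i in seq_len(n - 1)) {
      a <- pts[i, ]; b <- pts[i + 1, ]
      seg_len <- sqrt(sum((b - a)^2))
      nsub <- max(1L, ceiling(seg_len / 0.25))
      for (s in 0:nsub) {
        f <- s / nsub
        p <- a + f * (b - a)
        r <- seg$radius[i] + f * (seg$radius[i + 1] - seg$radius[i])
        arc <- seg$arc[i] + f * (seg$arc[i + 1] - seg$arc[i])
        mark_sphere(p, r, arc)
      }
      v <- round(b)
      walk6(prev_vox, v, seg$arc[i + 1])
      prev_vox <- v
    }
    if (n == 1L) mark_sphere(pts[1, ], seg$radius[1], seg$arc[1])
  }
  list(mask = mask, arc = arcm)
}

#' Rasterize a centerline tree into a binary mask
#'
#' The mask is the union of spheres of the local radius swept densely along
#' every centerline segment (a voxel is foreground when its center lies
#' within the local radius), plus a 6-connected voxel walk along each
#' centerline that keeps sub-voxel distal branches connected.
#'
#' @param tree A [sample_tree()] result (may be empty).
#' @param shape Integer `(depth, height, width)`.
#' @return A [label_mask]; the attribute `arc` carries each foreground
#'   voxel's arc length from its tree root (used for contrast falloff).
#' @export
rasterize_mask <- function(tree, shape) {
  shape <- as.integer(shape)
  if (length(tree) == 0) {
    m <- label_mask(array(0L, shape))
    attr(m, "arc") <- array(Inf, shape)
    return(m)
  }
  r <- rasterize_tree(tree, shape)
  m <- label_mask(r$mask)
  attr(m, "arc") <- r$arc
  m
}

# Straight distractor tube: axis point + direction, voxels within radius.
distractor_voxels <- function(p0, dir, radius, shape) {
  g <- expand.grid(z = 0:(shape[1] - 1), y = 0:(shape[2] - 1), x = 0:(shape[3] - 1))
  rel <- cbind(g$z - p0[1], g$y - p0[2], g$x - p0[3])
  t_par <- rel %*% dir
  d2 <- rowSums(rel^2) - t_par^2
  which(d2 <= radius^2)
}

#' Render a phantom volume from a tree and its mask
#'
#' Labeled vessel voxels receive `vessel_hu` linearly attenuated towards the
#' distal tips (`vessel_hu * (1 - distal_contrast_drop * arc_norm)`, with
#' `arc_norm` the voxel's arc length from its tree root normalised by the
#' tree's maximum). If enabled, a straight distractor tube of similar
#' intensity is rendered but *not* added to the mask; its placement is
#' rejection-sampled so it never overlaps the labeled tree. Zero-mean
#' Gaussian noise (seeded noise sub-stream) is added last.
#'
#' @param spec A [phantom_spec].
#' @param tree The [sample_tree()] output for `spec`.
#' @param mask The [rasterize_mask()] output for `tree`.
#' @return A [ct_volume] in HU.
#' @export
render_volume <- function(spec, tree, mask) {
  sh <- spec$shape
  vol <- array(spec$background_hu, sh)
  arcm <- attr(mask, "arc")
  max_arc <- attr(tree, "max_arc")
  mv <- vox(mask)
  fg <- which(mv == 1L)
  if (length(fg)) {
    norm_arc <- pmin(arcm[fg] / max(max_arc), 1)
    vol[fg] <- spec$vessel_hu * (1 - spec$distal_contrast_drop * norm_arc)
  }
  if (spec$distractor) {
    set.seed(cx_subseed(spec$seed, 2L))
    placed <- FALSE
    for (try in 1:25) {
      p0 <- c(runif(1, 0, sh[1] - 1), runif(1, 0, sh[2] - 1), runif(1, 0, sh[3] - 1))
      dir <- unit3(c(rnorm(1, 1, 0.15), rnorm(1, 0, 0.2), rnorm(1, 0, 0.2)))
      idx <- distractor_voxels(p0, dir, spec$distractor_radius, sh)
      if (length(idx) && !any(mv[idx] == 1L)) { placed <- TRUE; break }
    }
    if (placed) vol[idx] <- spec$distractor_hu
  }
  if (spec$noise_sd > 0) {
    set.seed(cx_subseed(spec$seed, 3L))
    vol <- vol + rnorm(length(vol), 0, spec$noise_sd)
    dim(vol) <- sh
  }
  ct_volume(vol)
}

#' Generate one synthetic case
#'
#' Composes [sample_tree()], [rasterize_mask()] and [render_volume()]; a pure
#' function of the spec. Optionally writes the pair as NIfTI.
#'
#' @param spec A [phantom_spec].
#' @param dir Optional directory; when given, writes `volume.nii.gz` and
#'   `mask.nii.gz` there.
#' @return List with elements `volume` ([ct_volume]) and `mask`
#'   ([label_mask]).
#' @export
generate_case <- function(spec, dir = NULL) {
  tree <- sample_tree(spec)
  mask <- rasterize_mask(tree, spec$shape)
  vol <- render_volume(spec, tree, mask)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_volume(vol, file.path(dir, "volume.nii.gz"))
    write_volume(mask, file.path(dir, "mask.nii.gz"))
  }
  list(volume = vol, mask = mask)
}
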