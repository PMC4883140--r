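# Synthetic tubular phantoms: sparse bright neurite-like tubes on a dark
# background, with branch points, signal gaps, optional intensity
# inhomogeneity and additive Gaussian noise, plus ground-truth centerline SWC.

# run expr with a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Specify a synthetic neuron phantom
#'
#' Describes a tubular phantom: a set of branch polylines (ground-truth
#' centerlines), tube radius and intensity per branch, signal gaps, optional
#' per-axis intensity ramp, and additive Gaussian noise. Branch control
#' points are in SWC convention: 0-based `(x, y, z)` voxel coordinates, one
#' matrix row per control point. Branches after the first must start at a
#' point lying on an earlier branch (that is where they attach in the
#' ground-truth tree).
#'
#' @param shape integer length-3 volume dimensions `(z, y, x)`.
#' @param branches list of numeric matrices (n >= 2 rows, 3 columns `x,y,z`).
#' @param tube_radius tube radius in voxels; scalar or one value per branch.
#' @param foreground_intensity centerline intensity; scalar or per branch.
#' @param background_intensity background level.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param gaps list of `list(branch =, start_frac =, length =)`: on the given
#'   branch, intensities from arc-length fraction `start_frac` over `length`
#'   voxels are set to the background level.
#' @param dim_sections list of `list(branch =, start_frac =, end_frac =,
#'   intensity =)`: arc-length intervals whose tube intensity is replaced by
#'   the given centerline intensity (for simulating faded/attenuated signal).
#' @param intensity_gradient optional length-3 `(z, y, x)` multiplicative
#'   ramp amplitudes applied to the signal above background (a value g means
#'   the factor runs from 1 - g/2 to 1 + g/2 along that axis).
#' @param brightfield if `TRUE` the tube is darker than the background
#'   (requires `foreground_intensity < background_intensity`).
#' @param bits image bit depth (8 or 16).
#' @param seed RNG seed for the noise; identical specs and seeds give
#'   bit-identical volumes.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, branches, tube_radius = 2,
                         foreground_intensity = 200,
                         background_intensity = 10,
                         noise_sigma = 0, gaps = list(),
                         dim_sections = list(),
                         intensity_gradient = NULL, brightfield = FALSE,
                         bits = 8L, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (!length(branches)) stop("at least one branch polyline is required")
  branches <- lapply(branches, function(b) {
    b <- matrix(as.numeric(b), ncol = 3)
    if (nrow(b) < 2) stop("each branch needs at least 2 control points")
    b
  })
  nb <- length(branches)
  rad <- rep_len(as.numeric(tube_radius), nb)
  fg <- rep_len(as.numeric(foreground_intensity), nb)
  bg <- as.numeric(background_intensity)
  if (!brightfield && any(fg <= bg))
    stop("foreground_intensity must exceed background_intensity")
  if (brightfield && any(fg >= bg))
    stop("brightfield phantoms need foreground darker than background")
  # tubes (including the 1-voxel falloff band) must fit inside the volume
  lims <- shape[c(3, 2, 1)] - 1  # (x, y, z) upper coordinate bounds
  for (i in seq_len(nb)) {
    b <- branches[[i]]
    margin <- rad[i] + 1
    if (any(b < margin) ||
        any(b > matrix(lims - margin, nrow(b), 3, byrow = TRUE)))
      stop("branch ", i, " tube extends out of bounds")
  }
  for (g in gaps) {
    stopifnot(all(c("branch", "start_frac", "length") %in% names(g)))
    len <- polyline_length(branches[[g$branch]])
    if (g$length >= len) stop("gap length must be shorter than its branch")
    if (g$start_frac < 0 || g$start_frac > 1) stop("start_frac outside [0,1]")
  }
  for (ds in dim_sections) {
    stopifnot(all(c("branch", "start_frac", "end_frac", "intensity") %in%
                    names(ds)))
    if (ds$start_frac >= ds$end_frac) stop("empty dim section")
  }
  if (!is.null(intensity_gradient)) {
    stopifnot(length(intensity_gradient) == 3)
  }
  structure(list(shape = shape, branches = branches, tube_radius = rad,
                 foreground_intensity = fg, background_intensity = bg,
                 noise_sigma = as.numeric(noise_sigma), gaps = gaps,
                 dim_sections = dim_sections,
                 intensity_gradient = intensity_gradient,
                 brightfield = brightfield, bits = as.integer(bits),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                    pts[-nrow(pts), , drop = FALSE])^2)))
}

# subdivide a polyline so consecutive points are at most `step` apart;
# control points are preserved exactly
densify_polyline <- function(pts, step = 1) {
  out <- pts[1, , drop = FALSE]
  for (s in seq_len(nrow(pts) - 1)) {
    a <- pts[s, ]; b <- pts[s + 1, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / step))
    tt <- seq_len(nseg) / nseg
    out <- rbind(out, outer(tt, b - a) + matrix(a, nseg, 3, byrow = TRUE))
  }
  out
}

#' Render a phantom volume and its ground-truth reconstruction
#'
#' Voxels within the tube radius of a branch centerline receive that branch's
#' foreground intensity, with a 1-voxel linear falloff band outside the
#' radius; listed gaps are carved back to the background level; the optional
#' intensity ramp and clipped additive Gaussian noise are applied last. The
#' ground-truth tree samples each centerline at <= 1 voxel spacing, so its
#' total length equals the analytic polyline length.
#'
#' @param spec a [phantom_spec].
#' @return `list(image = image3d, tree = neuron_tree)`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$shape
  n <- prod(dims)
  bg <- spec$background_intensity
  delta <- numeric(n)  # signed signal above/below background
  pick <- if (spec$brightfield) pmin else pmax
  for (i in seq_along(spec$branches)) {
    r <- spec$tube_radius[i]
    pts <- swc_to_zyx(spec$branches[[i]])
    db <- cpp_polyline_dist(rep(Inf, n), dims, pts, r + 1.5)
    cov <- pmin(1, pmax(0, r + 1 - db))
    delta <- pick(delta, (spec$foreground_intensity[i] - bg) * cov)
  }
  for (ds in spec$dim_sections) {
    r <- spec$tube_radius[ds$branch]
    pts <- swc_to_zyx(spec$branches[[ds$branch]])
    len <- polyline_length(spec$branches[[ds$branch]])
    da <- cpp_polyline_dist_arc(dims, pts, r + 2)
    hit <- !is.na(da$arc) & da$dist <= r + 2 &
      da$arc >= ds$start_frac * len & da$arc <= ds$end_frac * len
    cov <- pmin(1, pmax(0, r + 1 - da$dist[hit]))
    delta[hit] <- (ds$intensity - bg) * cov
  }
  for (g in spec$gaps) {
    r <- spec$tube_radius[g$branch]
    pts <- swc_to_zyx(spec$branches[[g$branch]])
    s0 <- g$start_frac * polyline_length(spec$branches[[g$branch]])
    da <- cpp_polyline_dist_arc(dims, pts, r + 2)
    hit <- !is.na(da$arc) & da$dist <= r + 2 &
      da$arc >= s0 & da$arc <= s0 + g$length
    delta[hit] <- 0
  }
  if (!is.null(spec$intensity_gradient)) {
    g <- spec$intensity_gradient
    ramp_axis <- function(nv, amp) {
      if (nv == 1) return(1)
      1 + amp * (seq_len(nv) - 1) / (nv - 1) - amp / 2
    }
    ramp <- outer(outer(ramp_axis(dims[1], g[1]), ramp_axis(dims[2], g[2])),
                  ramp_axis(dims[3], g[3]))
    delta <- delta * as.vector(ramp)
  }
  val <- bg + delta
  mx <- if (spec$bits == 8L) 255 else 65535
  if (spec$noise_sigma > 0) {
    val <- with_seed(spec$seed, val + stats::rnorm(n, 0, spec$noise_sigma))
    val <- round(val)
  }
  val <- pmin(pmax(val, 0), mx)
  img <- image3d(array(val, dim = dims), bits = spec$bits)
  list(image = img, tree = phantom_ground_truth(spec))
}

# ground-truth centerline tree from the branch polylines
phantom_ground_truth <- function(spec) {
  nodes <- NULL
  next_id <- 1L
  for (i in seq_along(spec$branches)) {
    pts <- densify_polyline(spec$branches[[i]], step = 1)
    r <- spec$tube_radius[i]
    if (i == 1L) {
      ids <- seq_len(nrow(pts))
      nodes <- data.frame(id = ids, type = c(1L, rep(3L, nrow(pts) - 1)),
                          x = pts[, 1], y = pts[, 2], z = pts[, 3],
                          radius = r, parent = c(-1L, ids[-length(ids)]))
      next_id <- nrow(pts) + 1L
    } else {
      d2 <- (nodes$x - pts[1, 1])^2 + (nodes$y - pts[1, 2])^2 +
        (nodes$z - pts[1, 3])^2
      attach_row <- which.min(d2)
      if (d2[attach_row] <= 4) {
        # attaches to an earlier branch
        pts <- pts[-1, , drop = FALSE]
        parent0 <- nodes$id[attach_row]
        type0 <- 3L
      } else {
        # detached branch: its own root (the ground truth is a forest)
        parent0 <- -1L
        type0 <- 1L
      }
      ids <- next_id + seq_len(nrow(pts)) - 1L
      nodes <- rbind(nodes, data.frame(
        id = ids, type = c(type0, rep(3L, length(ids) - 1L)),
        x = pts[, 1], y = pts[, 2], z = pts[, 3],
        radius = r,
        parent = c(if (parent0 == -1L) -1L else parent0,
                   ids[-length(ids)])))
      next_id <- max(ids) + 1L
    }
  }
  neuron_tree(nodes, comments = "# synthetic phantom ground truth")
}

#' Phantom with a closed bright loop
#'
#' Renders a circular tube (a closed loop) lying in a single z-plane and
#' returns a ground-truth tree covering only half of the loop. Because the
#' other half is equally bright, the traced half has a genuine alternative
#' path, making this the canonical fixture for confidence scores near 1.
#'
#' @param shape volume dimensions `(z, y, x)`.
#' @param loop_radius circle radius in voxels (> 0).
#' @param tube_radius,foreground_intensity,background_intensity,noise_sigma,bits,seed
#'   as in [phantom_spec()].
#' @return `list(image = image3d, tree = neuron_tree)`; the tree covers the
#'   half-loop at angles 0..pi.
#' @export
make_loop_phantom <- function(shape, loop_radius, tube_radius = 2,
                              foreground_intensity = 200,
                              background_intensity = 10, noise_sigma = 0,
                              bits = 8L, seed = 1L) {
  shape <- as.integer(shape)
  if (loop_radius <= 0) stop("loop_radius must be positive")
  z0 <- (shape[1] - 1) / 2
  cy <- (shape[2] - 1) / 2
  cx <- (shape[3] - 1) / 2
  nang <- max(16L, ceiling(2 * pi * loop_radius))
  ang <- seq(0, 2 * pi, length.out = nang + 1)
  circle <- cbind(cx + loop_radius * cos(ang),  # (x, y, z) SWC convention
                  cy + loop_radius * sin(ang), rep(z0, nang + 1))
  half <- circle[ang <= pi + 1e-9, , drop = FALSE]
  spec <- phantom_spec(shape, branches = list(circle),
                       tube_radius = tube_radius,
                       foreground_intensity = foreground_intensity,
                       background_intensity = background_intensity,
                       noise_sigma = noise_sigma, bits = bits, seed = seed)
  ph <- generate_phantom(spec)
  half_spec <- spec
  half_spec$branches <- list(half)
  list(image = ph$image, tree = phantom_ground_truth(half_spec))
}
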