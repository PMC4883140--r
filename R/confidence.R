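# Segment confidence scoring: mask a traced segment, search for the best
# intensity-weighted alternative path between its endpoints, and compare
# mean intensities. A score near 1 means a genuine alternative pathway
# exists (the segment is uncertain); a score much below 1 means the segment
# is the only bright route (confident).

# node cost for intensity-weighted path search: bright voxels are cheap.
# c(x) = (1 - I(x)/I_max)^2 + eps; edge cost = mean endpoint cost * step.
path_node_cost <- function(img, eps = 1e-6) {
  mx <- max(img$data)
  if (mx <= 0) stop("image maximum intensity must be positive")
  (1 - img$data / mx)^2 + eps
}

#' Mask the image along a traced segment
#'
#' Sets to zero every voxel within the masking tube around the segment
#' centerline, except inside protection spheres around the two endpoints
#' (the endpoints must stay reachable for the alternative-path search).
#' The input image is not modified. The tube radius follows the SWC node
#' radii: `max(median node radius, 1) + 1` voxels.
#'
#' @param img an [image3d].
#' @param seg a segment from [decompose_segments()].
#' @param tree the [neuron_tree] the segment belongs to.
#' @param protect_radius radius of the endpoint protection spheres (voxels);
#'   the default, one voxel more than the masking tube radius, keeps a free
#'   corridor around each endpoint so the alternative-path search can leave.
#' @return a masked copy of `img`.
#' @export
mask_segment <- function(img, seg, tree, protect_radius = NULL) {
  stopifnot(inherits(img, "image3d"))
  out <- img
  out$data[segment_mask_voxels(img, seg, tree, protect_radius)] <- 0
  out
}

# logical array marking the masking tube (minus endpoint protection spheres)
segment_mask_voxels <- function(img, seg, tree, protect_radius = NULL) {
  dims <- dim(img$data)
  pts <- segment_zyx(tree, seg)
  oob <- pts < 1 | pts > matrix(dims, nrow(pts), 3, byrow = TRUE)
  if (any(oob)) {
    warning("segment nodes outside the image were clipped")
    pts <- pmin(pmax(pts, 1), matrix(dims, nrow(pts), 3, byrow = TRUE))
  }
  rows <- tree_node_row(tree, seg$nodes)
  tube_r <- max(stats::median(tree$nodes$radius[rows]), 1) + 1
  if (is.null(protect_radius)) protect_radius <- tube_r + 1
  dist_seg <- cpp_polyline_dist(rep(Inf, prod(dims)), dims, pts, tube_r)
  in_tube <- dist_seg <= tube_r
  for (endp in list(pts[1, ], pts[nrow(pts), ])) {
    dist_end <- cpp_polyline_dist(rep(Inf, prod(dims)), dims,
                                  matrix(endp, 1, 3), protect_radius)
    in_tube <- in_tube & !(dist_end <= protect_radius)
  }
  array(in_tube, dim = dims)
}

#' Best intensity-weighted path between two voxels
#'
#' Dijkstra search over the voxel grid (26-connected by default) with node
#' cost `(1 - I/I_max)^2 + eps` and edge cost equal to the mean of the two
#' endpoint node costs times the Euclidean step length. With `eps > 0` every
#' voxel is traversable, so a path always exists. Distance ties are broken
#' by linear voxel index, making the result deterministic.
#'
#' @param img an [image3d] (typically the masked image). `i_max`, when given,
#'   fixes the normalizing maximum (use the unmasked image's maximum so that
#'   masking does not rescale costs).
#' @param from,to 1-based `(z, y, x)` voxel coordinates.
#' @param connectivity 6 or 26.
#' @param eps positive floor of the node cost.
#' @param i_max optional intensity normalizer.
#' @param blocked optional logical array (or vector) of voxels excluded from
#'   the search, e.g. the masked segment tube from the confidence scorer.
#' @return list with `path` (m x 3 matrix of 1-based `(z,y,x)` voxels from
#'   `from` to `to`) and `cost` (total path cost).
#' @export
alternative_path <- function(img, from, to, connectivity = 26, eps = 1e-6,
                             i_max = NULL, blocked = NULL) {
  dims <- dim(img$data)
  from <- round(as.numeric(from)); to <- round(as.numeric(to))
  if (all(from == to)) stop("`from` and `to` must differ")
  if (any(from < 1) || any(from > dims) || any(to < 1) || any(to > dims))
    stop("endpoints out of bounds")
  mx <- if (is.null(i_max)) max(img$data) else i_max
  if (mx <= 0) stop("image maximum intensity must be positive")
  cost <- (1 - img$data / mx)^2 + eps
  src <- vox_index(dims, matrix(from, 1)) - 1
  dst <- vox_index(dims, matrix(to, 1)) - 1
  allowed <- logical(0)
  if (!is.null(blocked)) {
    allowed <- !as.vector(blocked)
    if (!allowed[src + 1] || !allowed[dst + 1])
      stop("an endpoint lies in the blocked set")
  }
  res <- cpp_grid_dijkstra(as.integer(dims), as.vector(cost), src, dst,
                           allowed, as.integer(connectivity))
  if (!is.finite(res$dist[dst + 1])) stop("target voxel unreachable")
  # backtrack parents
  path_idx <- dst
  while (path_idx[1] != src) {
    p <- res$parent[path_idx[1] + 1]
    if (p < 0) stop("broken parent chain")  # cannot happen when dst reached
    path_idx <- c(p, path_idx)
  }
  list(path = vox_coords(dims, path_idx + 1), cost = res$dist[dst + 1])
}

#' Arc-length-weighted mean intensity along a path
#'
#' Discretizes the line integral of intensity over a polyline as the
#' trapezoidal rule with Euclidean step weights:
#' `sum((I_k + I_{k+1})/2 * ds_k) / sum(ds_k)`. Intensities at fractional
#' coordinates are trilinearly interpolated.
#'
#' @param img an [image3d] (use the original, unmasked image for scoring).
#' @param path m x 3 matrix of 1-based `(z, y, x)` points, m >= 2.
#' @return the mean intensity (scalar).
#' @export
mean_path_intensity <- function(img, path) {
  path <- matrix(as.numeric(path), ncol = 3)
  if (nrow(path) < 2) stop("path needs at least 2 points")
  steps <- sqrt(rowSums((path[-1, , drop = FALSE] -
                         path[-nrow(path), , drop = FALSE])^2))
  if (sum(steps) == 0) stop("zero-length path")
  ii <- interp_intensity(img, path)
  mid <- (ii[-1] + ii[-length(ii)]) / 2
  sum(mid * steps) / sum(steps)
}

#' Score every segment's reliability
#'
#' For each segment `L_ij` of the reconstruction: mask the image along the
#' segment (endpoints protected), search for the best alternative path
#' `L*_ij` between the endpoints, and score
#' `C_ij = mean intensity along L*_ij / mean intensity along L_ij`, both
#' means taken in the original image. `C_ij <= threshold` labels the segment
#' confident (no bright alternative route exists, so the tracing is likely
#' real signal); otherwise uncertain. Segments too short to score (fewer
#' than `min_nodes` nodes or shorter than `min_length` voxels) inherit the
#' label of their parent segment (confident when they have none).
#'
#' For brightfield images (background brighter than foreground) set
#' `invert = TRUE`: scoring then runs on the intensity-inverted image
#' `I_max - I`, which keeps the cost function's bright-is-cheap semantics.
#'
#' @param img an [image3d].
#' @param tree a [neuron_tree] traced on `img`.
#' @param threshold confidence threshold on the score (default 0.5).
#' @param invert brightfield flag.
#' @param connectivity path-search connectivity (6 or 26).
#' @param min_nodes,min_length below these a segment inherits its parent's
#'   label instead of being scored.
#' @return a list of class `confidence_report`: `segments` (the
#'   decomposition), `table` (data.frame with segment id, `mean_intensity`,
#'   `alt_mean_intensity`, `score`, `label`, `scored`), `threshold_used`,
#'   `inverted`.
#' @export
score_segments <- function(img, tree, threshold = 0.5, invert = FALSE,
                           connectivity = 26, min_nodes = 3, min_length = 5) {
  stopifnot(inherits(img, "image3d"), inherits(tree, "neuron_tree"))
  work <- img
  if (invert) work$data <- max(img$data) - img$data
  i_max <- max(work$data)
  segs <- decompose_segments(tree)
  n <- length(segs)
  mean_i <- alt_i <- score <- rep(NA_real_, n)
  label <- character(n)
  scored <- logical(n)
  for (k in seq_len(n)) {
    seg <- segs[[k]]
    too_short <- length(seg$nodes) < min_nodes ||
      segment_length(tree, seg) < min_length
    if (too_short) next
    pts <- densify_path(segment_zyx(tree, seg), step = 1)
    tube <- segment_mask_voxels(work, seg, tree)
    masked <- work
    masked$data[tube] <- 0
    ends <- segment_zyx(tree, seg)
    ap <- tryCatch(
      alternative_path(masked, ends[1, ], ends[nrow(ends), ],
                       connectivity = connectivity, i_max = i_max,
                       blocked = tube),
      error = function(e) NULL)
    mean_i[k] <- mean_path_intensity(work, pts)
    scored[k] <- TRUE
    if (is.null(ap)) {
      # exclusion disconnected the endpoints: no alternative route exists
      alt_i[k] <- 0
      score[k] <- 0
      label[k] <- "confident"
      next
    }
    alt_i[k] <- mean_path_intensity(work, ap$path)
    if (mean_i[k] <= 0) {
      warning("segment ", k, " has zero mean intensity; labeled uncertain")
      score[k] <- Inf
      label[k] <- "uncertain"
    } else {
      score[k] <- alt_i[k] / mean_i[k]
      label[k] <- if (score[k] <= threshold) "confident" else "uncertain"
    }
  }
  # short segments inherit their parent's label (confident at the root)
  for (k in seq_len(n)) {
    if (scored[k]) next
    p <- segs[[k]]$parent_segment
    visited <- integer(0)
    while (!is.na(p) && !scored[p] && !(p %in% visited)) {
      visited <- c(visited, p)
      p <- segs[[p]]$parent_segment
    }
    label[k] <- if (!is.na(p) && nzchar(label[p])) label[p] else "confident"
  }
  structure(list(
    segments = segs,
    table = data.frame(segment = seq_len(n), mean_intensity = mean_i,
                       alt_mean_intensity = alt_i, score = score,
                       label = label, scored = scored),
    threshold_used = threshold, inverted = invert),
    class = "confidence_report")
}

#' @export
print.confidence_report <- function(x, ...) {
  cat(sprintf("<confidence_report> %d segment(s), %d confident, threshold %g%s\n",
              nrow(x$table), sum(x$table$label == "confident"),
              x$threshold_used, if (x$inverted) " (brightfield)" else ""))
  invisible(x)
}

# densify a point path to at most `step` spacing (generic matrix version)
densify_path <- function(pts, step = 1) {
  densify_polyline(pts, step = step)
}

#' Per-node confidence scores for SWC coloring
#'
#' Expands a segment-level confidence report to one score per tree node so
#' the reconstruction can be written with [write_swc()]'s score sidecar.
#'
#' @param report a `confidence_report`.
#' @param tree the scored [neuron_tree].
#' @return named numeric vector (names are node ids).
#' @export
node_scores <- function(report, tree) {
  out <- rep(NA_real_, nrow(tree$nodes))
  names(out) <- as.character(tree$nodes$id)
  for (k in seq_along(report$segments)) {
    seg <- report$segments[[k]]
    s <- report$table$score[k]
    if (is.na(s)) s <- if (report$table$label[k] == "confident") 0 else 1
    out[as.character(seg$nodes)] <- s
  }
  out[is.na(out)] <- 0
  out
}
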