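# Turn confident segments into a 4-class voxel label volume and draw
# balanced foreground/background training samples from it.

#' Label codes of the exemplar volume
#'
#' Integer codes used in the label array: `IRRELEVANT = 0`,
#' `FOREGROUND_SAMPLE = 1`, `BACKGROUND_SAMPLE = 2`, `UNCERTAIN = 3`.
#' @export
label_codes <- function() {
  c(IRRELEVANT = 0L, FOREGROUND_SAMPLE = 1L, BACKGROUND_SAMPLE = 2L,
    UNCERTAIN = 3L)
}

# insufficient-exemplars condition, caught by the pipeline
insufficient_exemplars <- function(msg) {
  stop(structure(class = c("insufficient_exemplars", "error", "condition"),
                 list(message = paste0(
                   msg, " (insufficient training exemplars; lower the ",
                   "confidence threshold or supply a different initial ",
                   "tracing)"), call = NULL)))
}

#' Build the 4-class exemplar label volume
#'
#' Around confident-segment centerlines, three concentric layers are laid
#' out by exact distance to the centerline polylines: the core layer
#' (distance <= `layer_radii[1]`) gives foreground samples, the middle
#' annulus (`(layer_radii[1], layer_radii[2]]`) is uncertain, and the outer
#' annulus (`(layer_radii[2], layer_radii[3]]`) gives background samples.
#' The full dilated neighbourhood (radius `layer_radii[3]`) of uncertain
#' segments is also marked uncertain; that override beats background labels
#' but never the foreground core of a confident segment. Everything else is
#' irrelevant, as are voxels within `border_margin` voxels of the volume
#' border (their feature windows would spill over the edge).
#'
#' @param img an [image3d] (defines the domain).
#' @param report a `confidence_report` from [score_segments()].
#' @param tree the reconstruction the report refers to.
#' @param layer_radii `(core, middle, outer)` radii in voxels. Default:
#'   `core = max(median SWC radius, 1)`, `middle = core + 2`,
#'   `outer = middle + 3`.
#' @param border_margin demotion margin at the volume border (default 8,
#'   half the 16-voxel feature window).
#' @return list of class `label_volume`: `labels` (integer 3D array of
#'   [label_codes()]), `layer_radii`, `counts`.
#' @export
build_label_volume <- function(img, report, tree, layer_radii = NULL,
                               border_margin = 8) {
  stopifnot(inherits(img, "image3d"), inherits(report, "confidence_report"))
  dims <- dim(img$data)
  if (is.null(layer_radii)) {
    core <- max(stats::median(tree$nodes$radius), 1)
    layer_radii <- c(core, core + 2, core + 5)
  }
  stopifnot(length(layer_radii) == 3, all(diff(layer_radii) > 0))
  segs <- report$segments
  lab <- report$table$label
  if (!any(lab == "confident"))
    insufficient_exemplars("no confident segments")
  n <- prod(dims)
  dist_conf <- rep(Inf, n)
  dist_unc <- rep(Inf, n)
  for (k in seq_along(segs)) {
    pts <- segment_zyx(tree, segs[[k]])
    pts <- pmin(pmax(pts, 1), matrix(dims, nrow(pts), 3, byrow = TRUE))
    if (lab[k] == "confident") {
      dist_conf <- cpp_polyline_dist(dist_conf, dims, pts, layer_radii[3] + 1)
    } else {
      dist_unc <- cpp_polyline_dist(dist_unc, dims, pts, layer_radii[3] + 1)
    }
  }
  code <- label_codes()
  labels <- rep(code[["IRRELEVANT"]], n)
  labels[dist_conf <= layer_radii[3]] <- code[["BACKGROUND_SAMPLE"]]
  labels[dist_conf <= layer_radii[2]] <- code[["UNCERTAIN"]]
  labels[dist_conf <= layer_radii[1]] <- code[["FOREGROUND_SAMPLE"]]
  # uncertain-segment dilation: overrides background, never confident core
  unc_zone <- dist_unc <= layer_radii[3] &
    labels != code[["FOREGROUND_SAMPLE"]]
  labels[unc_zone] <- code[["UNCERTAIN"]]
  labels <- array(as.integer(labels), dim = dims)
  if (border_margin > 0) {
    bm <- as.integer(border_margin)
    sl <- function(nv) unique(c(seq_len(min(bm, nv)),
                                seq(max(1L, nv - bm + 1L), nv)))
    labels[sl(dims[1]), , ] <- code[["IRRELEVANT"]]
    labels[, sl(dims[2]), ] <- code[["IRRELEVANT"]]
    labels[, , sl(dims[3])] <- code[["IRRELEVANT"]]
  }
  counts <- table(factor(labels, levels = code,
                         labels = names(code)))
  if (counts[["FOREGROUND_SAMPLE"]] == 0)
    insufficient_exemplars("no foreground sample voxels")
  structure(list(labels = labels, layer_radii = layer_radii,
                 counts = counts),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> radii (", paste(x$layer_radii, collapse = ", "),
      "); counts:\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Draw balanced training samples
#'
#' Draws `min(max_per_class, available in the smaller class)` voxels
#' uniformly without replacement from the foreground-sample and
#' background-sample pools, the same number from each, so the classifier
#' sees balanced classes.
#'
#' @param lv a `label_volume`.
#' @param max_per_class cap on samples per class.
#' @param seed RNG seed; identical seeds give identical draws.
#' @return list with `foreground` and `background`, each an m x 3 matrix of
#'   1-based `(z, y, x)` voxel coordinates.
#' @export
draw_training_samples <- function(lv, max_per_class = 500, seed = 1L) {
  stopifnot(inherits(lv, "label_volume"))
  code <- label_codes()
  dims <- dim(lv$labels)
  fg_idx <- which(lv$labels == code[["FOREGROUND_SAMPLE"]])
  bg_idx <- which(lv$labels == code[["BACKGROUND_SAMPLE"]])
  if (length(fg_idx) == 0 || length(bg_idx) == 0)
    insufficient_exemplars("an exemplar class is empty")
  m <- min(max_per_class, length(fg_idx), length(bg_idx))
  with_seed(seed, {
    fg <- sort(sample(fg_idx, m))
    bg <- sort(sample(bg_idx, m))
  })
  list(foreground = vox_coords(dims, fg), background = vox_coords(dims, bg))
}
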