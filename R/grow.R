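# Classifier-gated foreground growth and the image adjustment applied
# before re-tracing.

#' Grow the predicted foreground from seed voxels
#'
#' Fast-marching foreground prediction: seed voxels are pre-labeled
#' foreground; the front then marches to adjacent unknown voxels
#' (26-connected by default), classifying each exactly once. Voxels accepted
#' as foreground join the front; growth stops when no new foreground voxel
#' can be reached, and every never-reached voxel is background. Expansion is
#' breadth-first; because acceptance depends only on the classifier, the
#' final mask is independent of expansion order.
#'
#' @param img an [image3d].
#' @param seeds m x 3 matrix of 1-based `(z, y, x)` seed voxels.
#' @param clf an `st_classifier`, or a function mapping a feature matrix to
#'   a logical vector (useful for stubbing).
#' @param feature_fn function mapping an m x 3 matrix of voxel coordinates
#'   to an m x d feature matrix matching the classifier's dimension.
#' @param connectivity 26 (default) or 6.
#' @param batch number of frontier voxels classified per call.
#' @return list of class `foreground_mask`: `mask` (logical 3D array),
#'   `seeds`, and visit statistics `examined`, `accepted`, `rejected`.
#' @export
grow_foreground <- function(img, seeds, clf, feature_fn, connectivity = 26,
                            batch = 4096) {
  stopifnot(inherits(img, "image3d"))
  dims <- dim(img$data)
  seeds <- matrix(round(as.numeric(seeds)), ncol = 3)
  if (nrow(seeds) == 0) stop("seeds must be non-empty")
  classify <- if (is.function(clf)) clf else function(f) predict(clf, f)

  offsets <- neighbour_offsets(connectivity)
  mask <- array(FALSE, dim = dims)
  visited <- array(FALSE, dim = dims)  # classified or seeded
  seed_idx <- unique(vox_index(dims, seeds))
  mask[seed_idx] <- TRUE
  visited[seed_idx] <- TRUE
  examined <- 0L; accepted <- 0L
  frontier <- seed_idx
  while (length(frontier)) {
    nb <- neighbour_indices(dims, frontier, offsets)
    nb <- unique(nb[!visited[nb]])
    if (!length(nb)) break
    nb <- sort(nb)
    visited[nb] <- TRUE
    newly <- integer(0)
    for (start in seq(1, length(nb), by = batch)) {
      chunk <- nb[start:min(start + batch - 1L, length(nb))]
      fz <- feature_fn(vox_coords(dims, chunk))
      keep <- classify(fz)
      examined <- examined + length(chunk)
      acc <- chunk[keep]
      accepted <- accepted + length(acc)
      mask[acc] <- TRUE
      newly <- c(newly, acc)
    }
    frontier <- newly
  }
  structure(list(mask = mask, seeds = seeds, examined = examined,
                 accepted = accepted, rejected = examined - accepted),
            class = "foreground_mask")
}

#' @export
print.foreground_mask <- function(x, ...) {
  cat(sprintf(
    "<foreground_mask> %d foreground voxels (%d seeds; examined %d, accepted %d)\n",
    sum(x$mask), nrow(x$seeds), x$examined, x$accepted))
  invisible(x)
}

neighbour_offsets <- function(connectivity) {
  stopifnot(connectivity %in% c(6, 26))
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  if (connectivity == 6) g <- g[abs(g$dz) + abs(g$dy) + abs(g$dx) == 1, ]
  as.matrix(g)
}

# all in-bounds neighbour linear indices of `idx` (may contain duplicates)
neighbour_indices <- function(dims, idx, offsets) {
  co <- vox_coords(dims, idx)
  out <- vector("list", nrow(offsets))
  for (k in seq_len(nrow(offsets))) {
    nz <- co[, 1] + offsets[k, 1]
    ny <- co[, 2] + offsets[k, 2]
    nx <- co[, 3] + offsets[k, 3]
    ok <- nz >= 1 & nz <= dims[1] & ny >= 1 & ny <= dims[2] &
      nx >= 1 & nx <= dims[3]
    out[[k]] <- vox_index(dims, cbind(nz[ok], ny[ok], nx[ok]))
  }
  unlist(out, use.names = FALSE)
}

#' Remap the image for the final tracing pass
#'
#' Background voxels (outside the mask) are set to 0. Foreground voxels
#' below the tracing threshold are raised to the threshold; brighter
#' foreground voxels are kept unchanged. The re-run tracer, with its
#' background threshold at the same value, then sees exactly the predicted
#' foreground.
#'
#' @param img an [image3d].
#' @param mask a `foreground_mask` (or logical array of matching shape).
#' @param trace_threshold the tracing threshold (default 1).
#' @return the adjusted [image3d] (same bit depth).
#' @export
adjust_image <- function(img, mask, trace_threshold = 1) {
  stopifnot(inherits(img, "image3d"))
  m <- if (inherits(mask, "foreground_mask")) mask$mask else mask
  if (!identical(dim(m), dim(img$data))) stop("mask shape mismatch")
  if (trace_threshold > img_max_value(img))
    stop("trace_threshold exceeds the image dtype range")
  out <- img
  out$data <- ifelse(m, pmax(img$data, trace_threshold), 0)
  dim(out$data) <- dim(img$data)
  out
}
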