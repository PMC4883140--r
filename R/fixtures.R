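# Canonical study fixtures: the phantom geometries used to validate the
# confidence score and the end-to-end gap-filling behaviour. Shared by the
# test suite and the acceptance script so both exercise identical
# conditions.

#' Canonical validation phantoms
#'
#' Construct the benchmark phantoms used to validate the pipeline:
#'
#' * `fixture_isolated_tube()` — one bright tube on dark background; its
#'   single segment has no alternative route, so the confidence score must
#'   be far below 1.
#' * `fixture_parallel_tubes()` — two identical parallel tubes; the tracing
#'   covers one of them, and the other provides a near-equal alternative
#'   path, so the score must be close to 1.
#' * `fixture_gap_phantom()` — a seeded 96 x 128 x 128 neuron (main neurite
#'   plus one side branch) with a hard signal gap placed so that over a
#'   third of the total length lies beyond it; the baseline tracer stops at
#'   the gap and the learned foreground prediction must recover the rest.
#' * `fixture_gapfree_phantom()` — the same neuron without the gap, as a
#'   stability control (no spurious growth expected).
#' * `fixture_wide_gap_phantom()` — a single long neurite whose middle
#'   section fades (centerline 90 instead of 200), followed by a very faint
#'   stretch (35) acting as a wide gap before a bright distal part, with a
#'   small hard gap stopping the initial trace early. One learning round
#'   recovers only the faded middle; the second round, trained on exemplars
#'   that now flank the faint stretch, crosses it.
#'
#' Each returns `list(image, tree, soma_seed, spec)` where `soma_seed` is
#' the 1-based `(z, y, x)` root voxel for tracing and `tree` is the
#' ground-truth centerline reconstruction.
#'
#' @param noise_sigma Gaussian noise level (default 5 for the end-to-end
#'   phantoms, 0 for the score fixtures).
#' @param seed RNG seed for the noise.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
fixture_isolated_tube <- function(noise_sigma = 0, seed = 1L) {
  spec <- phantom_spec(c(24, 40, 112),
                       branches = list(rbind(c(10, 20, 12), c(100, 20, 12))),
                       tube_radius = 2, foreground_intensity = 200,
                       background_intensity = 10,
                       noise_sigma = noise_sigma, seed = seed)
  ph <- generate_phantom(spec)
  list(image = ph$image, tree = ph$tree, soma_seed = c(13, 21, 11),
       spec = spec)
}

#' @rdname fixtures
#' @export
fixture_parallel_tubes <- function(noise_sigma = 0, seed = 1L) {
  # tubes 6 voxels apart: outside the masking tube (radius 3) of the traced
  # one, close enough that hopping across costs only a few dark steps
  spec <- phantom_spec(c(24, 36, 176),
                       branches = list(rbind(c(10, 14, 12), c(165, 14, 12)),
                                       rbind(c(10, 20, 12), c(165, 20, 12))),
                       tube_radius = 2, foreground_intensity = 200,
                       background_intensity = 10,
                       noise_sigma = noise_sigma, seed = seed)
  ph <- generate_phantom(spec)
  # ground truth/tracing covers only the first tube
  spec1 <- spec
  spec1$branches <- spec$branches[1]
  spec1$tube_radius <- spec$tube_radius[1]
  spec1$foreground_intensity <- spec$foreground_intensity[1]
  list(image = ph$image, tree = phantom_ground_truth(spec1),
       soma_seed = c(13, 15, 11), spec = spec)
}

#' @rdname fixtures
#' @export
fixture_gap_phantom <- function(noise_sigma = 5, seed = 1L, gap = TRUE) {
  main <- rbind(c(10, 64, 48), c(118, 64, 48))
  side <- rbind(c(45, 64, 48), c(95, 98, 66))
  gaps <- if (gap) list(list(branch = 1, start_frac = 0.45, length = 5))
          else list()
  spec <- phantom_spec(c(96, 128, 128), branches = list(main, side),
                       tube_radius = 2.5, foreground_intensity = 200,
                       background_intensity = 10,
                       noise_sigma = noise_sigma, gaps = gaps, seed = seed)
  ph <- generate_phantom(spec)
  list(image = ph$image, tree = ph$tree, soma_seed = c(49, 65, 11),
       spec = spec)
}

#' @rdname fixtures
#' @export
fixture_gapfree_phantom <- function(noise_sigma = 5, seed = 1L) {
  fixture_gap_phantom(noise_sigma = noise_sigma, seed = seed, gap = FALSE)
}

#' @rdname fixtures
#' @export
fixture_wide_gap_phantom <- function(noise_sigma = 6, seed = 1L) {
  branch <- rbind(c(10, 32, 24), c(150, 32, 24))  # length 140
  spec <- phantom_spec(
    c(48, 64, 160), branches = list(branch),
    tube_radius = 2, foreground_intensity = 200, background_intensity = 10,
    noise_sigma = noise_sigma, seed = seed,
    gaps = list(list(branch = 1, start_frac = 52 / 140, length = 3)),
    dim_sections = list(
      list(branch = 1, start_frac = 55 / 140, end_frac = 85 / 140,
           intensity = 120),  # faded middle: recovered in round 1
      list(branch = 1, start_frac = 85 / 140, end_frac = 93 / 140,
           intensity = 60),   # short faint preview: narrower than the
                              # feature window, so round 1 creeps across it
      list(branch = 1, start_frac = 93 / 140, end_frac = 100 / 140,
           intensity = 120),
      list(branch = 1, start_frac = 100 / 140, end_frac = 120 / 140,
           intensity = 60)))  # wide faint gap: its middle is farther than a
                              # window half-side from any brighter signal, so
                              # only a classifier whose exemplars include
                              # faint patterns (round 2) can cross it
  ph <- generate_phantom(spec)
  list(image = ph$image, tree = ph$tree, soma_seed = c(25, 33, 11),
       spec = spec)
}

#' Length of a reconstruction lying near a reference centerline
#'
#' Sums the Euclidean edge lengths of `tree` whose two endpoint nodes both
#' lie within `tol` voxels of the reference tree's centerline polyline.
#' Used to check that a recovered reconstruction actually follows the
#' ground truth rather than inflating length elsewhere.
#'
#' @param tree the reconstruction to evaluate.
#' @param reference the ground-truth [neuron_tree].
#' @param tol centerline distance tolerance in voxels.
#' @return total on-centerline length (voxels).
#' @export
length_on_reference <- function(tree, reference, tol = 2) {
  nd <- tree$nodes
  if (nrow(nd) < 2) return(0)
  ref <- reference$nodes
  pr <- match(ref$parent, ref$id)
  # distance of every node to the reference edge set
  dmin <- rep(Inf, nrow(nd))
  for (e in which(!is.na(pr))) {
    a <- c(ref$x[pr[e]], ref$y[pr[e]], ref$z[pr[e]])
    b <- c(ref$x[e], ref$y[e], ref$z[e])
    v <- b - a
    vv <- sum(v^2)
    w <- cbind(nd$x - a[1], nd$y - a[2], nd$z - a[3])
    t <- if (vv > 0) pmin(pmax((w %*% v) / vv, 0), 1) else 0
    d <- sqrt(rowSums((w - outer(as.vector(t), v))^2))
    dmin <- pmin(dmin, d)
  }
  ok <- dmin <= tol
  prow <- match(nd$parent, nd$id)
  keep <- which(!is.na(prow) & ok & ok[prow])
  if (!length(keep)) return(0)
  sum(sqrt((nd$x[keep] - nd$x[prow[keep]])^2 +
           (nd$y[keep] - nd$y[prow[keep]])^2 +
           (nd$z[keep] - nd$z[prow[keep]])^2))
}
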