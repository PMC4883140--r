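# 3D multi-resolution wavelet features and minimum-redundancy
# maximum-relevance feature selection.

wavelet_filter <- function(wavelet = c("haar", "d4")) {
  wavelet <- match.arg(wavelet)
  if (wavelet == "haar") {
    c(1, 1) / sqrt(2)
  } else {
    # 4-tap Daubechies (2 vanishing moments), orthonormal
    c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  }
}

#' Extract a cubic window around a voxel
#'
#' Returns the `side`^3 cube of intensities around `center`. Along each axis
#' the window spans `center - side/2 + 1 .. center + side/2`, so the center
#' voxel sits at in-window position `side/2`. Out-of-bounds indices are
#' mirror-reflected with edge repetition (`..., 2, 1, 1, 2, ...`).
#'
#' @param img an [image3d].
#' @param center 1-based `(z, y, x)` voxel.
#' @param side window side, a power of two no larger than every image
#'   dimension... the default 16 matches the classifier's feature window.
#' @return numeric `side`^3 array.
#' @export
extract_window <- function(img, center, side = 16) {
  dims <- dim(img$data)
  if (all(side > dims))
    stop("window side exceeds every image dimension")
  if (bitwAnd(side, side - 1L) != 0L) stop("side must be a power of two")
  center <- round(as.numeric(center))
  mirror <- function(i, n) {
    i <- i - 1L
    while (any(i < 0 | i >= n)) {
      i <- ifelse(i < 0, -1L - i, i)
      i <- ifelse(i >= n, 2L * n - 1L - i, i)
    }
    i + 1L
  }
  off <- seq_len(side) - side / 2
  img$data[mirror(center[1] + off, dims[1]),
           mirror(center[2] + off, dims[2]),
           mirror(center[3] + off, dims[3]), drop = FALSE]
}

#' One level of separable 3D wavelet decomposition
#'
#' Applies the low/high orthonormal filter pair along z, then y, then x with
#' periodic (circular) boundary handling, producing the eight half-size
#' subbands LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH; the letters name the
#' filter applied along (z, y, x). Periodization keeps the total coefficient
#' count equal to the input voxel count, and the transform is orthonormal:
#' [idwt3_level()] reconstructs the input exactly (up to round-off) and
#' energy is conserved.
#'
#' @param cube 3D numeric array with even sides.
#' @param wavelet `"haar"` (default) or `"d4"` (4-tap Daubechies).
#' @return named list of 8 subband arrays.
#' @export
dwt3_level <- function(cube, wavelet = "haar") {
  d <- dim(cube)
  if (is.null(d) || length(d) != 3) stop("`cube` must be a 3D array")
  if (any(d %% 2 != 0)) stop("all sides must be even")
  cpp_dwt3(cube, wavelet_filter(wavelet))
}

#' Inverse of [dwt3_level()]
#' @param subbands named list of 8 subband arrays (order LLL..HHH).
#' @param wavelet filter used for the forward transform.
#' @return the reconstructed 3D array.
#' @export
idwt3_level <- function(subbands, wavelet = "haar") {
  cpp_idwt3(subbands, wavelet_filter(wavelet))
}

#' Multi-resolution wavelet feature vector of a cube
#'
#' Iterated 3D decomposition: at each level the seven detail subbands
#' (LLH, LHL, LHH, HLL, HLH, HHL, HHH, each flattened in column-major
#' order) are appended to the feature vector and the smooth LLL band is
#' decomposed again; the final LLL is appended last. The feature count
#' equals the cube's voxel count (e.g. 4096 for a 16-voxel window:
#' 7*512 + 7*64 + 7*8 + 8).
#'
#' @param cube cubic 3D array whose side is divisible by `2^levels`.
#' @param levels decomposition depth (default 3).
#' @param wavelet `"haar"` or `"d4"`.
#' @return numeric feature vector.
#' @export
mwr_features <- function(cube, levels = 3, wavelet = "haar") {
  d <- dim(cube)
  if (is.null(d) || length(d) != 3 || length(unique(d)) != 1)
    stop("`cube` must be a cubic 3D array")
  if (d[1] %% 2^levels != 0) stop("side not divisible by 2^levels")
  cpp_mwr(cube, as.integer(levels), wavelet_filter(wavelet))
}

# features for a batch of voxel centers directly from the image
mwr_feature_batch <- function(img, centers_zyx, side = 16, levels = 3,
                              wavelet = "haar", select = NULL) {
  centers0 <- matrix(as.integer(round(centers_zyx) - 1L), ncol = 3)
  sel0 <- if (is.null(select)) integer(0) else as.integer(select - 1L)
  cpp_mwr_batch(img$data, centers0, as.integer(side), as.integer(levels),
                wavelet_filter(wavelet), sel0)
}

#' Mutual information of two discrete vectors
#'
#' Plug-in estimate from the joint empirical distribution, in bits:
#' `I(a,b) = sum p(a,b) log2( p(a,b) / (p(a) p(b)) )`. Non-negative and
#' symmetric.
#'
#' @param a,b equal-length vectors of discrete values (integers, factors or
#'   anything coercible to factor levels).
#' @return mutual information in bits.
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) == 0) stop("empty vectors")
  ai <- as.integer(factor(a)); bi <- as.integer(factor(b))
  na <- max(ai); nb <- max(bi)
  joint <- tabulate((ai - 1L) * nb + bi, nbins = na * nb)
  n <- length(a)
  pj <- joint / n
  pa <- rowSums(matrix(pj, na, nb, byrow = TRUE))
  pb <- colSums(matrix(pj, na, nb, byrow = TRUE))
  pe <- as.vector(t(outer(pa, pb)))  # match joint's (a-major, b-fast) layout
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / pe[nz]))
}

# discretize continuous features into 3 states at mean +/- sd
# (population sd: with the n-1 divisor a balanced binary feature would land
# entirely inside the middle bin and lose all its information)
discretize_features <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd_ <- sqrt(colMeans(sweep(x, 2, mu)^2))
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  lo <- matrix(mu - sd_, nrow(x), ncol(x), byrow = TRUE)
  hi <- matrix(mu + sd_, nrow(x), ncol(x), byrow = TRUE)
  disc <- (x > lo) + (x > hi)
  list(states = disc, edges = cbind(lower = mu - sd_, upper = mu + sd_))
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy incremental selection: the first feature maximizes the mutual
#' information `I(c, f)` with the class vector; each subsequent feature
#' maximizes `I(c, f) - mean_{s in S} I(f, f_s)` over the already-selected
#' set `S` (the first-order difference scheme, whose per-step work is linear
#' in the number of remaining candidates). Continuous features are first
#' discretized into 3 states at mean +/- one standard deviation. Exact score
#' ties go to the lowest feature index, so runs are deterministic; constant
#' features have zero relevance and never win ties.
#'
#' @param features n x p numeric matrix (samples in rows).
#' @param labels length-n class vector (>= 2 classes).
#' @param k number of features to select.
#' @return list of class `mrmr_selection`: `selected` (ordered indices),
#'   `relevance` (per-feature `I(c, f)`), `step_scores` (the winning
#'   incremental score at each step), `edges` (discretization edges).
#' @export
mrmr_select <- function(features, labels, k = 20) {
  features <- as.matrix(features)
  p <- ncol(features)
  if (k > p) stop("k exceeds the feature dimension")
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  if (length(labels) != nrow(features)) stop("labels/features mismatch")
  disc <- discretize_features(features)
  st <- disc$states
  storage.mode(st) <- "integer"
  cl <- as.integer(factor(labels)) - 1L
  relevance <- cpp_mi_columns(cl, st, seq_len(p) - 1L)
  selected <- integer(0)
  step_scores <- numeric(0)
  red_sum <- numeric(p)  # sum over selected s of I(f_j, f_s)
  candidates <- rep(TRUE, p)
  for (step in seq_len(k)) {
    score <- if (length(selected) == 0) relevance else
      relevance - red_sum / length(selected)
    score[!candidates] <- -Inf
    best <- which.max(score)  # ties -> lowest index
    selected <- c(selected, best)
    step_scores <- c(step_scores, score[best])
    candidates[best] <- FALSE
    if (step < k) {
      upd <- which(candidates)
      red_sum[upd] <- red_sum[upd] +
        cpp_mi_columns(st[, best], st, upd - 1L)
    }
  }
  structure(list(selected = selected, relevance = relevance,
                 step_scores = step_scores, edges = disc$edges),
            class = "mrmr_selection")
}
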