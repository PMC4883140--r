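#' 3D intensity volume
#'
#' Container for a 3D scalar microscopy volume. Data are stored as a numeric
#' array indexed `(z, y, x)` (slice first), the layout produced by reading a
#' TIFF stack page by page. Intensities are non-negative integers on the
#' 8-bit or 16-bit scale; `spacing` records the per-axis voxel size and is
#' informational only (path costs and distances are computed in voxel units).
#'
#' @param data numeric 3D array in `(z, y, x)` order, or a 2D matrix which is
#'   treated as a single-slice volume.
#' @param bits bit depth, 8 or 16. Determines the dynamic range ceiling used
#'   for clipping and TIFF output.
#' @param spacing numeric length-3 voxel size `(z, y, x)`, default 1.
#' @return an object of class `image3d`.
#' @export
image3d <- function(data, bits = 8L, spacing = c(1, 1, 1)) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, dim(data)))
  if (length(dim(data)) != 3L) stop("`data` must be a 2D or 3D array")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (!bits %in% c(8L, 16L)) stop("`bits` must be 8 or 16")
  storage.mode(data) <- "double"
  if (any(data < 0)) stop("intensities must be non-negative")
  structure(
    list(data = data, bits = as.integer(bits), spacing = as.numeric(spacing)),
    class = "image3d"
  )
}

#' @export
print.image3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image3d> %d x %d x %d (z,y,x), %d-bit, range [%g, %g]\n",
              d[1], d[2], d[3], x$bits, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image3d <- function(x) dim(x$data)

img_max_value <- function(img) if (img$bits == 8L) 255 else 65535

#' Read a TIFF stack as a 3D volume
#'
#' Reads a grayscale multi-page TIFF into an [image3d]. A single-page 2D TIFF
#' becomes a one-slice volume of shape `(1, y, x)`. RGB or floating-point
#' input is rejected unless `convert = TRUE`, in which case channels are
#' averaged / values rescaled to the integer range.
#'
#' @param path path to a TIFF file.
#' @param convert allow lossy conversion of RGB/float input.
#' @return an [image3d].
#' @export
read_image <- function(path, convert = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  first <- pages[[1]]
  if (length(dim(first)) == 3L) {
    if (!convert) stop("RGB TIFF input requires `convert = TRUE`")
    pages <- lapply(pages, function(p) apply(p, c(1, 2), mean))
  }
  bps <- attr(first, "bits.per.sample")
  is_float <- is.double(pages[[1]]) || (!is.null(bps) && bps > 16)
  if (is_float && !convert)
    stop("floating-point TIFF input requires `convert = TRUE`")
  bits <- if (!is.null(bps) && bps > 8) 16L else 8L
  if (is_float) {
    # re-read normalized, then rescale onto the 16-bit integer range
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(dim(pages[[1]])) == 3L)
      pages <- lapply(pages, function(p) apply(p, c(1, 2), mean))
    bits <- 16L
    mx <- max(1e-12, max(unlist(lapply(pages, max))))
    pages <- lapply(pages, function(p) round(pmax(p, 0) / mx * 65535))
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(length(pages), ny, nx))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  image3d(arr, bits = bits)
}

#' Write a 3D volume as a multi-page TIFF stack
#'
#' @param img an [image3d].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "image3d"))
  mx <- img_max_value(img)
  if (any(img$data > mx))
    stop("intensities exceed the ", img$bits, "-bit range")
  slices <- lapply(seq_len(dim(img$data)[1]),
                   function(z) img$data[z, , ] / mx)
  ok <- tiff::writeTIFF(slices, path, bits.per.sample = img$bits,
                        compression = "none")
  if (!ok[1]) stop("failed to write ", path)
  invisible(path)
}

#' Dump a label volume as a raw debugging file
#'
#' Plain-text header (dims, one line) followed by the flat array, one value
#' per line. Intended for inspecting intermediate label volumes only.
#' @param arr integer 3D array.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raw_dump <- function(arr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(dim(arr), collapse = " "), con)
  writeLines(as.character(as.vector(arr)), con)
  invisible(path)
}

# linear (1-based) voxel index from 1-based (z,y,x) rows
vox_index <- function(dims, zyx) {
  zyx <- matrix(as.numeric(zyx), ncol = 3)
  as.integer((zyx[, 1]) + dims[1] * ((zyx[, 2] - 1) + dims[2] * (zyx[, 3] - 1)))
}

# inverse of vox_index: n x 3 matrix of 1-based (z,y,x)
vox_coords <- function(dims, idx) {
  idx0 <- idx - 1L
  z <- idx0 %% dims[1]
  y <- (idx0 %/% dims[1]) %% dims[2]
  x <- idx0 %/% (dims[1] * dims[2])
  cbind(z + 1L, y + 1L, x + 1L)
}

# SWC (x,y,z) 0-based coordinates -> 1-based (z,y,x) array coordinates
swc_to_zyx <- function(xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  cbind(xyz[, 3] + 1, xyz[, 2] + 1, xyz[, 1] + 1)
}

# 1-based (z,y,x) -> SWC 0-based (x,y,z)
zyx_to_swc <- function(zyx) {
  zyx <- matrix(as.numeric(zyx), ncol = 3)
  cbind(zyx[, 3] - 1, zyx[, 2] - 1, zyx[, 1] - 1)
}

# trilinear interpolation of img at fractional 1-based (z,y,x) points
interp_intensity <- function(img, zyx) {
  d <- dim(img$data)
  zyx <- matrix(as.numeric(zyx), ncol = 3)
  p <- pmin(pmax(zyx, 1), matrix(d, nrow(zyx), 3, byrow = TRUE))
  f <- pmin(floor(p), matrix(d - 1L, nrow(p), 3, byrow = TRUE))
  f <- pmax(f, 1)
  w <- p - f
  out <- numeric(nrow(p))
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    wt <- (if (bz) w[, 1] else 1 - w[, 1]) *
          (if (by) w[, 2] else 1 - w[, 2]) *
          (if (bx) w[, 3] else 1 - w[, 3])
    keep <- wt > 0
    if (any(keep)) {
      ii <- vox_index(d, cbind(f[keep, 1] + bz, f[keep, 2] + by,
                               f[keep, 3] + bx))
      out[keep] <- out[keep] + wt[keep] * img$data[ii]
    }
  }
  out
}
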