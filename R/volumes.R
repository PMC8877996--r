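#' Image volume and binary mask containers
#'
#' An `iris_volume` holds a 3D grid of scalar intensities together with the
#' voxel spacing; an `iris_mask` holds a congruent 3D logical grid. The axis
#' order is fixed as (slice, row, col) -- the first array index walks through
#' axial slices -- and all public coordinates are 1-based. Spacing is given in
#' mm per axis, in the same (slice, row, col) order.
#'
#' @param data 3D numeric array (volume) or array coercible to logical (mask).
#' @param spacing Numeric length-3 voxel size in mm, `(slice, row, col)`.
#' @return An object of class `iris_volume` or `iris_mask`: a list with
#'   elements `data` and `spacing`.
#' @examples
#' v <- image_volume(array(runif(8), c(2, 2, 2)), spacing = c(8, 1.5, 1.5))
#' m <- binary_mask(array(c(TRUE, FALSE), c(2, 2, 2)), spacing = c(8, 1.5, 1.5))
#' @export
image_volume <- function(data, spacing = c(1, 1, 1)) {
  data <- check_grid(data, "volume")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = check_spacing(spacing)),
            class = "iris_volume")
}

#' @rdname image_volume
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1)) {
  data <- check_grid(data, "mask")
  if (!is.logical(data)) {
    if (any(!data %in% c(0, 1)))
      iris_abort("mask data must be logical or 0/1", "irisseg_value_error")
    data <- array(as.logical(data), dim(data))
  }
  structure(list(data = data, spacing = check_spacing(spacing)),
            class = "iris_mask")
}

check_grid <- function(data, what) {
  if (!is.array(data) || length(dim(data)) != 3)
    iris_abort(sprintf("%s data must be a 3D array, got %s dimension(s)",
                       what, paste(length(dim(data)), collapse = "")),
               "irisseg_dim_error")
  if (any(dim(data) < 1))
    iris_abort(sprintf("%s dimensions must all be >= 1", what),
               "irisseg_dim_error")
  data
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    iris_abort("spacing must be 3 positive finite numbers (mm)",
               "irisseg_value_error")
  spacing
}

#' @export
print.iris_volume <- function(x, ...) {
  cat(sprintf("<iris_volume> %s voxels (slice x row x col), spacing %s mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.iris_mask <- function(x, ...) {
  cat(sprintf("<iris_mask> %s voxels, spacing %s mm, %d foreground (%.2f mL)\n",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing), collapse = " x "),
              sum(x$data), volume_ml(x)))
  invisible(x)
}

# Shape + spacing congruence used throughout the pipeline.
check_congruent <- function(a, b, what = "inputs") {
  if (!identical(dim(a$data), dim(b$data)))
    iris_abort(sprintf("%s have mismatched shapes (%s vs %s)", what,
                       paste(dim(a$data), collapse = "x"),
                       paste(dim(b$data), collapse = "x")),
               "irisseg_dim_error")
  if (!isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-6)))
    iris_abort(sprintf("%s have mismatched spacing", what),
               "irisseg_value_error")
  invisible(TRUE)
}

#' Read a 3D NIfTI file as a volume or mask
#'
#' Reads a NIfTI-1 file (`.nii` or `.nii.gz`) into the package's
#' (slice, row, col) convention: the NIfTI z axis becomes the slice axis.
#' Intensities are passed through unmodified; spacing comes from the header
#' `pixdim`. `read_mask()` additionally requires the voxel values to be 0/1
#' and returns an `iris_mask`.
#'
#' @param path Path to a readable NIfTI-1 file containing a 3D image.
#' @return An [image_volume()] (or [binary_mask()] for `read_mask`).
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!is.character(path) || length(path) != 1)
    iris_abort("path must be a single file path", "irisseg_usage_error")
  if (!file.exists(path))
    iris_abort(sprintf("file not found: %s", path), "irisseg_io_error")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) iris_abort(
                    sprintf("unreadable NIfTI file %s: %s", path,
                            conditionMessage(e)),
                    "irisseg_io_error"))
  d <- dim(img)
  if (length(d) != 3)
    iris_abort(sprintf("%s is %dD; a 3D image is required", path, length(d)),
               "irisseg_dim_error")
  arr <- aperm(array(as.numeric(img), d), c(3, 2, 1))
  sp <- rev(RNifti::pixdim(img)[seq_len(3)])
  image_volume(arr, spacing = sp)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  if (any(!v$data %in% c(0, 1)))
    iris_abort(sprintf("%s contains values other than 0/1; not a mask", path),
               "irisseg_value_error")
  binary_mask(v$data != 0, spacing = v$spacing)
}

#' Write a volume or mask to NIfTI
#'
#' Masks are written as unsigned 8-bit 0/1 for interoperability with common
#' viewers; volumes as 64-bit float so intensities round-trip exactly through
#' [read_volume()].
#'
#' @param x An [image_volume()] or [binary_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (!inherits(x, c("iris_volume", "iris_mask")))
    iris_abort("x must be an iris_volume or iris_mask", "irisseg_usage_error")
  is_mask <- inherits(x, "iris_mask")
  arr <- aperm(if (is_mask) array(as.integer(x$data), dim(x$data)) else x$data,
               c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(x$spacing)
  ok <- tryCatch({
    RNifti::writeNifti(img, path,
                       datatype = if (is_mask) "uint8" else "double")
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path))
    iris_abort(sprintf("cannot write NIfTI file: %s", path),
               "irisseg_io_error")
  invisible(path)
}

#' Min-max intensity normalization
#'
#' Linearly rescales intensities to `[0, 1]`:
#' `(x - min) / (max - min)`. The map is monotone (order-preserving) and
#' idempotent on already-normalized input. If `roi` is supplied, the min and
#' max are computed over the ROI voxels only and the rescaled volume is
#' clipped to `[0, 1]` outside that range.
#'
#' A constant-intensity volume (max == min) is degenerate: the result is all
#' zeros and a warning is emitted, so a flat slice does not abort a pipeline.
#'
#' @param volume An [image_volume()].
#' @param roi Optional [binary_mask()] restricting where min/max are taken.
#' @return A normalized [image_volume()].
#' @export
normalize_minmax <- function(volume, roi = NULL) {
  if (!inherits(volume, "iris_volume"))
    iris_abort("volume must be an iris_volume", "irisseg_usage_error")
  vals <- volume$data
  if (!is.null(roi)) {
    if (!inherits(roi, "iris_mask"))
      iris_abort("roi must be an iris_mask", "irisseg_usage_error")
    check_congruent(volume, roi, "volume and roi")
    if (!any(roi$data))
      iris_abort("roi is empty; cannot normalize over it",
                 "irisseg_value_error")
    vals <- volume$data[roi$data]
  }
  lo <- min(vals); hi <- max(vals)
  if (hi == lo) {
    iris_warn("constant-intensity volume: normalization returns all zeros",
              "irisseg_degenerate_warning")
    return(image_volume(array(0, dim(volume$data)), volume$spacing))
  }
  out <- (volume$data - lo) / (hi - lo)
  if (!is.null(roi)) out <- pmin(pmax(out, 0), 1)
  image_volume(array(out, dim(volume$data)), volume$spacing)
}

#' Foreground volume of a mask in milliliters
#'
#' `count(TRUE) * voxel volume (mm^3) / 1000`. Additive over disjoint masks.
#'
#' @param mask An [binary_mask()].
#' @return Volume in mL.
#' @export
volume_ml <- function(mask) {
  if (!inherits(mask, "iris_mask"))
    iris_abort("mask must be an iris_mask", "irisseg_usage_error")
  sum(mask$data) * prod(mask$spacing) / 1000
}
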