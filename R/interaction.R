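#' Affinity region-growth parameters
#'
#' Configuration of the single-click editing engine. Growth from a clicked
#' seed accepts a frontier voxel `g` adjacent to an accepted voxel `s` when
#' the intensity affinity `rho = 1 - |I_g - I_s| / a` is at least
#' `threshold`; growth stops when no frontier voxel reaches the threshold
#' (equivalently, when the affinity falls under it).
#'
#' @param sensitivity_a Adjustable sensitivity `a > 0`, in normalized
#'   intensity units. Larger `a` tolerates larger intensity steps.
#' @param threshold Acceptance threshold on the affinity, in `(0, 1]`;
#'   the boundary case `rho == threshold` is accepted.
#' @param connectivity In-plane neighborhood: 4 (edge neighbors) or
#'   8 (edge + diagonal). 4 is the conservative default, so growth does not
#'   jump diagonal gaps between neighboring cysts.
#' @param scope `"2d"` restricts growth to the clicked axial slice;
#'   `"3d"` also grows across adjacent slices (face neighbors).
#' @param comparison_mode `"chain"` compares each candidate to the accepted
#'   neighbor it grows from (iterative growth); `"seed"` compares every
#'   candidate to the originally clicked voxel.
#' @param closing_radius In-plane disk radius (voxels, `>= 0`) of the
#'   morphological closing applied to a grown region to fill interior holes;
#'   `0` disables closing.
#' @return An `affinity_config` list.
#' @export
affinity_config <- function(sensitivity_a = 0.2, threshold = 0.5,
                            connectivity = 4L, scope = c("2d", "3d"),
                            comparison_mode = c("chain", "seed"),
                            closing_radius = 1L) {
  if (!is.numeric(sensitivity_a) || length(sensitivity_a) != 1 ||
      sensitivity_a <= 0)
    iris_abort("sensitivity_a must be a single number > 0",
               "irisseg_value_error")
  if (threshold <= 0 || threshold > 1)
    iris_abort("threshold must be in (0, 1]", "irisseg_value_error")
  if (!connectivity %in% c(4, 8))
    iris_abort("connectivity must be 4 or 8", "irisseg_value_error")
  scope <- match.arg(scope)
  comparison_mode <- match.arg(comparison_mode)
  if (closing_radius < 0)
    iris_abort("closing_radius must be >= 0", "irisseg_value_error")
  structure(list(sensitivity_a = sensitivity_a, threshold = threshold,
                 connectivity = as.integer(connectivity), scope = scope,
                 comparison_mode = comparison_mode,
                 closing_radius = closing_radius),
            class = "affinity_config")
}

#' Intensity affinity between two voxels
#'
#' `rho = 1 - |I_g - I_s| / a`: 1 for identical intensities, 0 when the
#' difference equals the sensitivity `a`, and negative beyond. Vectorized.
#'
#' @param intensity_g,intensity_s Normalized intensities.
#' @param sensitivity_a Sensitivity `a > 0`.
#' @return The affinity value(s).
#' @examples
#' affinity(0.9, 0.8, 0.4)  # 0.75
#' @export
affinity <- function(intensity_g, intensity_s, sensitivity_a) {
  if (!is.numeric(sensitivity_a) || any(sensitivity_a <= 0))
    iris_abort("sensitivity_a must be > 0", "irisseg_value_error")
  1 - abs(intensity_g - intensity_s) / sensitivity_a
}

# Neighbor offsets (dz, dr, dc) for a config.
growth_offsets <- function(config) {
  offs <- list(c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  if (config$connectivity == 8)
    offs <- c(offs, list(c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1)))
  if (config$scope == "3d")
    offs <- c(offs, list(c(1, 0, 0), c(-1, 0, 0)))
  offs
}

# Grow the affinity-connected region from a seed. Returns a logical array.
# `allowed`, if given, restricts growth (used for removal: only voxels
# currently in the mask may be grown over).
#
# Growth runs inside an expanding window around the seed: if the accepted
# region touches a window face that is not an array boundary, the window is
# doubled and growth restarts. The fixed point is confined, so the result
# is identical to growing over the full array, at a fraction of the cost
# for the typical small lesion.
grow_region <- function(I, seed, config, allowed = NULL) {
  d <- dim(I)
  w <- 8L
  repeat {
    zr <- if (config$scope == "2d") c(seed[1], seed[1])
          else c(max(1, seed[1] - w), min(d[1], seed[1] + w))
    rr <- c(max(1, seed[2] - w), min(d[2], seed[2] + w))
    cr <- c(max(1, seed[3] - w), min(d[3], seed[3] + w))
    zi <- zr[1]:zr[2]; ri <- rr[1]:rr[2]; ci <- cr[1]:cr[2]
    sub_seed <- c(seed[1] - zr[1] + 1L, seed[2] - rr[1] + 1L,
                  seed[3] - cr[1] + 1L)
    sub <- grow_region_window(
      I[zi, ri, ci, drop = FALSE], sub_seed, config,
      if (!is.null(allowed)) allowed[zi, ri, ci, drop = FALSE])
    sd <- dim(sub)
    touches <-
      (config$scope == "3d" &&
         ((zr[1] > 1 && any(sub[1, , ])) ||
          (zr[2] < d[1] && any(sub[sd[1], , ])))) ||
      (rr[1] > 1 && any(sub[, 1, ])) ||
      (rr[2] < d[2] && any(sub[, sd[2], ])) ||
      (cr[1] > 1 && any(sub[, , 1])) ||
      (cr[2] < d[3] && any(sub[, , sd[3]]))
    if (!touches) {  # faces at the array boundary never trigger expansion
      acc <- array(FALSE, d)
      acc[zi, ri, ci] <- sub
      return(acc)
    }
    w <- w * 2L
  }
}

grow_region_window <- function(I, seed, config, allowed = NULL) {
  d <- dim(I)
  offs <- growth_offsets(config)
  acc <- array(FALSE, d)
  acc[seed[1], seed[2], seed[3]] <- TRUE
  a <- config$sensitivity_a
  thr <- config$threshold

  if (config$comparison_mode == "seed") {
    Is <- I[seed[1], seed[2], seed[3]]
    elig <- (1 - abs(I - Is) / a) >= thr
    if (!is.null(allowed)) elig <- elig & allowed
    elig[seed[1], seed[2], seed[3]] <- TRUE
    repeat {
      newly <- array(FALSE, d)
      for (o in offs)
        newly <- newly | (shift3(acc, o[1], o[2], o[3]) & elig & !acc)
      if (!any(newly)) break
      acc <- acc | newly
    }
  } else {
    ok_step <- lapply(offs, function(o) {
      Js <- shift3(I, o[1], o[2], o[3], fill = NA)
      r <- (1 - abs(I - Js) / a) >= thr
      r[is.na(r)] <- FALSE
      if (!is.null(allowed)) r <- r & allowed
      r
    })
    repeat {
      newly <- array(FALSE, d)
      for (k in seq_along(offs)) {
        o <- offs[[k]]
        newly <- newly | (shift3(acc, o[1], o[2], o[3]) & ok_step[[k]] & !acc)
      }
      if (!any(newly)) break
      acc <- acc | newly
    }
  }
  acc
}

#' Single-click region growth (add)
#'
#' Grows an intensity-affinity-connected region from the clicked seed voxel
#' (breadth-first; see [affinity_config()] for the acceptance rule), applies
#' the in-plane morphological closing to the grown region to fill interior
#' holes, and returns the union with the input mask. Input mask voxels are
#' never removed.
#'
#' @param volume A normalized [image_volume()].
#' @param mask Current segmentation ([binary_mask()], congruent).
#' @param seed Clicked voxel, 1-based `(slice, row, col)`.
#' @param config An [affinity_config()].
#' @return The updated [binary_mask()].
#' @export
smart_click <- function(volume, mask, seed, config = affinity_config()) {
  check_click_inputs(volume, mask, seed)
  region <- grow_region(volume$data, seed, config)
  if (config$closing_radius > 0)
    region <- close_array(region, config$closing_radius)
  binary_mask(mask$data | region, spacing = mask$spacing)
}

#' Single-click region removal
#'
#' The removal counterpart of [smart_click()]: grows the same
#' affinity-connected region from the seed, but restricted to voxels
#' currently `TRUE` in the mask, and erases it. No closing is applied to a
#' removal (closing exists to fill holes within a grown lesion; applying it
#' here would refill erased holes). A seed outside the current mask is a
#' warning no-op.
#'
#' @inheritParams smart_click
#' @return The updated [binary_mask()].
#' @export
anti_smart_click <- function(volume, mask, seed, config = affinity_config()) {
  check_click_inputs(volume, mask, seed)
  if (!mask$data[seed[1], seed[2], seed[3]]) {
    iris_warn(sprintf("seed (%d, %d, %d) is not inside the mask; nothing removed",
                      seed[1], seed[2], seed[3]),
              "irisseg_noop_warning")
    return(mask)
  }
  region <- grow_region(volume$data, seed, config, allowed = mask$data)
  binary_mask(mask$data & !region, spacing = mask$spacing)
}

check_click_inputs <- function(volume, mask, seed) {
  if (!inherits(volume, "iris_volume") || !inherits(mask, "iris_mask"))
    iris_abort("expected an iris_volume and an iris_mask",
               "irisseg_usage_error")
  check_congruent(volume, mask, "volume and mask")
  if (!in_bounds(seed, dim(volume$data)))
    iris_abort(sprintf("seed (%s) out of bounds for a %s volume",
                       paste(seed, collapse = ", "),
                       paste(dim(volume$data), collapse = "x")),
               "irisseg_usage_error")
  invisible(TRUE)
}

#' Paintbrush edit
#'
#' Sets an in-plane Euclidean disk (offsets with `dr^2 + dc^2 <= radius^2`)
#' on the clicked slice to `TRUE` (`mode = "add"`) or `FALSE`
#' (`mode = "remove"`). Radius 0 touches exactly the clicked voxel.
#'
#' @param mask A [binary_mask()].
#' @param coordinate Clicked voxel, 1-based `(slice, row, col)`.
#' @param brush_radius Disk radius in voxels, `>= 0`.
#' @param mode `"add"` or `"remove"`.
#' @return The updated [binary_mask()].
#' @export
paint <- function(mask, coordinate, brush_radius = 0, mode = c("add", "remove")) {
  if (!inherits(mask, "iris_mask"))
    iris_abort("mask must be an iris_mask", "irisseg_usage_error")
  mode <- match.arg(mode)
  d <- dim(mask$data)
  if (!in_bounds(coordinate, d))
    iris_abort(sprintf("coordinate (%s) out of bounds",
                       paste(coordinate, collapse = ", ")),
               "irisseg_usage_error")
  if (brush_radius < 0)
    iris_abort("brush_radius must be >= 0", "irisseg_value_error")
  offs <- disk_offsets(brush_radius)
  rr <- coordinate[2] + offs$dr
  cc <- coordinate[3] + offs$dc
  keep <- rr >= 1 & rr <= d[2] & cc >= 1 & cc <= d[3]
  data <- mask$data
  data[cbind(coordinate[1], rr[keep], cc[keep])] <- (mode == "add")
  binary_mask(data, spacing = mask$spacing)
}

# Closing on a raw logical 3D array, slice by slice.
close_array <- function(arr, radius) {
  r <- as.integer(floor(radius))
  if (r <= 0) return(arr)
  offs <- disk_offsets(radius)
  for (z in seq_len(dim(arr)[1])) {
    if (any(arr[z, , ])) arr[z, , ] <- close_slice(arr[z, , ], offs, r)
  }
  arr
}

# Exact in-plane closing: pad by the radius so dilation is never clipped,
# dilate (OR of shifts), erode (AND of shifts), crop. On the padded domain
# this equals closing on the unbounded plane, hence it is extensive
# (output >= input) and idempotent.
close_slice <- function(m, offs, r) {
  nr <- nrow(m); nc <- ncol(m)
  P <- matrix(FALSE, nr + 2L * r, nc + 2L * r)
  P[r + seq_len(nr), r + seq_len(nc)] <- m
  D <- matrix(FALSE, nrow(P), ncol(P))
  for (k in seq_len(nrow(offs)))
    D <- D | shift2(P, offs$dr[k], offs$dc[k])
  E <- matrix(TRUE, nrow(P), ncol(P))
  for (k in seq_len(nrow(offs)))
    E <- E & shift2(D, offs$dr[k], offs$dc[k])
  E[r + seq_len(nr), r + seq_len(nc)]
}

#' Morphological closing of a mask (in-plane)
#'
#' Dilation followed by erosion with a Euclidean disk of the given radius,
#' applied independently on each axial slice. Fills interior holes smaller
#' than the structuring element; extensive (`output >= input`) and
#' idempotent. Radius 0 is the identity.
#'
#' @param mask A [binary_mask()].
#' @param radius In-plane disk radius in voxels, `>= 0`.
#' @return The closed [binary_mask()].
#' @export
closing <- function(mask, radius) {
  if (!inherits(mask, "iris_mask"))
    iris_abort("mask must be an iris_mask", "irisseg_usage_error")
  if (radius < 0)
    iris_abort("radius must be >= 0", "irisseg_value_error")
  binary_mask(close_array(mask$data, radius), spacing = mask$spacing)
}
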