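#' Chan-Vese segmentation parameters
#'
#' Parameters of the two-phase piecewise-constant (Chan-Vese) energy
#' minimized per axial slice:
#' `E = mu * Per(C) + lambda1 * sum_in (I - c1)^2 + lambda2 * sum_out (I - c2)^2`
#' where `Per` is the 4-neighbor boundary length of the inside region, and
#' `c1`, `c2` are the mean intensities of the two phases within the liver ROI.
#'
#' @param mu Boundary-length weight, dimensionless `>= 0`. Larger values
#'   smooth the contour and suppress speckle at the cost of eroding
#'   single-voxel protrusions of small lesions: a one-voxel tip attached by
#'   one edge survives only while `2 * mu` is below the squared
#'   lesion-to-parenchyma contrast. The default 0.05 removes isolated noise
#'   voxels while preserving tips down to a contrast of ~0.32.
#' @param lambda1,lambda2 Inside/outside fidelity weights, `> 0`.
#' @param max_iterations Iteration cap per slice (`>= 1`).
#' @param tolerance Relative energy-change stopping threshold (`> 0`).
#' @param init_patch Half-width in voxels of the square initialization region
#'   placed on the lowest-intensity ROI voxel of each slice (`>= 0`).
#' @param min_contrast Minimum separation of the two phase means (normalized
#'   intensity) for a slice to report any foreground. A slice whose best
#'   two-phase split separates the means by less than this is treated as
#'   having no separable phases -- the conservative generalization of the
#'   constant-slice rule: no cysts are claimed without contrast. The default
#'   0.1 sits far above the split that pure noise or a smooth bias field can
#'   produce and far below any real fluid-bright lesion contrast.
#' @return A `chan_vese_config` list.
#' @export
chan_vese_config <- function(mu = 0.05, lambda1 = 1.0, lambda2 = 1.0,
                             max_iterations = 200L, tolerance = 1e-3,
                             init_patch = 1L, min_contrast = 0.1) {
  if (!is.numeric(mu) || length(mu) != 1 || mu < 0)
    iris_abort("mu must be a single number >= 0", "irisseg_value_error")
  if (lambda1 <= 0 || lambda2 <= 0)
    iris_abort("lambda1 and lambda2 must be > 0", "irisseg_value_error")
  if (max_iterations < 1)
    iris_abort("max_iterations must be >= 1", "irisseg_value_error")
  if (tolerance <= 0)
    iris_abort("tolerance must be > 0", "irisseg_value_error")
  if (init_patch < 0)
    iris_abort("init_patch must be >= 0", "irisseg_value_error")
  if (min_contrast < 0)
    iris_abort("min_contrast must be >= 0", "irisseg_value_error")
  structure(list(mu = mu, lambda1 = lambda1, lambda2 = lambda2,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, init_patch = as.integer(init_patch),
                 min_contrast = min_contrast),
            class = "chan_vese_config")
}

#' Per-slice level-set initialization at the intensity minimum
#'
#' Builds the initial inside region for one axial slice: a square of side
#' `2 * init_patch + 1` centered on the ROI voxel of minimum intensity on
#' that slice (on real liver T2 images typically a corner of the ROI),
#' clipped to the slice bounds and intersected with the ROI. Ties between
#' equal-minimum voxels are broken lexicographically by (row, col).
#'
#' @inheritParams chan_vese_segment
#' @param slice_index 1-based axial slice index.
#' @return A logical matrix (row x col). If the ROI is empty on the slice the
#'   matrix is all-`FALSE` and carries attribute `empty_roi = TRUE`.
#' @export
init_levelset_slice <- function(volume, roi, slice_index,
                                config = chan_vese_config()) {
  check_congruent(volume, roi, "volume and roi")
  d <- dim(volume$data)
  if (slice_index < 1 || slice_index > d[1] || slice_index != floor(slice_index))
    iris_abort(sprintf("slice_index %s out of bounds [1, %d]",
                       format(slice_index), d[1]), "irisseg_usage_error")
  I <- volume$data[slice_index, , ]
  R <- roi$data[slice_index, , ]
  out <- matrix(FALSE, d[2], d[3])
  if (!any(R)) {
    attr(out, "empty_roi") <- TRUE
    return(out)
  }
  idx <- which(R)
  cand <- idx[I[idx] == min(I[idx])]
  rr <- (cand - 1L) %% d[2] + 1L
  cc <- (cand - 1L) %/% d[2] + 1L
  o <- order(rr, cc)[1]
  p <- config$init_patch
  out[max(1, rr[o] - p):min(d[2], rr[o] + p),
      max(1, cc[o] - p):min(d[3], cc[o] + p)] <- TRUE
  out <- out & R
  attr(out, "center") <- c(rr[o], cc[o])
  out
}

# 4-neighbor boundary length of a logical matrix (count of differing
# horizontal + vertical adjacent pairs).
perimeter4 <- function(phi) {
  p <- 0L
  if (nrow(phi) > 1) p <- p + sum(phi[-1, ] != phi[-nrow(phi), ])
  if (ncol(phi) > 1) p <- p + sum(phi[, -1] != phi[, -ncol(phi)])
  p
}

# Two-stage discrete minimization of the Chan-Vese energy on one slice.
#
# Stage 1 alternates the two exact coordinate updates of the unregularized
# energy: means given the partition, then the pointwise optimal partition
# given the means (a Lloyd iteration; each step weakly decreases the
# fidelity energy). Stage 2 minimizes the full length-regularized energy by
# single-voxel flips on a checkerboard schedule: voxels of one parity are
# never 4-adjacent, so simultaneous flips change the energy by the sum of
# their individual (strictly negative) contributions, and the recorded
# energy trace is exactly non-increasing.
cv_slice <- function(I, R, cfg) {
  nr <- nrow(I); nc <- ncol(I)
  empty <- matrix(FALSE, nr, nc)
  if (!any(R)) return(list(fg = empty, energy = numeric(0), iterations = 0L))

  phi <- init_levelset_slice_raw(I, R, cfg$init_patch)
  l1 <- cfg$lambda1; l2 <- cfg$lambda2; mu <- cfg$mu
  it <- 0L
  n_roi <- sum(R)

  # stage 1: unregularized alternating assignment
  repeat {
    if (it >= cfg$max_iterations) break
    nin <- sum(phi)
    if (nin == 0 || nin == n_roi) break
    c1 <- mean(I[phi]); c2 <- mean(I[R & !phi])
    d1 <- l1 * (I - c1)^2; d2 <- l2 * (I - c2)^2
    newphi <- R & (d1 < d2 | (phi & d1 == d2))
    it <- it + 1L
    if (identical(newphi, phi)) break
    phi <- newphi
  }

  # stage 2: length-regularized checkerboard flips
  energy <- numeric(0)
  if (mu > 0) {
    nnb <- matrix(4L, nr, nc)
    if (nr > 1) nnb[c(1, nr), ] <- nnb[c(1, nr), ] - 1L else nnb <- nnb - 2L
    if (nc > 1) nnb[, c(1, nc)] <- nnb[, c(1, nc)] - 1L else nnb <- nnb - 2L
    parity <- (row(I) + col(I)) %% 2
    while (it < cfg$max_iterations) {
      nin <- sum(phi)
      if (nin == 0 || nin == n_roi) break
      c1 <- mean(I[phi]); c2 <- mean(I[R & !phi])
      E <- mu * perimeter4(phi) + l1 * sum((I[phi] - c1)^2) +
        l2 * sum((I[R & !phi] - c2)^2)
      energy <- c(energy, E)
      k <- length(energy)
      if (k >= 2 &&
          abs(energy[k - 1] - energy[k]) <=
            cfg$tolerance * max(abs(energy[k - 1]), 1e-12)) break
      flipped <- FALSE
      fid_in <- -l1 * (I - c1)^2 + l2 * (I - c2)^2   # dE of an in->out flip
      fid_out <- -fid_in                             # dE of an out->in flip
      for (p in 0:1) {
        nbrT <- shift2(phi, 1, 0) + shift2(phi, -1, 0) +
          shift2(phi, 0, 1) + shift2(phi, 0, -1)
        same <- ifelse(phi, nbrT, nnb - nbrT)
        dE <- mu * (2 * same - nnb) + ifelse(phi, fid_in, fid_out)
        fl <- R & (parity == p) & (dE < -1e-12)
        if (any(fl)) {
          phi[fl] <- !phi[fl]
          flipped <- TRUE
        }
      }
      it <- it + 1L
      if (!flipped) break
    }
  }

  nin <- sum(phi)
  if (nin == 0 || nin == n_roi)
    return(list(fg = empty, energy = energy, iterations = it))
  c1 <- mean(I[phi]); c2 <- mean(I[R & !phi])
  # no separable phases: constant region, or a split that only carves up
  # noise / smooth bias (phase means closer than min_contrast)
  if (abs(c1 - c2) < max(cfg$min_contrast, 1e-12))
    return(list(fg = empty, energy = energy, iterations = it))
  fg <- if (c1 > c2) phi else R & !phi
  list(fg = fg, energy = energy, iterations = it)
}

# Initialization on raw matrices (shared by cv_slice and the exported
# init_levelset_slice, which adds validation and attributes).
init_levelset_slice_raw <- function(I, R, patch) {
  nr <- nrow(I); nc <- ncol(I)
  phi <- matrix(FALSE, nr, nc)
  idx <- which(R)
  if (!length(idx)) return(phi)
  cand <- idx[I[idx] == min(I[idx])]
  rr <- (cand - 1L) %% nr + 1L
  cc <- (cand - 1L) %/% nr + 1L
  o <- order(rr, cc)[1]
  phi[max(1, rr[o] - patch):min(nr, rr[o] + patch),
      max(1, cc[o] - patch):min(nc, cc[o] + patch)] <- TRUE
  phi & R
}

#' Automated Chan-Vese cyst segmentation within a liver ROI
#'
#' Runs a per-axial-slice two-phase piecewise-constant (Chan-Vese) level-set
#' segmentation restricted to the liver region of interest. Each slice is
#' initialized with a small square at the lowest-intensity ROI voxel
#' ([init_levelset_slice()]) and evolved until the relative energy change
#' falls below `config$tolerance` or `config$max_iterations` is reached. The
#' phase with the higher mean intensity is reported as foreground, since
#' cysts (and vessels, the classic false positive) are T2-hyperintense.
#' Voxels outside the ROI are always `FALSE`; a slice with constant ROI
#' intensity yields no foreground.
#'
#' The minimizer is a discrete two-stage scheme (unregularized alternating
#' assignment, then length-regularized checkerboard voxel flips), so the
#' result is fully deterministic and the recorded energy is non-increasing.
#'
#' @param volume A normalized [image_volume()] with intensities in `[0, 1]`.
#' @param roi A [binary_mask()] congruent with `volume` (the liver ROI).
#' @param config A [chan_vese_config()].
#' @param trace If `TRUE`, attach the per-slice energy traces as attribute
#'   `energy` of the result.
#' @return A [binary_mask()] of segmented cysts (subset of the ROI), with
#'   attribute `iterations`: the per-slice iteration counts.
#' @export
chan_vese_segment <- function(volume, roi, config = chan_vese_config(),
                              trace = FALSE) {
  if (!inherits(volume, "iris_volume"))
    iris_abort("volume must be an iris_volume", "irisseg_usage_error")
  if (!inherits(roi, "iris_mask"))
    iris_abort("roi must be an iris_mask", "irisseg_usage_error")
  check_congruent(volume, roi, "volume and roi")
  rng <- range(volume$data)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    iris_abort(sprintf(
      "volume intensities in [%.4g, %.4g]; normalize to [0, 1] first (normalize_minmax)",
      rng[1], rng[2]), "irisseg_value_error")

  d <- dim(volume$data)
  out <- array(FALSE, d)
  iters <- integer(d[1])
  traces <- if (trace) vector("list", d[1])
  for (z in seq_len(d[1])) {
    res <- cv_slice(volume$data[z, , ], roi$data[z, , ], config)
    out[z, , ] <- res$fg
    iters[z] <- res$iterations
    if (trace) traces[[z]] <- res$energy
  }
  m <- binary_mask(out, spacing = volume$spacing)
  attr(m, "iterations") <- iters
  if (trace) attr(m, "energy") <- traces
  m
}
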