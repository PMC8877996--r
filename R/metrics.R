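#' Dice similarity coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`: 1 for identical masks, 0 for disjoint
#' nonempty masks. Two empty masks agree perfectly on absence, so the value
#' is defined as 1 (with a warning), keeping phantom edge cases total.
#'
#' @param a,b Congruent [binary_mask()]s.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!inherits(a, "iris_mask") || !inherits(b, "iris_mask"))
    iris_abort("a and b must be iris_mask objects", "irisseg_usage_error")
  check_congruent(a, b, "masks")
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) {
    iris_warn("both masks are empty; Dice defined as 1", "irisseg_degenerate_warning")
    return(1)
  }
  2 * sum(a$data & b$data) / (na + nb)
}

#' Normalized volume error
#'
#' `|v_ref - v_cand| / v_ref`, the volume discrepancy as a fraction of the
#' reference volume.
#'
#' @param v_ref Reference volume (mL), `> 0`.
#' @param v_cand Candidate volume (mL).
#' @return Error fraction (0 = perfect agreement).
#' @export
normalized_volume_error <- function(v_ref, v_cand) {
  if (any(v_ref <= 0))
    iris_abort("v_ref must be > 0", "irisseg_value_error")
  abs(v_ref - v_cand) / v_ref
}

#' Root-mean-square error between paired volume lists
#'
#' @param volumes_ref,volumes_cand Equal-length numeric vectors (mL).
#' @return RMSE in mL.
#' @export
rmse <- function(volumes_ref, volumes_cand) {
  check_pairs(volumes_ref, volumes_cand, min_n = 1)
  sqrt(mean((volumes_ref - volumes_cand)^2))
}

check_pairs <- function(ref, cand, min_n = 2) {
  if (length(ref) != length(cand))
    iris_abort("paired lists must have equal length", "irisseg_usage_error")
  if (length(ref) < min_n)
    iris_abort(sprintf("at least %d pair(s) required", min_n),
               "irisseg_value_error")
  if (any(!is.finite(ref)) || any(!is.finite(cand)))
    iris_abort("volumes must be finite", "irisseg_value_error")
  invisible(TRUE)
}

#' Intraclass correlation coefficient for paired volumes
#'
#' Computed from the classical two-way ANOVA mean squares on the
#' subject-by-rater table (here: case-by-method, k = 2). The default,
#' ICC(2,1) -- two-way random effects, single measure, absolute agreement --
#' is the standard choice for method comparison of volume measurements,
#' because a systematic offset between methods should lower agreement.
#' `type = "consistency"` gives the consistency form, which is invariant to
#' a fixed offset.
#'
#' With subjects' mean square `MSR`, raters' mean square `MSC` and residual
#' `MSE` (n subjects, k raters):
#' agreement `= (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`;
#' consistency `= (MSR - MSE) / (MSR + (k-1) MSE)`.
#'
#' @param volumes_ref,volumes_cand Equal-length numeric vectors (mL), n >= 2.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return The ICC, in `[-1, 1]`; attribute `form` records the variant.
#' @export
icc <- function(volumes_ref, volumes_cand,
                type = c("agreement", "consistency")) {
  type <- match.arg(type)
  check_pairs(volumes_ref, volumes_cand, min_n = 2)
  x <- cbind(volumes_ref, volumes_cand)
  if (all(x == x[1, 1]))
    iris_abort("zero variance in both raters; ICC undefined",
               "irisseg_value_error")
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  val <- switch(type,
    agreement = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    consistency = (msr - mse) / (msr + (k - 1) * mse))
  structure(val, form = if (type == "agreement")
    "ICC(2,1): two-way random, single measure, absolute agreement"
    else "ICC(3,1)-style consistency, single measure")
}

#' Bland-Altman analysis of paired volumes, in percent
#'
#' Per-case percent difference `100 (cand - ref) / mean(cand, ref)` (the
#' standard percent-difference construction, normalizing by the per-case
#' mean of the two measurements); bias is the mean of these, and the limits
#' of agreement are `bias -/+ 1.96 * STD` with the sample (n-1) standard
#' deviation.
#'
#' @param volumes_ref,volumes_cand Equal-length numeric vectors (mL) with
#'   all pairwise means `> 0`.
#' @return A list with `bias`, `std`, `lower`, `upper` (all percent) and the
#'   per-case `percent_diff` vector.
#' @export
bland_altman_percent <- function(volumes_ref, volumes_cand) {
  check_pairs(volumes_ref, volumes_cand, min_n = 1)
  m <- (volumes_ref + volumes_cand) / 2
  if (any(m <= 0))
    iris_abort("all pairwise means must be > 0", "irisseg_value_error")
  pd <- 100 * (volumes_cand - volumes_ref) / m
  bias <- mean(pd)
  s <- if (length(pd) > 1) stats::sd(pd) else 0
  list(bias = bias, std = s,
       lower = bias - 1.96 * s, upper = bias + 1.96 * s,
       percent_diff = pd)
}

#' Lesion SNR and CNR from intensity ROIs
#'
#' Signal-to-noise ratio of a cyst ROI (`mean / STD` of its intensities) and
#' cyst-to-liver contrast-to-noise ratio
#' (`(cyst mean - liver mean) / cyst STD`), the standard conspicuity
#' measures for fluid-bright lesions. STD is the sample (n-1) standard
#' deviation. Both ratios are invariant to a global intensity scaling.
#'
#' @param volume An [image_volume()].
#' @param cyst_roi [binary_mask()] over the cyst (nonempty, STD `> 0`).
#' @param liver_roi [binary_mask()] over adjacent liver parenchyma (nonempty).
#' @return A list of class `roi_stats`: `mean`, `std`, `liver_mean`, `snr`,
#'   `cnr`.
#' @export
snr_cnr <- function(volume, cyst_roi, liver_roi) {
  if (!inherits(volume, "iris_volume"))
    iris_abort("volume must be an iris_volume", "irisseg_usage_error")
  check_congruent(volume, cyst_roi, "volume and cyst_roi")
  check_congruent(volume, liver_roi, "volume and liver_roi")
  if (!any(cyst_roi$data) || !any(liver_roi$data))
    iris_abort("both ROIs must be nonempty", "irisseg_value_error")
  cyst <- volume$data[cyst_roi$data]
  liver <- volume$data[liver_roi$data]
  s <- stats::sd(cyst)
  if (length(cyst) < 2 || s == 0)
    iris_abort("cyst ROI standard deviation must be > 0",
               "irisseg_value_error")
  m <- mean(cyst); lm <- mean(liver)
  structure(list(mean = m, std = s, liver_mean = lm,
                 snr = m / s, cnr = (m - lm) / s),
            class = "roi_stats")
}

#' Cohort summary in the standard table layout
#'
#' The four per-cohort summaries used in method-comparison tables:
#' mean, median, `[min, max]`, and the sample (n-1) standard deviation.
#' Order-invariant.
#'
#' @param values Nonempty numeric vector of per-case values.
#' @return A list: `mean`, `median`, `min`, `max`, `std`.
#' @export
cohort_summary <- function(values) {
  if (!length(values) || any(!is.finite(values)))
    iris_abort("values must be a nonempty finite numeric vector",
               "irisseg_value_error")
  list(mean = mean(values), median = stats::median(values),
       min = min(values), max = max(values),
       std = if (length(values) > 1) stats::sd(values) else 0)
}

#' Agreement report between candidate and reference segmentations
#'
#' Bundles the full method-comparison suite for a cohort of paired volume
#' measurements: per-case volumes, normalized volume errors and (optionally)
#' Dice scores; cohort summaries; ICC; RMSE; and Bland-Altman statistics.
#'
#' @param volumes_ref,volumes_cand Per-case volumes in mL (reference and
#'   candidate method).
#' @param dice_scores Optional per-case Dice scores against the reference.
#' @param label Candidate method label used when printing.
#' @return A list of class `iris_agreement` with elements `per_case` (data
#'   frame), `dice_summary`, `nve_summary`, `icc`, `icc_form`, `rmse_ml`,
#'   `bland_altman`, `label`.
#' @export
agreement_report <- function(volumes_ref, volumes_cand, dice_scores = NULL,
                             label = "candidate") {
  check_pairs(volumes_ref, volumes_cand, min_n = 2)
  nve <- normalized_volume_error(volumes_ref, volumes_cand)
  per_case <- data.frame(case = seq_along(volumes_ref),
                         volume_ref_ml = volumes_ref,
                         volume_cand_ml = volumes_cand,
                         normalized_volume_error = nve)
  if (!is.null(dice_scores)) per_case$dice <- dice_scores
  ic <- icc(volumes_ref, volumes_cand)
  structure(list(
    per_case = per_case,
    dice_summary = if (!is.null(dice_scores)) cohort_summary(dice_scores),
    nve_summary = cohort_summary(nve),
    icc = as.numeric(ic),
    icc_form = attr(ic, "form"),
    rmse_ml = rmse(volumes_ref, volumes_cand),
    bland_altman = bland_altman_percent(volumes_ref, volumes_cand),
    label = label), class = "iris_agreement")
}

#' @export
print.iris_agreement <- function(x, ...) {
  cat(sprintf("<iris_agreement> %s vs reference, n = %d cases\n",
              x$label, nrow(x$per_case)))
  fmt_sum <- function(s, scale = 1, unit = "") {
    sprintf("mean %.2f%s / median %.2f%s / [%.2f, %.2f]%s / STD %.2f%s",
            s$mean * scale, unit, s$median * scale, unit,
            s$min * scale, s$max * scale, unit, s$std * scale, unit)
  }
  if (!is.null(x$dice_summary))
    cat("  Dice:        ", fmt_sum(x$dice_summary, 100, "%"), "\n")
  cat("  Volume error:", fmt_sum(x$nve_summary, 100, "%"), "\n")
  cat(sprintf("  ICC: %.4f   RMSE: %.2f mL\n", x$icc, x$rmse_ml))
  ba <- x$bland_altman
  cat(sprintf("  Bland-Altman: bias %.2f%%, STD %.2f%%, LoA [%.0f%%, %.0f%%]\n",
              ba$bias, ba$std, ba$lower, ba$upper))
  invisible(x)
}
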