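mk <- function(v) binary_mask(array(v, c(1, 2, 4)))

test_that("dice handles identity, disjointness, overlap and symmetry", {
  a <- mk(c(T, T, T, T, F, F, F, F))
  b <- mk(c(F, F, T, T, T, T, F, F))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, mk(c(F, F, F, F, T, T, T, T))), 0)
  expect_equal(dice(a, b), 0.5)     # 2*2 / (4+4)
  expect_equal(dice(a, b), dice(b, a))
  expect_warning(expect_equal(dice(mk(rep(F, 8)), mk(rep(F, 8))), 1),
                 class = "irisseg_degenerate_warning")
  expect_error(dice(a, binary_mask(array(TRUE, c(1, 2, 2)))),
               class = "irisseg_dim_error")
})

test_that("normalized volume error reproduces the clinical worked example", {
  # a 13 mL reference measured as 8 mL is a 38.46% error (printed as ~38.7%
  # after the source's own rounding of the underlying volumes)
  expect_equal(normalized_volume_error(13, 8), 5 / 13)
  expect_equal(100 * normalized_volume_error(13, 8), 38.46, tolerance = 1e-3)
  expect_equal(normalized_volume_error(100, 150), 0.5)
  expect_equal(normalized_volume_error(7, 7), 0)
  expect_error(normalized_volume_error(0, 5), class = "irisseg_value_error")
})

test_that("rmse matches hand-computed values", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(100, 90), 10)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_error(rmse(1:3, 1:2), class = "irisseg_usage_error")
})

test_that("ICC(2,1) agrees with the independent ANOVA oracle", {
  ref <- c(10, 50, 100, 500, 1000, 1500)

  expect_equal(as.numeric(icc(ref, ref)), 1)

  # fixed offset: absolute agreement < 1 and equal to the oracle
  cand <- ref + 20
  got <- icc(ref, cand)
  expect_equal(as.numeric(got), oracle_icc(ref, cand, "agreement"),
               tolerance = 1e-10)
  expect_lt(as.numeric(got), 1)
  expect_match(attr(got, "form"), "absolute agreement")

  # consistency form is offset-invariant; agreement strictly decreases as
  # the offset grows
  expect_equal(as.numeric(icc(ref, cand, "consistency")), 1, tolerance = 1e-12)
  expect_lt(as.numeric(icc(ref, ref + 200)), as.numeric(icc(ref, ref + 20)))

  # random cohorts against the oracle, both forms
  set.seed(9)
  for (rep in 1:10) {
    r <- runif(8, 10, 1500)
    c_ <- r * runif(1, 0.8, 1.2) + rnorm(8, 0, 30)
    expect_equal(as.numeric(icc(r, c_)), oracle_icc(r, c_, "agreement"),
                 tolerance = 1e-8)
    expect_equal(as.numeric(icc(r, c_, "consistency")),
                 oracle_icc(r, c_, "consistency"), tolerance = 1e-8)
  }

  # swapping one pair between distant values degrades agreement
  swapped <- ref; swapped[c(1, 6)] <- ref[c(6, 1)]
  expect_lt(as.numeric(icc(ref, swapped)), 1)

  expect_error(icc(1, 1), class = "irisseg_value_error")
  expect_error(icc(c(5, 5), c(5, 5)), class = "irisseg_value_error")
})

test_that("Bland-Altman percent statistics follow their definitions", {
  ba0 <- bland_altman_percent(c(10, 20), c(10, 20))
  expect_equal(ba0$bias, 0); expect_equal(ba0$std, 0)
  expect_equal(c(ba0$lower, ba0$upper), c(0, 0))

  ba1 <- bland_altman_percent(100, 110)
  expect_equal(ba1$percent_diff, 100 * 10 / 105)

  set.seed(12)
  r <- runif(30, 50, 500); c_ <- r + rnorm(30, 5, 20)
  ba <- bland_altman_percent(r, c_)
  expect_equal(ba$upper - ba$lower, 2 * 1.96 * ba$std)
  expect_equal(ba$bias, mean(ba$percent_diff))
  expect_error(bland_altman_percent(c(1, -1), c(1, 0)),
               class = "irisseg_value_error")
})

test_that("Bland-Altman limits bracket ~95% of a large Gaussian cohort", {
  set.seed(77)
  n <- 4000
  r <- runif(n, 400, 600)
  c_ <- r + rnorm(n, 10, 25)
  ba <- bland_altman_percent(r, c_)
  frac <- mean(ba$percent_diff >= ba$lower & ba$percent_diff <= ba$upper)
  expect_gt(frac, 0.93)
  expect_lt(frac, 0.97)
})

test_that("SNR and CNR follow the ROI statistics and are scale invariant", {
  arr <- array(0.4, c(1, 3, 3))
  arr[1, 1, ] <- c(0.8, 1.0, 1.2)
  vol <- image_volume(arr / 1.2)  # keep within [0,1]; ratios unaffected
  cyst <- binary_mask(array(c(T, F, F, T, F, F, T, F, F), c(1, 3, 3)))
  liver <- binary_mask(array(c(F, T, T, F, T, T, F, T, T), c(1, 3, 3)))
  st <- snr_cnr(vol, cyst, liver)
  s <- sd(c(0.8, 1.0, 1.2) / 1.2)
  expect_equal(st$snr, (1.0 / 1.2) / s)
  expect_equal(st$cnr, (1.0 / 1.2 - 0.4 / 1.2) / s)

  half <- image_volume(arr / 2.4)
  st2 <- snr_cnr(half, cyst, liver)
  expect_equal(st2$snr, st$snr)
  expect_equal(st2$cnr, st$cnr)

  same <- snr_cnr(vol, cyst, cyst)
  expect_equal(same$cnr, 0)

  expect_error(snr_cnr(vol, binary_mask(array(FALSE, c(1, 3, 3))), liver),
               class = "irisseg_value_error")
})

test_that("cohort summary prints the four standard rows, order invariant", {
  s <- cohort_summary(c(1, 2, 3))
  expect_equal(s, list(mean = 2, median = 2, min = 1, max = 3, std = 1))
  s1 <- cohort_summary(5)
  expect_equal(c(s1$mean, s1$median, s1$min, s1$max), rep(5, 4))
  set.seed(3)
  x <- runif(9)
  expect_identical(cohort_summary(x), cohort_summary(sample(x)))
})

test_that("agreement report bundles the full metric suite", {
  ref <- c(100, 300, 50, 800)
  cand <- c(110, 280, 60, 790)
  rep_ <- agreement_report(ref, cand, dice_scores = c(0.9, 0.8, 0.7, 0.95),
                           label = "IRIS")
  expect_s3_class(rep_, "iris_agreement")
  expect_equal(nrow(rep_$per_case), 4)
  expect_equal(rep_$rmse_ml, rmse(ref, cand))
  expect_equal(rep_$icc, as.numeric(icc(ref, cand)))
  expect_equal(rep_$per_case$normalized_volume_error,
               abs(ref - cand) / ref)
  expect_equal(rep_$dice_summary$mean, mean(c(0.9, 0.8, 0.7, 0.95)))
  expect_output(print(rep_), "Bland-Altman")
})
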