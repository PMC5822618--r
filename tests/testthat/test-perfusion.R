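test_that("fermi_irf matches direct formula substitution", {
  p <- fermi_params(2, 0.5, 4, 1)
  # hand-evaluated: R(t) = F / (1 + exp(k (t - td - w)))
  expect_equal(fermi_irf(1, p), 2 / (1 + exp(0.5 * (1 - 1 - 4))))
  expect_equal(fermi_irf(21, p), 2 / (1 + exp(0.5 * (21 - 1 - 4))))
  # zero before the delay
  expect_equal(fermi_irf(c(0, 0.5, 0.999), p), c(0, 0, 0))
  # non-increasing after the delay
  tt <- seq(1, 30, by = 0.1)
  expect_true(all(diff(fermi_irf(tt, p)) <= 0))
  # k = 0: constant plateau after the delay
  p0 <- fermi_params(2, 0, 4, 1)
  expect_equal(fermi_irf(c(1, 10, 100), p0), rep(2 / (1 + exp(0)), 3))
  expect_error(fermi_params(-1, 0.5, 4, 1), "amplitude_f")
  expect_error(fermi_params(1, 0.5, 4, 9), "delay_td")
})

test_that("fermi_mbf is the impulse-response amplitude at arrival", {
  p <- fermi_params(2, 0.5, 4, 1)
  expect_equal(fermi_mbf(p), fermi_irf(1 + 1e-12, p), tolerance = 1e-9)
})

test_that("model_tissue_curve matches the double-loop oracle and is linear in F", {
  aif <- resample_curve(gen_aif(), 0.5)
  p <- fermi_params(2.3, 0.6, 3, 1.5)
  m <- model_tissue_curve(aif, p)
  rel <- aif$times_s - aif$times_s[1]
  r <- fermi_irf(rel, p) * 1.05 / 60
  expect_equal(m$values_mmol,
               oracle_conv_trapz(aif$values_mmol, r, 0.5),
               tolerance = 1e-10)
  # zero AIF -> zero tissue curve
  z <- conc_curve(aif$times_s, rep(0, length(aif$times_s)), "aif")
  expect_true(all(model_tissue_curve(z, p)$values_mmol == 0))
  # exactly linear in amplitude
  p2 <- fermi_params(4.6, 0.6, 3, 1.5)
  expect_equal(model_tissue_curve(aif, p2)$values_mmol,
               2 * m$values_mmol, tolerance = 1e-12)
  # non-uniform grid is an internal error
  bad <- conc_curve(c(0, 1, 3, 4, 5, 6, 7, 8, 9, 10), rep(1, 10), "aif")
  expect_error(model_tissue_curve(bad, p), "uniform")
})

test_that("fit_fermi recovers noiseless parameters and flags degeneracy", {
  aif <- gen_aif()
  # recovery at a single level: MBF (and the full parameter set) to < 1%
  p_true <- fermi_for_mbf(2.5)
  tis <- gen_tissue_curve(aif, mbf = NA, p = p_true)
  fit <- fit_fermi(aif, tis)
  expect_true(fit$valid)
  expect_equal(fit$mbf, fermi_mbf(p_true), tolerance = 0.01)
  expect_equal(fit$params$amplitude_f, p_true$amplitude_f, tolerance = 0.01)
  # all-zero tissue: pinned at the lower amplitude bound, degenerate
  z <- conc_curve(aif$times_s, rep(0, length(aif$times_s)), "tissue")
  fz <- fit_fermi(aif, z)
  expect_true(fz$degenerate)
  expect_false(fz$valid)
  expect_equal(fz$params$amplitude_f, fermi_default_bounds()$amplitude_f[1])
  # too-short curves are rejected
  short <- conc_curve(1:5, rep(1, 5), "tissue")
  expect_error(fit_fermi(short, short), "10 samples")
})

test_that("noiseless forward-inverse sweep is monotone and within 2%", {
  aif <- gen_aif()
  grid <- c(0.5, 1.0, 2.0, 4.0)
  est <- vapply(grid, function(mbf) {
    fit_fermi(aif, gen_tissue_curve(aif, mbf))$mbf
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_true(all(abs(est - grid) / grid < 0.02))
})

test_that("fit_fermi at curve-level SNR 20 is unbiased at its noise floor", {
  # Gaussian noise on the concentration curve (sd = peak / 20). The
  # achievable median relative MBF error of the constrained 4-parameter
  # fit sits near 13% here (see the vignette's limitations section and
  # the red noise-robustness acceptance criterion, which asserts the 10%
  # target); this test pins the achieved floor and unbiasedness so
  # regressions are caught.
  aif <- gen_aif()
  set.seed(2024)
  res <- vapply(1:100, function(i) {
    mbf <- runif(1, 0.5, 4.5)
    tis <- gen_tissue_curve(aif, mbf)
    noisy <- pmax(tis$values_mmol +
                    rnorm(length(tis$values_mmol),
                          0, max(tis$values_mmol) / 20), 0)
    f <- fit_fermi(aif, conc_curve(tis$times_s, noisy, "tissue"))
    (f$mbf - mbf) / mbf
  }, numeric(1))
  expect_lt(median(abs(res)), 0.20)
  expect_lt(abs(mean(res)), 0.05)
})

test_that("MPR is invariant to a common concentration scale", {
  aif <- gen_aif()
  rest <- gen_tissue_curve(aif, 1.1)
  stress <- gen_tissue_curve(aif, 3.0)
  mpr1 <- compute_mpr(fit_fermi(aif, stress)$mbf, fit_fermi(aif, rest)$mbf)
  sc <- 2.7
  aif2 <- conc_curve(aif$times_s, sc * aif$values_mmol, "aif")
  rest2 <- conc_curve(rest$times_s, sc * rest$values_mmol, "tissue")
  stress2 <- conc_curve(stress$times_s, sc * stress$values_mmol, "tissue")
  mpr2 <- compute_mpr(fit_fermi(aif2, stress2)$mbf,
                      fit_fermi(aif2, rest2)$mbf)
  expect_equal(mpr1, mpr2, tolerance = 0.01)
})

test_that("pixelwise_mbf maps regions and excludes invalid fits", {
  # single-pixel mask equals a direct fit_fermi call
  sim <- gen_dynamic_series(matrix(2.0, 2, 2), snr = Inf)
  ctx <- relaxation_context()
  cs <- concentration_series(sim$imaging, seq_imaging(), seq_pd(), ctx)
  mask1 <- array(FALSE, c(2, 2, 1)); mask1[1, 1, 1] <- TRUE
  aif <- sim$truth$aif_curve
  px <- pixelwise_mbf(cs$conc, cs$times_s, aif, mask1)
  direct <- fit_fermi(aif, conc_curve(cs$times_s, cs$conc[1, 1, 1, ],
                                      "tissue"))
  expect_equal(px$mbf_map[1, 1, 1], direct$mbf)
  expect_equal(nrow(px$diagnostics), 1L)
  expect_error(pixelwise_mbf(cs$conc, cs$times_s, aif,
                             array(FALSE, c(2, 2, 1))), "empty mask")

  # two-region 8x8 phantom at SNR 20 (noise at this op's boundary: on the
  # concentration curves, sd = pixel peak / 20): region means within 5%
  set.seed(55)
  mbf_map <- matrix(1.0, 8, 8); mbf_map[, 5:8] <- 3.0
  tt <- seq(2, 49)
  aif2 <- gen_aif(times_s = tt)
  conc <- array(0, c(8, 8, 1, length(tt)))
  for (i in 1:8) for (j in 1:8) {
    tc <- gen_tissue_curve(aif2, mbf_map[i, j])
    conc[i, j, 1, ] <- pmax(tc$values_mmol +
                              rnorm(length(tt), 0,
                                    max(tc$values_mmol) / 20), 0)
  }
  px2 <- pixelwise_mbf(conc, tt, aif2, array(TRUE, c(8, 8, 1)))
  m_lo <- mean(px2$mbf_map[, 1:4, 1], na.rm = TRUE)
  m_hi <- mean(px2$mbf_map[, 5:8, 1], na.rm = TRUE)
  expect_equal(m_lo, 1.0, tolerance = 0.05)
  expect_equal(m_hi, 3.0, tolerance = 0.05)

  # uniform region: map CV bounded by a Monte-Carlo noise prediction from
  # independent single-curve fits at the same level
  tc3 <- gen_tissue_curve(aif2, 3.0)
  mc <- vapply(1:25, function(i) {
    noisy <- pmax(tc3$values_mmol + rnorm(length(tt), 0,
                                          max(tc3$values_mmol) / 20), 0)
    fit_fermi(aif2, conc_curve(tt, noisy, "tissue"))$mbf
  }, numeric(1))
  predicted_cv <- sd(mc) / mean(mc)
  map_cv <- sd(px2$mbf_map[, 5:8, 1]) / m_hi
  expect_lt(map_cv, 1.5 * predicted_cv + 0.02)
})

test_that("global_perfusion averages valid pixels and mpr divides", {
  expect_equal(global_perfusion(c(1, 2, 3)), 2.0)
  expect_equal(global_perfusion(c(1, 2, NA)), 1.5)
  expect_error(global_perfusion(c(NA_real_, NA_real_)), "no valid")
  expect_equal(compute_mpr(3.0, 1.0), 3.0)
  expect_equal(compute_mpr(2.0, 2.0), 1.0)
  expect_error(compute_mpr(2.0, 0), "rest")
})
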