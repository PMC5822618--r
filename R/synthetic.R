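#' Gamma-variate bolus curve
#'
#' Peak-normalized gamma variate: 0 before arrival, then
#' `peak * (tau/(alpha beta))^alpha * exp(alpha - tau/beta)` with
#' `tau = t - t_arrival`, peaking at `tau = alpha beta` with value `peak`.
#' The closed-form area is `peak * exp(alpha) * gamma(alpha+1) * beta /
#' alpha^alpha`.
#'
#' @param t Times, s.
#' @param t_arrival Bolus arrival time, s.
#' @param alpha,beta Gamma-variate shape and scale.
#' @param peak Peak concentration, mmol/L.
#' @return Concentration values, mmol/L.
#' @export
gamma_variate <- function(t, t_arrival, alpha, beta, peak) {
  tau <- t - t_arrival
  y <- numeric(length(t))
  pos <- tau > 0
  y[pos] <- peak * (tau[pos] / (alpha * beta))^alpha *
    exp(alpha - tau[pos] / beta)
  y
}

#' Analytic area under a gamma-variate curve
#' @inheritParams gamma_variate
#' @return Integral of the curve over (t_arrival, Inf), mmol s / L.
#' @export
gamma_variate_auc <- function(alpha, beta, peak) {
  peak * exp(alpha) * gamma(alpha + 1) * beta / alpha^alpha
}

#' Generate a synthetic arterial input function
#'
#' First-pass gamma-variate bolus (emulating a compact ~0.075 mmol/kg
#' contrast injection at 4 ml/s) with an optional dispersed, delayed
#' recirculation bump. Deterministic given its arguments; `seed` is
#' accepted for interface symmetry but the curve itself is noise-free.
#'
#' @param times_s Sample times, s.
#' @param peak Peak blood-pool concentration, mmol/L.
#' @param t_arrival Bolus arrival, s.
#' @param alpha,beta Gamma-variate shape/scale of the first pass.
#' @param recirc_frac Peak fraction of the recirculation bump (0 disables).
#' @param recirc_delay_s Delay of the recirculation bump after arrival, s.
#' @param seed Unused (determinism hook).
#' @return A `conc_curve` of kind `"aif"`.
#' @export
gen_aif <- function(times_s = seq(0, 49, by = 1), peak = 5.0, t_arrival = 5,
                    alpha = 2.5, beta = 1.5, recirc_frac = 0.1,
                    recirc_delay_s = 15, seed = NULL) {
  if (peak <= 0) stop("peak must be > 0")
  v <- gamma_variate(times_s, t_arrival, alpha, beta, peak)
  if (recirc_frac > 0) {
    v <- v + gamma_variate(times_s, t_arrival + recirc_delay_s,
                           alpha, beta * 2, peak * recirc_frac)
  }
  conc_curve(times_s, v, kind = "aif")
}

#' Fermi parameters realizing a target myocardial blood flow
#'
#' Fixes physiologic decay/width/delay and solves the amplitude so that
#' the impulse response at arrival equals `mbf` (see [fermi_mbf()]).
#'
#' @param mbf Target MBF, ml/min/g.
#' @param decay_k,width_w,delay_td Shape parameters (1/s, s, s).
#' @return A `fermi_params`.
#' @export
fermi_for_mbf <- function(mbf, decay_k = 0.5, width_w = 4, delay_td = 1.5) {
  if (mbf <= 0) stop("mbf must be > 0")
  fermi_params(mbf * (1 + exp(-decay_k * width_w)), decay_k, width_w,
               delay_td)
}

#' Synthetic tissue concentration curve at a known flow
#'
#' Convolves the AIF with a Fermi impulse response whose arrival amplitude
#' equals `mbf`, on a fine uniform grid, then samples at the AIF times.
#'
#' @param aif A `conc_curve`.
#' @param mbf True MBF, ml/min/g.
#' @param p Optional explicit `fermi_params` (overrides `mbf`).
#' @param dt_fine_s Fine grid for the forward convolution, s.
#' @param density_g_per_ml Tissue density folded into the kernel.
#' @return A `conc_curve` of kind `"tissue"` at the AIF sample times.
#' @export
gen_tissue_curve <- function(aif, mbf, p = NULL, dt_fine_s = 0.25,
                             density_g_per_ml = 1.05) {
  if (is.null(p)) p <- fermi_for_mbf(mbf)
  fine <- resample_curve(aif, dt_fine_s)
  ct <- model_tissue_curve(fine, p, density_g_per_ml)
  vals <- stats::approx(ct$times_s, ct$values_mmol, xout = aif$times_s,
                        rule = 2)$y
  conc_curve(aif$times_s, vals, kind = "tissue")
}

#' Simulate a dual-sequence dynamic perfusion acquisition
#'
#' Forward-encodes a ground-truth MBF map through the full signal chain:
#' per-pixel tissue concentration (AIF convolved with a Fermi response at
#' the pixel's true MBF), concentration to T1 via 1/T1 = 1/T10 + r1 C,
#' T1 to intensity via the SR pulse-train model, plus 2 leading PD frames;
#' the AIF series is encoded the same way from blood T1 with the
#' low-resolution AIF sequence. Gaussian noise (or Rician, i.e. the
#' magnitude of complex Gaussian noise) is added at the stated SNR, defined
#' as the peak noiseless imaging-frame signal divided by the noise SD.
#'
#' @param mbf_map Matrix or 3D array (x, y\[, slice\]) of true MBF,
#'   ml/min/g; 0 pixels stay at baseline.
#' @param aif A `conc_curve`; default [gen_aif()] on the frame grid.
#' @param seqs List of `sequence_params`: `imaging`, `aif`, `pd`.
#' @param ctx A `relaxation_context`.
#' @param snr Signal-to-noise ratio; `Inf` for noiseless.
#' @param seed Integer seed (mandatory when `snr` is finite).
#' @param n_frames Total frames including the PD frames.
#' @param rr_ms RR interval (frame spacing), ms.
#' @param n_pd Number of leading PD frames.
#' @param noise Noise model.
#' @param aif_dim In-plane size of the synthetic AIF blood-pool series.
#' @return A list: `imaging` and `aif` (`perf_series`), `truth`
#'   (`mbf_map`, `aif_curve`, `fermi_shape`, per-pixel curve generator).
#' @export
gen_dynamic_series <- function(mbf_map, aif = NULL,
                               seqs = list(imaging = seq_imaging(),
                                           aif = seq_aif(), pd = seq_pd()),
                               ctx = relaxation_context(), snr = Inf,
                               seed = NULL, n_frames = 50, rr_ms = 1000,
                               n_pd = 2, noise = c("gaussian", "rician"),
                               aif_dim = 2) {
  noise <- match.arg(noise)
  if (is.finite(snr) && is.null(seed)) {
    stop("seed is mandatory when simulating noise")
  }
  if (is.matrix(mbf_map)) dim(mbf_map) <- c(dim(mbf_map), 1L)
  d <- dim(mbf_map)
  frame_t <- (seq_len(n_frames) - 1) * rr_ms / 1000
  roles <- c(rep("pd", n_pd), rep("imaging", n_frames - n_pd))
  dyn_t <- frame_t[roles != "pd"]
  if (is.null(aif)) aif <- gen_aif(times_s = dyn_t)

  p_shape <- fermi_for_mbf(1)  # shape only; amplitude set per pixel
  # tissue curve is linear in amplitude: compute the unit-MBF curve once
  unit_ct <- gen_tissue_curve(aif, mbf = 1)$values_mmol

  conc_to_t1 <- function(conc, t10) 1000 / (1000 / t10 + ctx$r1 * conc)

  data <- array(0, dim = c(d, n_frames))
  pd_val <- pd_signal(ctx$t10_tissue_ms, seqs$pd)
  nvox <- prod(d)
  mbf_vec <- as.vector(mbf_map)
  sr_dyn <- matrix(0, nvox, length(dyn_t))
  for (v in seq_len(nvox)) {
    conc <- unit_ct * mbf_vec[v]
    sr_dyn[v, ] <- sr_signal(conc_to_t1(conc, ctx$t10_tissue_ms),
                             seqs$imaging)
  }
  data_mat <- matrix(0, nvox, n_frames)
  data_mat[, roles == "pd"] <- pd_val
  data_mat[, roles != "pd"] <- sr_dyn
  peak_sig <- max(sr_dyn)

  aif_t1 <- conc_to_t1(aif$values_mmol, ctx$t10_blood_ms)
  aif_sig <- sr_signal(aif_t1, seqs$aif)
  aif_pd <- pd_signal(ctx$t10_blood_ms, seqs$pd)
  aif_mat <- matrix(0, aif_dim * aif_dim, n_frames)
  aif_mat[, roles == "pd"] <- aif_pd
  aif_mat[, roles != "pd"] <- rep(aif_sig, each = aif_dim * aif_dim)

  if (is.finite(snr)) {
    set.seed(seed)
    sd_n <- peak_sig / snr
    add_noise <- function(m) {
      if (noise == "gaussian") m + stats::rnorm(length(m), 0, sd_n)
      else sqrt((m + stats::rnorm(length(m), 0, sd_n))^2 +
                  stats::rnorm(length(m), 0, sd_n)^2)
    }
    data_mat <- add_noise(data_mat)
    aif_mat <- add_noise(aif_mat)
  }
  dim(data_mat) <- c(d, n_frames)
  imaging <- perf_series(data_mat, frame_t, roles)
  aif_series <- perf_series(array(aif_mat,
                                  dim = c(aif_dim, aif_dim, 1, n_frames)),
                            frame_t, roles)
  list(imaging = imaging, aif = aif_series,
       truth = list(mbf_map = mbf_map, aif_curve = aif,
                    fermi_shape = p_shape,
                    tissue_curve = function(mbf) {
                      conc_curve(dyn_t, unit_ct * mbf, "tissue")
                    }))
}

#' Default two-group cohort specification
#'
#' Group sizes, outcome and covariate distributions shaped like the study
#' design this package emulates: 46 subjects with risk factors for
#' microvascular disease versus 20 healthy controls; rest/stress MBF drawn
#' bivariate-normal with correlation `rs_cor` (MPR = stress/rest);
#' median/IQR-reported quantities converted to mean/SD under normality
#' (SD = IQR/1.349). CAC is a point mass at 0 (prevalence `p_zero`) plus a
#' lognormal tail, generated for the risk group only (controls are not
#' scanned).
#'
#' @return A `cohort_spec` list with `groups` (named per-group parameter
#'   lists) and `floors` (physiologic truncation floors).
#' @export
cohort_spec_default <- function() {
  structure(list(
    groups = list(
      mvd_risk = list(
        n = 46,
        rest_mbf = c(1.15, 0.28), stress_mbf = c(2.65, 0.62), rs_cor = 0.5,
        age = c(57.5, 11.2), bmi = c(31.3, 6.0), female_p = 0.74,
        lv_mass = c(79, 23), lvef = c(61.2, 6.7),
        native_t1 = c(988, 42), ecv_pct = c(26.6, 2.9),
        hct = c(0.41, 0.03),
        diabetes_p = 0.80, smoking_p = 0.54, htn_p = 0.80, hld_p = 0.87,
        # zero-inflated lognormal calibrated to the reported prevalences:
        # 57% score < 1 and 28% score > 10 Agatston units
        cac = list(p_zero = 0.57, meanlog = log(18), sdlog = 1.5)),
      control = list(
        n = 20,
        rest_mbf = c(1.10, 0.23), stress_mbf = c(3.17, 0.49), rs_cor = 0.5,
        age = c(53.4, 11.9), bmi = c(24.3, 3.6), female_p = 0.60,
        lv_mass = c(71, 24), lvef = c(59.7, 4.3),
        native_t1 = c(987, 35), ecv_pct = c(27.1, 2.2),
        hct = c(0.42, 0.03),
        diabetes_p = 0.00, smoking_p = 0.05, htn_p = 0.05, hld_p = 0.05,
        cac = NULL)),
    floors = list(rest_mbf = 0.3, stress_mbf = 0.5, age = 18, bmi = 15,
                  lv_mass = 30, lvef = 20, native_t1 = 600, ecv_pct = 10,
                  hct = 0.2)),
    class = "cohort_spec")
}

#' Generate a two-group synthetic cohort with ground truth
#'
#' Per-subject draws: bivariate normal (rest, stress) MBF with the group's
#' correlation, normal covariates truncated at physiologic floors,
#' Bernoulli flags, and a zero-inflated lognormal CAC where specified.
#' MPR is stress/rest by construction. Byte-identical output under a fixed
#' seed.
#'
#' @param spec A `cohort_spec`; see [cohort_spec_default()].
#' @param seed Integer seed.
#' @return A list: `table` (data.frame, one row per subject) and `truth`
#'   (data.frame of the generating per-subject values).
#' @export
gen_cohort <- function(spec = cohort_spec_default(), seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  floors <- spec$floors
  tnorm <- function(n, ms, floor_val) {
    pmax(stats::rnorm(n, ms[1], ms[2]), floor_val)
  }
  rows <- list()
  for (g in names(spec$groups)) {
    gp <- spec$groups[[g]]
    n <- gp$n
    if (n == 0) next
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    rho <- gp$rs_cor
    rest <- gp$rest_mbf[1] + gp$rest_mbf[2] * z1
    stress <- gp$stress_mbf[1] +
      gp$stress_mbf[2] * (rho * z1 + sqrt(1 - rho^2) * z2)
    rest <- pmax(rest, floors$rest_mbf)
    stress <- pmax(stress, floors$stress_mbf)
    cac <- rep(NA_real_, n)
    if (!is.null(gp$cac)) {
      zero <- stats::runif(n) < gp$cac$p_zero
      cac <- ifelse(zero, 0,
                    stats::rlnorm(n, gp$cac$meanlog, gp$cac$sdlog))
    }
    rows[[g]] <- data.frame(
      subject_id = sprintf("%s_%03d", g, seq_len(n)),
      group = g,
      age = tnorm(n, gp$age, floors$age),
      female = stats::runif(n) < gp$female_p,
      bmi = tnorm(n, gp$bmi, floors$bmi),
      diabetes = stats::runif(n) < gp$diabetes_p,
      htn = stats::runif(n) < gp$htn_p,
      hld = stats::runif(n) < gp$hld_p,
      smoking = stats::runif(n) < gp$smoking_p,
      lv_mass = tnorm(n, gp$lv_mass, floors$lv_mass),
      lvef = tnorm(n, gp$lvef, floors$lvef),
      rest_mbf = rest, stress_mbf = stress, mpr = stress / rest,
      native_t1 = tnorm(n, gp$native_t1, floors$native_t1),
      ecv = tnorm(n, gp$ecv_pct, floors$ecv_pct) / 100,
      hct = pmin(pmax(stats::rnorm(n, gp$hct[1], gp$hct[2]), floors$hct),
                 0.6),
      cac = cac)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  truth <- table[, c("subject_id", "group", "rest_mbf", "stress_mbf",
                     "mpr", "native_t1", "ecv", "hct", "cac")]
  names(truth) <- c("subject_id", "group", "true_rest_mbf",
                    "true_stress_mbf", "true_mpr", "true_native_t1",
                    "true_ecv", "true_hct", "true_cac")
  truth$true_lambda <- truth$true_ecv / (1 - truth$true_hct)
  list(table = table, truth = truth)
}

#' Simulate MOLLI magnitude samples at a known T1
#'
#' Signed relaxation model `A - B exp(-TI/T1*)` with the apparent time
#' constant `T1* = T1 / (B/A - 1)` so the Look-Locker-corrected fit
#' recovers `t1_ms` exactly in the noiseless limit; the returned signals
#' are magnitudes.
#'
#' @param t1_ms True T1, ms.
#' @param inversion_times_ms Sampling scheme (default [molli_scheme_543()]).
#' @param a,b Model coefficients (B/A > 1 encodes inversion efficiency and
#'   readout-driven recovery).
#' @param noise_sd Gaussian noise SD on the signed signal before the
#'   magnitude (0 = noiseless).
#' @param seed Integer seed (mandatory when `noise_sd > 0`).
#' @return A `molli_samples`.
#' @export
gen_molli_samples <- function(t1_ms, inversion_times_ms = molli_scheme_543(),
                              a = 0.85, b = 1.8, noise_sd = 0, seed = NULL) {
  if (t1_ms <= 0) stop("t1_ms must be > 0")
  if (b / a <= 1) stop("b/a must exceed 1 for a valid Look-Locker model")
  t1_star <- t1_ms / (b / a - 1)
  sig <- a - b * exp(-inversion_times_ms / t1_star)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed is mandatory when simulating noise")
    set.seed(seed)
    sig <- sig + stats::rnorm(length(sig), 0, noise_sd)
  }
  molli_samples(inversion_times_ms, abs(sig))
}

#' Simulate serial T1 pairs at a known partition coefficient
#'
#' Blood relaxation rates are spread from native to a post-contrast level;
#' myocardial rates follow 1/T1_myo = lambda / T1_blood + intercept, with
#' optional Gaussian jitter on the rates.
#'
#' @param lambda True partition coefficient.
#' @param t10_myo_ms,t10_blood_ms Native T1s, ms.
#' @param post_r1_blood Post-contrast blood relaxation rates, 1/ms.
#' @param jitter_sd Gaussian SD added to both rates (1/ms).
#' @param seed Integer seed (mandatory when `jitter_sd > 0`).
#' @return Data frame: `timepoint`, `t1_myo`, `t1_blood`.
#' @export
gen_t1_pairs <- function(lambda, t10_myo_ms = 1100, t10_blood_ms = 1650,
                         post_r1_blood = c(1.8, 2.6, 3.2) / 1000,
                         jitter_sd = 0, seed = NULL) {
  r1b <- c(1 / t10_blood_ms, post_r1_blood)
  intercept <- 1 / t10_myo_ms - lambda / t10_blood_ms
  r1m <- lambda * r1b + intercept
  if (jitter_sd > 0) {
    if (is.null(seed)) stop("seed is mandatory when simulating noise")
    set.seed(seed)
    r1b <- r1b + stats::rnorm(length(r1b), 0, jitter_sd)
    r1m <- r1m + stats::rnorm(length(r1m), 0, jitter_sd)
  }
  data.frame(timepoint = c("native", "post1", "post2", "post3"),
             t1_myo = 1 / r1m, t1_blood = 1 / r1b)
}

#' Simulate a non-contrast CT phantom with calcified lesions
#'
#' Uniform soft-tissue background with square-ish lesions of exact pixel
#' areas placed on given slices; optional Gaussian HU noise.
#'
#' @param dims Volume dimensions (x, y, slices).
#' @param pixel_spacing_mm In-plane spacing, mm.
#' @param slice_thickness_mm Slice thickness, mm.
#' @param lesions Data frame: `slice`, `x`, `y` (top-left corner),
#'   `n_pixels`, `hu`. Empty for a lesion-free phantom.
#' @param background_hu Background attenuation, HU.
#' @param noise_sd Gaussian HU noise SD.
#' @param seed Integer seed (mandatory when `noise_sd > 0`).
#' @return A `ct_volume`.
#' @export
gen_ct_phantom <- function(dims = c(64, 64, 4), pixel_spacing_mm = c(1, 1),
                           slice_thickness_mm = 3,
                           lesions = data.frame(slice = integer(),
                                                x = integer(), y = integer(),
                                                n_pixels = integer(),
                                                hu = numeric()),
                           background_hu = 40, noise_sd = 0, seed = NULL) {
  vox <- array(background_hu, dim = dims)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed is mandatory when simulating noise")
    set.seed(seed)
    vox <- vox + array(stats::rnorm(prod(dims), 0, noise_sd), dim = dims)
  }
  for (i in seq_len(nrow(lesions))) {
    le <- lesions[i, ]
    side <- ceiling(sqrt(le$n_pixels))
    placed <- 0
    for (dy in 0:(side - 1)) {
      for (dx in 0:(side - 1)) {
        if (placed >= le$n_pixels) break
        vox[le$x + dx, le$y + dy, le$slice] <- le$hu
        placed <- placed + 1
      }
    }
  }
  ct_volume(vox, pixel_spacing_mm, slice_thickness_mm)
}
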