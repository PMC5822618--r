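#' Time-stamped gadolinium concentration curve
#'
#' The currency of deconvolution: a blood-pool (AIF) or tissue concentration
#' curve sampled at the (possibly non-uniform) frame times of the dynamic
#' acquisition.
#'
#' @param times_s Sample times in seconds, strictly increasing.
#' @param values_mmol Concentrations in mmol/L, finite.
#' @param kind `"aif"` or `"tissue"`.
#' @return An object of class `conc_curve`.
#' @export
conc_curve <- function(times_s, values_mmol, kind = c("tissue", "aif")) {
  kind <- match.arg(kind)
  if (length(times_s) != length(values_mmol)) {
    stop("times_s and values_mmol must have the same length")
  }
  if (any(diff(times_s) <= 0)) stop("times_s must be strictly increasing")
  if (any(!is.finite(values_mmol))) stop("values_mmol must be finite")
  structure(list(times_s = as.numeric(times_s),
                 values_mmol = as.numeric(values_mmol), kind = kind),
            class = "conc_curve")
}

#' Fermi impulse-response parameters
#'
#' The impulse response of the Fermi deconvolution model,
#' R(t) = F / (1 + exp(k (t - td - w))) for t >= td (0 before td).
#' Myocardial blood flow is the amplitude of the response at contrast
#' arrival, MBF = R(td+) = F / (1 + exp(-k w)).
#'
#' @param amplitude_f Plateau amplitude F, ml/min/g; > 0.
#' @param decay_k Decay rate k, 1/s; >= 0.
#' @param width_w Plateau width w, s; >= 0.
#' @param delay_td Bolus arrival delay td, s; in \[0, max_delay\].
#' @param max_delay Upper bound on the delay, s.
#' @return An object of class `fermi_params`.
#' @export
fermi_params <- function(amplitude_f, decay_k, width_w, delay_td,
                         max_delay = 5) {
  if (amplitude_f <= 0) stop("amplitude_f must be > 0")
  if (decay_k < 0) stop("decay_k must be >= 0")
  if (width_w < 0) stop("width_w must be >= 0")
  if (delay_td < 0 || delay_td > max_delay) {
    stop(sprintf("delay_td must lie in [0, %g] s", max_delay))
  }
  structure(list(amplitude_f = amplitude_f, decay_k = decay_k,
                 width_w = width_w, delay_td = delay_td),
            class = "fermi_params")
}

#' Fermi impulse response
#'
#' @param t Times in seconds (vectorized); values before the delay return 0.
#' @param p A `fermi_params`.
#' @return R(t) in ml/min/g.
#' @export
fermi_irf <- function(t, p) {
  stopifnot(inherits(p, "fermi_params"))
  r <- p$amplitude_f / (1 + exp(p$decay_k * (t - p$delay_td - p$width_w)))
  r[t < p$delay_td] <- 0
  r
}

#' Myocardial blood flow implied by a Fermi impulse response
#'
#' MBF = R(td+), the impulse-response amplitude at bolus arrival.
#'
#' @param p A `fermi_params`.
#' @return MBF in ml/min/g.
#' @export
fermi_mbf <- function(p) {
  stopifnot(inherits(p, "fermi_params"))
  p$amplitude_f / (1 + exp(-p$decay_k * p$width_w))
}

#' Resample a concentration curve to a uniform grid
#'
#' Linear interpolation onto a uniform grid starting at the first sample;
#' heart-rate variation makes raw frame times non-uniform.
#'
#' @param curve A `conc_curve`.
#' @param dt_s Grid step, s.
#' @return A `conc_curve` on the uniform grid.
#' @export
resample_curve <- function(curve, dt_s = 0.5) {
  stopifnot(inherits(curve, "conc_curve"))
  t0 <- curve$times_s[1]
  t1 <- curve$times_s[length(curve$times_s)]
  grid <- seq(t0, t1, by = dt_s)
  vals <- stats::approx(curve$times_s, curve$values_mmol, xout = grid,
                        rule = 2)$y
  conc_curve(grid, vals, kind = curve$kind)
}

#' Forward model: tissue curve from AIF and Fermi impulse response
#'
#' Discrete convolution of the AIF with the Fermi impulse response on a
#' uniform grid, C_t(t_i) = dt * sum_j AIF(t_j) R(t_i - t_j) * dens / 60.
#' The factor 60 converts the ml/min/g response to a per-second kernel and
#' `density_g_per_ml` folds tissue density into the kernel scale.
#'
#' @param aif A `conc_curve` on a uniform grid (see [resample_curve()]).
#' @param p A `fermi_params`.
#' @param density_g_per_ml Tissue density folded into the kernel, g/ml.
#' @return A `conc_curve` of kind `"tissue"` on the same grid.
#' @export
model_tissue_curve <- function(aif, p, density_g_per_ml = 1.05) {
  stopifnot(inherits(aif, "conc_curve"))
  dts <- diff(aif$times_s)
  dt <- dts[1]
  if (length(dts) && any(abs(dts - dt) > 1e-9 * max(dt, 1))) {
    stop("internal error: AIF grid is not uniform; resample first")
  }
  n <- length(aif$values_mmol)
  rel <- aif$times_s - aif$times_s[1]
  r <- fermi_irf(rel, p) * density_g_per_ml / 60
  ct <- convolve_discrete(aif$values_mmol, r, dt)
  conc_curve(aif$times_s, ct[seq_len(n)], kind = "tissue")
}

# trapezoid-rule discrete convolution:
# out_i = dt * (sum_{j=1..i} a_j b_{i-j+1} - (a_1 b_i + a_i b_1)/2)
convolve_discrete <- function(a, b, dt) {
  n <- length(a)
  full <- stats::convolve(a, rev(b), type = "open")[seq_len(n)]
  dt * (full - 0.5 * (a[1] * b + a * b[1]))
}

#' Fit the Fermi deconvolution model to a tissue curve
#'
#' Bounded nonlinear least squares of the convolution model
#' AIF (x) R_fermi against an observed tissue curve, restricted to the
#' first-pass window of the AIF. The impulse response is zero before the
#' delay, so the objective is discontinuous in `delay_td`: the delay is
#' profiled over a discrete grid (step `dt_s`) and, at each delay, the
#' smooth inner problem over (amplitude, decay, width) is solved by
#' deterministic multi-start L-BFGS-B. Ties in residual are broken toward
#' the smallest delay.
#'
#' The convolution is computed on a fine uniform grid (step `dt_s`) using
#' the linearly-interpolated AIF, and the residual is evaluated at the
#' tissue curve's own sample times — the observed frames are never
#' interpolated. The first-pass window runs from bolus arrival (first
#' sample where the AIF exceeds `arrival_frac` of its peak) to the AIF's
#' post-peak minimum before recirculation, or `max_window_s` after
#' arrival, whichever is first.
#'
#' @param aif,tissue `conc_curve`s sharing time support (>= 10 samples
#'   each).
#' @param bounds Named list of `c(lower, upper)` for `amplitude_f`
#'   (ml/min/g), `decay_k` (1/s), `width_w` (s), `delay_td` (s);
#'   physiologic defaults regularize the ill-posed deconvolution.
#' @param n_starts Number of deterministic starting points.
#' @param dt_s Uniform convolution grid step and delay-profile step, s.
#' @param arrival_frac AIF peak fraction defining bolus arrival.
#' @param max_window_s Cap on the first-pass window length, s.
#' @param density_g_per_ml Passed to [model_tissue_curve()].
#' @param window Set `FALSE` to fit over the whole curve.
#' @return A list: `params` (`fermi_params`), `mbf` (ml/min/g), `residual`
#'   (root-mean-square, mmol/L), `converged`, `valid`, `degenerate`,
#'   `window` (fitted time range, s).
#' @export
fit_fermi <- function(aif, tissue,
                      bounds = fermi_default_bounds(),
                      n_starts = 5, dt_s = 0.25, arrival_frac = 0.1,
                      max_window_s = 25, density_g_per_ml = 1.05,
                      window = TRUE) {
  stopifnot(inherits(aif, "conc_curve"), inherits(tissue, "conc_curve"))
  if (length(aif$times_s) < 10 || length(tissue$times_s) < 10) {
    stop("curves need at least 10 samples for fitting")
  }
  a <- resample_curve(aif, dt_s)
  fidx <- if (window) first_pass_window(a, arrival_frac, max_window_s)
          else seq_along(a$times_s)
  t_lo <- a$times_s[fidx[1]]
  t_hi <- a$times_s[fidx[length(fidx)]]
  obs_idx <- which(tissue$times_s >= t_lo & tissue$times_s <= t_hi)
  if (length(obs_idx) < 5) obs_idx <- seq_along(tissue$times_s)
  obs_t <- tissue$times_s[obs_idx]
  obs <- tissue$values_mmol[obs_idx]

  degenerate <- max(obs) <= 0 || max(a$values_mmol) <= 0
  f_lo <- bounds$amplitude_f[1]; f_hi <- bounds$amplitude_f[2]
  lo <- c(bounds$decay_k[1], bounds$width_w[1])
  hi <- c(bounds$decay_k[2], bounds$width_w[2])
  td_grid <- seq(bounds$delay_td[1], bounds$delay_td[2], by = dt_s)

  # convolution grid truncated at the window end; the trapezoid-rule
  # convolution against the fixed AIF is a lower-triangular Toeplitz
  # operator, precomputed once per fit
  ng <- which(a$times_s <= t_hi + dt_s)
  gt <- a$times_s[ng]
  av <- a$values_mmol[ng]
  n <- length(av)
  rel <- gt - gt[1]
  cmat <- matrix(0, n, n)
  for (j in seq_len(n)) cmat[j:n, j] <- av[seq_len(n - j + 1L)]
  diag(cmat) <- diag(cmat) - 0.5 * av[1]
  cmat[, 1] <- cmat[, 1] - 0.5 * av
  cmat <- cmat * dt_s * density_g_per_ml / 60
  # linear-interpolation weights from the fine grid to the frame times
  pos <- pmin(pmax((obs_t - gt[1]) / dt_s, 0), n - 1)
  i0 <- pmin(floor(pos) + 1L, n - 1L)
  wfr <- pos - (i0 - 1L)

  # unit-amplitude model prediction at the observed frame times
  pred_unit <- function(kw, td) {
    r <- 1 / (1 + exp(kw[1] * (rel - td - kw[2])))
    r[rel < td] <- 0
    m <- drop(cmat %*% r)
    m[i0] * (1 - wfr) + m[i0 + 1L] * wfr
  }
  # model is linear in amplitude: profile F analytically within its bounds
  profile_f <- function(p1) {
    den <- sum(p1 * p1)
    if (den <= 0) return(f_lo)
    min(max(sum(p1 * obs) / den, f_lo), f_hi)
  }
  obj_at <- function(kw, td) {
    p1 <- pred_unit(kw, td)
    f <- profile_f(p1)
    sum((f * p1 - obs)^2)
  }

  starts <- fermi_starts(n_starts, lo, hi)
  best <- NULL
  warm <- NULL
  any_conv <- FALSE
  for (ti in seq_along(td_grid)) {
    td <- td_grid[ti]
    # all heuristic starts at the first delay; afterwards warm-start from
    # the previous delay's solution plus the primary heuristic
    cand <- if (ti == 1L) starts else rbind(warm, starts[1, , drop = FALSE])
    for (s in seq_len(nrow(cand))) {
      fit <- tryCatch(
        stats::optim(cand[s, ], obj_at, td = td, method = "L-BFGS-B",
                     lower = lo, upper = hi,
                     control = list(maxit = 200, factr = 1e7)),
        error = function(e) NULL)
      if (is.null(fit)) next
      any_conv <- any_conv || fit$convergence == 0
      if (s == 1L || is.null(warm)) warm <- fit$par
      # td grid is ascending, so strict improvement keeps the smallest delay
      if (is.null(best) || fit$value < best$value - 1e-12) {
        best <- fit
        best$td <- td
        warm <- fit$par
      }
    }
  }
  if (is.null(best)) {
    return(list(params = NULL, mbf = NA_real_, residual = NA_real_,
                converged = FALSE, valid = FALSE, degenerate = degenerate,
                window = c(t_lo, t_hi)))
  }
  best$par <- pmin(pmax(best$par, lo), hi)  # guard optimizer round-off
  f_best <- profile_f(pred_unit(best$par, best$td))
  p <- fermi_params(f_best, best$par[1], best$par[2], best$td,
                    max_delay = bounds$delay_td[2])
  pinned_low <- abs(f_best - f_lo) < 1e-9
  list(params = p,
       mbf = fermi_mbf(p),
       residual = sqrt(best$value / length(obs_idx)),
       converged = any_conv,
       valid = any_conv && !degenerate,
       degenerate = degenerate || pinned_low,
       window = c(t_lo, t_hi))
}

#' Default physiologic constraint box for the Fermi fit
#' @return Named list of `c(lower, upper)` bounds.
#' @export
fermi_default_bounds <- function() {
  list(amplitude_f = c(0.05, 8), decay_k = c(0, 5),
       width_w = c(0, 30), delay_td = c(0, 5))
}

# deterministic multi-start grid over (decay, width); the amplitude is
# profiled analytically inside the objective
fermi_starts <- function(n_starts, lo, hi) {
  cand <- rbind(
    c(0.5,  4),
    c(0.25, 10),
    c(1.0,  2),
    c(0.1,  15),
    c(2.0,  1),
    c(0.75, 8),
    c(0.4,  4))
  cand <- cand[seq_len(min(n_starts, nrow(cand))), , drop = FALSE]
  for (k in 1:2) cand[, k] <- pmin(pmax(cand[, k], lo[k]), hi[k])
  cand
}

#' First-pass window of an AIF on a uniform grid
#'
#' @param aif A uniform-grid `conc_curve`.
#' @param arrival_frac Fraction of peak defining bolus arrival.
#' @param max_window_s Maximum window length after arrival, s.
#' @return Integer index vector into the AIF grid.
#' @export
first_pass_window <- function(aif, arrival_frac = 0.1, max_window_s = 25) {
  v <- aif$values_mmol
  pk <- max(v)
  if (pk <= 0) return(seq_along(v))
  start <- which(v >= arrival_frac * pk)[1]
  ipk <- which.max(v)
  end <- length(v)
  if (ipk < length(v) - 1) {
    post <- v[(ipk + 1):length(v)]
    rising <- which(diff(post) > 0)
    if (length(rising)) end <- ipk + rising[1]
  }
  dt <- aif$times_s[2] - aif$times_s[1]
  end <- min(end, start + round(max_window_s / dt))
  seq.int(start, max(end, start + 9))
}

#' Pixel-wise myocardial blood flow map
#'
#' Applies [fit_fermi()] to every masked pixel of a concentration series.
#' Invalid fits are `NA` in the map and flagged in the diagnostics; they are
#' excluded from downstream statistics.
#'
#' @param conc 4D concentration array (x, y, slice, frame), mmol/L.
#' @param times_s Frame times, s.
#' @param aif A `conc_curve` of kind `"aif"`.
#' @param mask Logical array (x, y, slice); must select >= 1 pixel.
#' @param ... Passed to [fit_fermi()].
#' @return A list: `mbf_map` (x, y, slice; `NA` outside mask / invalid),
#'   `diagnostics` (data.frame: x, y, slice, mbf, residual, converged,
#'   valid, degenerate).
#' @export
pixelwise_mbf <- function(conc, times_s, aif, mask, ...) {
  d <- dim(conc)
  if (is.null(dim(mask))) dim(mask) <- d[1:3]
  if (!any(mask)) stop("empty mask")
  which_idx <- which(mask, arr.ind = TRUE)
  if (ncol(which_idx) == 2) which_idx <- cbind(which_idx, 1L)
  mbf_map <- array(NA_real_, dim = d[1:3])
  diag_rows <- vector("list", nrow(which_idx))
  for (i in seq_len(nrow(which_idx))) {
    px <- which_idx[i, ]
    vals <- conc[px[1], px[2], px[3], ]
    if (any(is.na(vals))) {
      diag_rows[[i]] <- data.frame(x = px[1], y = px[2], slice = px[3],
                                   mbf = NA_real_, residual = NA_real_,
                                   converged = FALSE, valid = FALSE,
                                   degenerate = TRUE)
      next
    }
    fit <- fit_fermi(aif, conc_curve(times_s, vals, "tissue"), ...)
    if (fit$valid) mbf_map[px[1], px[2], px[3]] <- fit$mbf
    diag_rows[[i]] <- data.frame(x = px[1], y = px[2], slice = px[3],
                                 mbf = fit$mbf, residual = fit$residual,
                                 converged = fit$converged,
                                 valid = fit$valid,
                                 degenerate = fit$degenerate)
  }
  list(mbf_map = mbf_map, diagnostics = do.call(rbind, diag_rows))
}

#' Global perfusion from an MBF map
#'
#' Mean MBF over valid (non-`NA`) masked pixels across all slices.
#'
#' @param mbf_map Numeric array from [pixelwise_mbf()].
#' @param mask Optional logical array; defaults to all non-`NA` pixels.
#' @return Global MBF, ml/min/g.
#' @export
global_perfusion <- function(mbf_map, mask = NULL) {
  v <- if (is.null(mask)) as.vector(mbf_map) else as.vector(mbf_map)[as.vector(mask)]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no valid pixels in MBF map")
  mean(v)
}

#' Myocardial perfusion reserve
#'
#' MPR = stress MBF / rest MBF.
#'
#' @param stress_mbf,rest_mbf Global MBF values, ml/min/g.
#' @return Dimensionless MPR.
#' @export
compute_mpr <- function(stress_mbf, rest_mbf) {
  if (rest_mbf <= 0) stop("rest MBF must be > 0")
  stress_mbf / rest_mbf
}

#' Quantify one dynamic perfusion acquisition
#'
#' Full inverse chain for one subject at one physiologic state: converts
#' imaging and AIF series to concentration, extracts the blood-pool AIF as
#' the ROI-mean curve, and runs the pixel-wise Fermi deconvolution over the
#' myocardial mask.
#'
#' @param imaging,aif_series `perf_series` objects for the imaging and AIF
#'   acquisitions.
#' @param myo_mask Logical array (x, y, slice) of myocardium.
#' @param aif_mask Optional logical array for the AIF blood pool (defaults
#'   to all valid AIF pixels).
#' @param seqs List with `imaging`, `aif`, `pd` `sequence_params`.
#' @param ctx A `relaxation_context`.
#' @param global_mode `"pixel_mean"` (mean of pixel-wise MBFs, default) or
#'   `"roi_curve"` (single fit of the ROI-mean tissue curve).
#' @param ... Passed to [fit_fermi()].
#' @return A list: `global_mbf`, `mbf_map`, `diagnostics`, `aif_curve`,
#'   `n_valid_pixels`.
#' @export
quantify_perfusion <- function(imaging, aif_series, myo_mask,
                               aif_mask = NULL,
                               seqs = list(imaging = seq_imaging(),
                                           aif = seq_aif(), pd = seq_pd()),
                               ctx = relaxation_context(),
                               global_mode = c("pixel_mean", "roi_curve"),
                               ...) {
  global_mode <- match.arg(global_mode)
  cs_aif <- concentration_series(aif_series, seqs$aif, seqs$pd, ctx,
                                 t10_ms = ctx$t10_blood_ms)
  if (is.null(aif_mask)) aif_mask <- cs_aif$valid
  aif_vals <- apply(cs_aif$conc, 4, function(fr) mean(fr[aif_mask]))
  aif <- conc_curve(cs_aif$times_s, aif_vals, kind = "aif")

  cs <- concentration_series(imaging, seqs$imaging, seqs$pd, ctx,
                             t10_ms = ctx$t10_tissue_ms)
  if (global_mode == "roi_curve") {
    roi_vals <- apply(cs$conc, 4, function(fr) mean(fr[myo_mask]))
    fit <- fit_fermi(aif, conc_curve(cs$times_s, roi_vals, "tissue"), ...)
    return(list(global_mbf = fit$mbf, mbf_map = NULL,
                diagnostics = data.frame(mbf = fit$mbf,
                                         residual = fit$residual,
                                         converged = fit$converged,
                                         valid = fit$valid,
                                         degenerate = fit$degenerate),
                aif_curve = aif, n_valid_pixels = sum(myo_mask)))
  }
  px <- pixelwise_mbf(cs$conc, cs$times_s, aif, myo_mask & cs$valid, ...)
  list(global_mbf = global_perfusion(px$mbf_map),
       mbf_map = px$mbf_map, diagnostics = px$diagnostics,
       aif_curve = aif,
       n_valid_pixels = sum(!is.na(px$mbf_map)))
}
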