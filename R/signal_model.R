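#' Sequence parameters for a spoiled-gradient-echo acquisition
#'
#' Describes one of the three acquisitions of a dual-sequence first-pass
#' perfusion protocol: the saturation-recovery (SR) imaging readout, the
#' low-resolution SR arterial-input-function (AIF) readout, and the
#' unsaturated proton-density (PD) reference frames.
#'
#' @param sr_time_ms Saturation-recovery time in ms: delay from the
#'   saturation pulse to the first radiofrequency pulse of the readout.
#'   `NA` for the PD acquisition (no saturation pulse).
#' @param tr_ms Repetition time of the readout pulse train, ms.
#' @param flip_angle_deg Readout flip angle, degrees; must lie in (0, 90).
#' @param n_pulses_to_center Number of RF pulses up to and including the one
#'   that acquires the k-space center; >= 1.
#' @param readout_duration_ms Duration of one readout, ms (bookkeeping only).
#' @return An object of class `sequence_params`.
#' @seealso [seq_imaging()], [seq_aif()], [seq_pd()] for the protocol
#'   defaults; [sr_signal()] and [pd_signal()] for the signal model.
#' @export
sequence_params <- function(sr_time_ms = NA_real_, tr_ms, flip_angle_deg,
                            n_pulses_to_center = 1L,
                            readout_duration_ms = NA_real_) {
  if (!is.na(sr_time_ms) && sr_time_ms < 0) {
    stop("sr_time_ms must be >= 0 (or NA for a PD acquisition)")
  }
  if (tr_ms <= 0) stop("tr_ms must be > 0")
  if (flip_angle_deg <= 0 || flip_angle_deg >= 90) {
    stop("flip_angle_deg must lie strictly between 0 and 90 degrees")
  }
  n_pulses_to_center <- as.integer(n_pulses_to_center)
  if (n_pulses_to_center < 1L) stop("n_pulses_to_center must be >= 1")
  structure(
    list(sr_time_ms = sr_time_ms, tr_ms = tr_ms,
         flip_angle_deg = flip_angle_deg,
         n_pulses_to_center = n_pulses_to_center,
         readout_duration_ms = readout_duration_ms),
    class = "sequence_params")
}

#' Default protocol sequences
#'
#' The imaging readout is an SR-prepared spiral with 8 interleaves; the
#' k-space center is reached at interleave 4 (interleave count / 2). The AIF
#' readout is single-shot (center at pulse 1). The PD frames share the
#' imaging readout but use a low flip angle and no saturation pulse.
#'
#' @return A `sequence_params` object.
#' @export
seq_imaging <- function() {
  sequence_params(sr_time_ms = 80, tr_ms = 9, flip_angle_deg = 30,
                  n_pulses_to_center = 4L, readout_duration_ms = 6.1)
}

#' @rdname seq_imaging
#' @export
seq_aif <- function() {
  sequence_params(sr_time_ms = 20, tr_ms = 9, flip_angle_deg = 45,
                  n_pulses_to_center = 1L, readout_duration_ms = 6.1)
}

#' @rdname seq_imaging
#' @export
seq_pd <- function() {
  sequence_params(sr_time_ms = NA_real_, tr_ms = 9, flip_angle_deg = 10,
                  n_pulses_to_center = 4L, readout_duration_ms = 6.1)
}

#' Relaxation context for signal-to-concentration conversion
#'
#' Pre-contrast longitudinal relaxation times and the contrast-agent
#' relaxivity linking gadolinium concentration to relaxation rate via
#' 1/T1 = 1/T10 + r1 * C.
#'
#' Defaults are literature-typical 1.5 T values for myocardium, blood and a
#' gadopentetate agent; they are configuration, not measured ground truth.
#'
#' @param t10_tissue_ms Native (pre-contrast) tissue T1, ms.
#' @param t10_blood_ms Native blood T1, ms.
#' @param r1 Longitudinal relaxivity, L mmol^-1 s^-1.
#' @return An object of class `relaxation_context`.
#' @export
relaxation_context <- function(t10_tissue_ms = 1100, t10_blood_ms = 1650,
                               r1 = 4.3) {
  if (t10_tissue_ms <= 0 || t10_blood_ms <= 0 || r1 <= 0) {
    stop("relaxation_context fields must all be strictly positive")
  }
  structure(list(t10_tissue_ms = t10_tissue_ms, t10_blood_ms = t10_blood_ms,
                 r1 = r1),
            class = "relaxation_context")
}

#' Saturation-recovery spoiled-GRE signal
#'
#' Longitudinal-recurrence pulse-train simulation with ideal spoiling.
#' Starting from Mz = 0 at the saturation pulse, magnetization recovers for
#' `sr_time_ms`, then each readout pulse tips Mz by the flip angle and the
#' remainder recovers over one TR:
#' Mz <- (Mz cos a) E1 + M0 (1 - E1), with E1 = exp(-TR/T1).
#' The returned signal is Mz at the pulse acquiring the k-space center,
#' times sin(a). M0 = 1; PD normalization cancels the scale.
#'
#' @param t1_ms Longitudinal relaxation time(s), ms; vectorized.
#' @param seq A `sequence_params` with a non-missing `sr_time_ms`.
#' @param m0 Equilibrium magnetization (arbitrary units).
#' @return Dimensionless signal, same length as `t1_ms`.
#' @export
sr_signal <- function(t1_ms, seq, m0 = 1) {
  stopifnot(inherits(seq, "sequence_params"))
  if (is.na(seq$sr_time_ms)) stop("sr_signal needs a saturation-prepared sequence")
  if (any(t1_ms <= 0)) stop("t1_ms must be strictly positive")
  a <- seq$flip_angle_deg * pi / 180
  e1 <- exp(-seq$tr_ms / t1_ms)
  mz <- m0 * (1 - exp(-seq$sr_time_ms / t1_ms))
  n <- seq$n_pulses_to_center
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      mz <- mz * cos(a) * e1 + m0 * (1 - e1)
    }
  }
  mz * sin(a)
}

#' Proton-density-weighted spoiled-GRE signal
#'
#' Same pulse-train recurrence as [sr_signal()] but starting from fully
#' relaxed magnetization (no saturation pulse). At a low flip angle the
#' result is nearly independent of T1 — the proton-density weighting that
#' makes the PD frames usable as a normalization reference.
#'
#' @inheritParams sr_signal
#' @param seq A `sequence_params` with `sr_time_ms = NA`.
#' @return Dimensionless signal, same length as `t1_ms`.
#' @export
pd_signal <- function(t1_ms, seq, m0 = 1) {
  stopifnot(inherits(seq, "sequence_params"))
  if (!is.na(seq$sr_time_ms)) stop("pd_signal expects a sequence without a saturation pulse")
  if (any(t1_ms <= 0)) stop("t1_ms must be strictly positive")
  a <- seq$flip_angle_deg * pi / 180
  e1 <- exp(-seq$tr_ms / t1_ms)
  mz <- rep_len(m0, length(t1_ms))
  n <- seq$n_pulses_to_center
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      mz <- mz * cos(a) * e1 + m0 * (1 - e1)
    }
  }
  mz * sin(a)
}

#' Normalize SR frames by the PD reference
#'
#' Pixel-wise ratio of each saturation-recovery frame to the mean of the
#' proton-density frames. Pixels whose mean PD signal falls below
#' `pd_floor_frac` times the median PD signal (air / no-signal regions) are
#' marked invalid and returned as `NA`.
#'
#' @param sr_frames Numeric array, spatial dims first and frames last
#'   (e.g. x,y,frame or x,y,slice,frame).
#' @param pd_frames Numeric array with the same spatial dims; one or more
#'   PD frames in the last dimension.
#' @param pd_floor_frac Noise-floor mask threshold as a fraction of the
#'   median PD signal.
#' @return A list: `ratio` (array like `sr_frames`, `NA` where invalid) and
#'   `valid` (logical array over the spatial dims).
#' @export
normalize_series <- function(sr_frames, pd_frames, pd_floor_frac = 0.05) {
  dsr <- dim(sr_frames); dpd <- dim(pd_frames)
  if (is.null(dsr)) dsr <- c(length(sr_frames), 1L)
  if (is.null(dpd)) dpd <- c(length(pd_frames), 1L)
  nsd <- length(dsr) - 1L
  if (length(dpd) - 1L != nsd || !all(dsr[seq_len(nsd)] == dpd[seq_len(nsd)])) {
    stop("sr_frames and pd_frames have mismatched spatial dimensions")
  }
  if (dpd[length(dpd)] < 1L) stop("pd_frames must contain at least one frame")
  npix <- prod(dsr[seq_len(nsd)])
  pd <- matrix(pd_frames, nrow = npix)
  pd_mean <- rowMeans(pd)
  if (all(pd_mean == 0)) stop("all-zero PD frames: cannot normalize")
  floor_val <- pd_floor_frac * stats::median(pd_mean)
  valid <- pd_mean >= floor_val & pd_mean > 0
  sr <- matrix(sr_frames, nrow = npix)
  ratio <- sweep(sr, 1, pd_mean, "/")
  ratio[!valid, ] <- NA_real_
  dim(ratio) <- dsr
  dim(valid) <- if (nsd > 1L) dsr[seq_len(nsd)] else NULL
  list(ratio = ratio, valid = valid)
}

#' Precomputed ratio-to-T1 lookup for signal inversion
#'
#' Tabulates the PD-normalized SR signal ratio over a dense T1 grid
#' (default 20..4000 ms in 1 ms steps). The ratio is strictly decreasing in
#' T1 for the protocol sequences, so monotone interpolation inverts it.
#'
#' @param seq_sr SR `sequence_params` (imaging or AIF).
#' @param seq_pd PD `sequence_params`.
#' @param ctx A `relaxation_context`; supplies the native T1 used for the PD
#'   denominator (PD frames are acquired pre-contrast).
#' @param t10_ms Native T1 of the tissue class being inverted (defaults to
#'   `ctx$t10_tissue_ms`).
#' @param t1_grid_ms T1 grid for the lookup, ms.
#' @return An object of class `conc_lookup`.
#' @export
conc_lookup <- function(seq_sr, seq_pd, ctx, t10_ms = ctx$t10_tissue_ms,
                        t1_grid_ms = seq(20, 4000, by = 1)) {
  stopifnot(inherits(ctx, "relaxation_context"))
  pd_ref <- pd_signal(t10_ms, seq_pd)
  ratio_grid <- sr_signal(t1_grid_ms, seq_sr) / pd_ref
  if (any(diff(ratio_grid) >= 0)) {
    stop("ratio is not strictly decreasing in T1 for this sequence pair")
  }
  structure(list(t1_grid_ms = t1_grid_ms, ratio_grid = ratio_grid,
                 t10_ms = t10_ms, r1 = ctx$r1,
                 ratio_max = ratio_grid[1]),
            class = "conc_lookup")
}

#' Convert PD-normalized signal ratio to gadolinium concentration
#'
#' Inverts ratio(T1) = sr_signal(T1)/pd_signal(T10) by monotone linear
#' interpolation on the precomputed lookup, then converts to concentration
#' through C = (1/T1 - 1/T10)/r1 (rates in s^-1). Ratios mapping to
#' T1 >= T10 (pre-contrast noise) are clipped to concentration 0.
#'
#' @param ratio Dimensionless signal ratio(s); `NA` passes through.
#' @param lookup A `conc_lookup` from [conc_lookup()].
#' @return Concentration(s) in mmol/L, non-negative.
#' @export
signal_to_concentration <- function(ratio, lookup) {
  stopifnot(inherits(lookup, "conc_lookup"))
  out <- rep(NA_real_, length(ratio))
  ok <- !is.na(ratio)
  if (any(ratio[ok] < 0)) stop("ratio must be non-negative")
  if (any(ratio[ok] > lookup$ratio_max)) {
    stop(sprintf(
      "signal saturation: ratio %.4g exceeds the model maximum %.4g at T1 = %g ms",
      max(ratio[ok]), lookup$ratio_max, lookup$t1_grid_ms[1]))
  }
  t1 <- ratio_to_t1(ratio[ok], lookup)
  conc <- (1000 / t1 - 1000 / lookup$t10_ms) / lookup$r1
  out[ok] <- pmax(conc, 0)
  out
}

# monotone inversion of the lookup (ratio decreasing in T1)
ratio_to_t1 <- function(ratio, lookup) {
  stats::approx(x = rev(lookup$ratio_grid), y = rev(lookup$t1_grid_ms),
                xout = ratio, rule = 2)$y
}

#' Concentration time series from a dynamic SR series
#'
#' Full inverse chain for one acquisition: PD normalization, ratio-to-T1
#' inversion, and rate-to-concentration conversion. The mean ratio of the
#' first `baseline_frames` post-PD frames defines each pixel's pre-contrast
#' baseline: its inverted T1 anchors C = 0, removing scanner-scale offsets
#' and T10 mis-specification; concentrations are clipped at 0.
#'
#' @param series A `perf_series` (see [perf_series()]).
#' @param seq_sr,seq_pd Sequence parameters of the SR and PD acquisitions.
#' @param ctx A `relaxation_context`.
#' @param t10_ms Native T1 of the series' tissue class.
#' @param baseline_frames Number of initial non-PD frames averaged as the
#'   pre-contrast baseline.
#' @param pd_floor_frac Passed to [normalize_series()].
#' @return A list: `conc` array (x,y,slice,frame over non-PD frames,
#'   mmol/L), `times_s`, `valid` mask, `n_clipped` (ratios clipped into the
#'   invertible range; noise tolerance).
#' @export
concentration_series <- function(series, seq_sr, seq_pd, ctx,
                                 t10_ms = ctx$t10_tissue_ms,
                                 baseline_frames = 3, pd_floor_frac = 0.05) {
  stopifnot(inherits(series, "perf_series"))
  is_pd <- series$roles == "pd"
  if (!any(is_pd)) stop("series contains no PD frames")
  d <- dim(series$data)
  sr <- series$data[, , , !is_pd, drop = FALSE]
  pd <- series$data[, , , is_pd, drop = FALSE]
  nrm <- normalize_series(sr, pd, pd_floor_frac = pd_floor_frac)
  lk <- conc_lookup(seq_sr, seq_pd, ctx, t10_ms = t10_ms)
  # noise can push ratios outside the invertible range: clip into it here
  # (the scalar converter keeps its strict saturation/domain errors)
  ratio <- pmin(pmax(nrm$ratio, 0), lk$ratio_max)
  n_clipped <- sum(ratio != nrm$ratio, na.rm = TRUE)
  nb <- min(baseline_frames, dim(ratio)[4])
  base_ratio <- apply(ratio[, , , seq_len(nb), drop = FALSE], c(1, 2, 3),
                      mean)
  t1 <- ratio_to_t1(as.vector(ratio), lk)
  dim(t1) <- dim(ratio)
  t1_base <- ratio_to_t1(as.vector(base_ratio), lk)
  conc <- sweep(1000 / t1, c(1, 2, 3), 1000 / t1_base, "-") / lk$r1
  conc <- pmax(conc, 0)
  dim(conc) <- dim(ratio)
  list(conc = conc, times_s = series$times_s[!is_pd], valid = nrm$valid,
       n_clipped = n_clipped)
}
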