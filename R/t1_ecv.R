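#' MOLLI sample set
#'
#' Inversion-time / magnitude-signal pairs from a Modified Look-Locker
#' Inversion Recovery acquisition (5(4)3 scheme by default: 5 images after
#' the first inversion, 4 recovery beats, 3 images after the second).
#'
#' @param inversion_times_ms Inversion times, ms; positive.
#' @param signals Magnitude intensities, same length; >= 6 samples.
#' @param scheme Text tag for the sampling scheme.
#' @return An object of class `molli_samples`, sorted by inversion time.
#' @export
molli_samples <- function(inversion_times_ms, signals, scheme = "5(4)3") {
  if (length(inversion_times_ms) != length(signals)) {
    stop("inversion_times_ms and signals must have the same length")
  }
  if (length(signals) < 6) stop("MOLLI fitting needs at least 6 samples")
  if (any(inversion_times_ms <= 0)) stop("inversion times must be positive")
  o <- order(inversion_times_ms)
  structure(list(inversion_times_ms = as.numeric(inversion_times_ms[o]),
                 signals = as.numeric(signals[o]), scheme = scheme),
            class = "molli_samples")
}

#' Inversion times of a MOLLI scheme
#'
#' 5(4)3: five samples at `ti1 + (0:4) RR` from the first inversion and
#' three at `ti2 + (0:2) RR` from the second.
#'
#' @param rr_ms RR interval, ms.
#' @param ti1_ms,ti2_ms Minimum inversion times of the two inversions, ms.
#' @return Numeric vector of 8 inversion times (unsorted).
#' @export
molli_scheme_543 <- function(rr_ms = 1000, ti1_ms = 100, ti2_ms = 180) {
  c(ti1_ms + (0:4) * rr_ms, ti2_ms + (0:2) * rr_ms)
}

#' Fit the three-parameter MOLLI relaxation model
#'
#' Magnitude fit of |A - B exp(-TI/T1*)| with polarity restoration: the
#' sign of the first j sorted samples is flipped for each candidate
#' j = 0..n and the signed model A - B exp(-TI/T1*) is fitted to each
#' candidate; the best-residual candidate wins. For fixed T1* the model is
#' linear in (A, B), so the search is a 1-D profile over T1* (log-spaced
#' grid then golden-section refinement) — deterministic and derivative-free.
#' The apparent time constant is corrected with the Look-Locker factor,
#' T1 = T1* (B/A - 1).
#'
#' @param samples A `molli_samples`.
#' @param t1_star_grid Profile grid over apparent T1*, ms.
#' @return A list: `t1_ms`, `t1_star_ms`, `a`, `b`, `residual` (RMS),
#'   `r2`, `n_flipped`, `valid`.
#' @export
fit_molli <- function(samples, t1_star_grid = exp(seq(log(30), log(5000),
                                                      length.out = 120))) {
  stopifnot(inherits(samples, "molli_samples"))
  ti <- samples$inversion_times_ms
  y0 <- samples$signals
  n <- length(ti)
  if (stats::sd(y0) == 0) {
    return(list(t1_ms = NA_real_, t1_star_ms = NA_real_, a = NA_real_,
                b = NA_real_, residual = NA_real_, r2 = NA_real_,
                n_flipped = NA_integer_, valid = FALSE))
  }

  sse_for <- function(y, t1s) {
    x <- exp(-ti / t1s)
    fit <- stats::lm.fit(cbind(1, -x), y)
    c(sum(fit$residuals^2), fit$coefficients)
  }
  best <- NULL
  for (j in 0:n) {
    y <- y0
    if (j > 0) y[seq_len(j)] <- -y[seq_len(j)]
    sse_grid <- vapply(t1_star_grid, function(t1s) sse_for(y, t1s)[1],
                       numeric(1))
    k <- which.min(sse_grid)
    lo <- t1_star_grid[max(1, k - 1)]
    hi <- t1_star_grid[min(length(t1_star_grid), k + 1)]
    opt <- stats::optimize(function(t1s) sse_for(y, t1s)[1], c(lo, hi),
                           tol = 1e-6)
    cand <- list(j = j, t1_star = opt$minimum, sse = opt$objective, y = y)
    if (is.null(best) || cand$sse < best$sse) best <- cand
  }
  ab <- unname(sse_for(best$y, best$t1_star)[2:3])
  a <- ab[1]; b <- ab[2]
  valid <- is.finite(a) && is.finite(b) && a > 0 && b / a > 1
  t1 <- if (valid) best$t1_star * (b / a - 1) else NA_real_
  ss_tot <- sum((best$y - mean(best$y))^2)
  list(t1_ms = t1, t1_star_ms = best$t1_star, a = a, b = b,
       residual = sqrt(best$sse / n),
       r2 = if (ss_tot > 0) 1 - best$sse / ss_tot else NA_real_,
       n_flipped = best$j, valid = valid)
}

#' Gadolinium partition coefficient from serial T1 pairs
#'
#' lambda is the slope of the ordinary least-squares fit of 1/T1(myocardium)
#' on 1/T1(blood) across the native and post-contrast timepoints.
#'
#' @param t1_myo_ms,t1_blood_ms Paired T1 values, ms; >= 2 pairs with
#'   distinct blood values.
#' @return A list: `lambda`, `intercept` (1/ms), `r2`, `n`.
#' @export
partition_coefficient <- function(t1_myo_ms, t1_blood_ms) {
  if (length(t1_myo_ms) != length(t1_blood_ms)) {
    stop("t1_myo_ms and t1_blood_ms must be paired")
  }
  ok <- is.finite(t1_myo_ms) & is.finite(t1_blood_ms) &
    t1_myo_ms > 0 & t1_blood_ms > 0
  x <- 1 / t1_blood_ms[ok]
  y <- 1 / t1_myo_ms[ok]
  if (length(unique(x)) < 2) {
    stop("partition coefficient needs >= 2 pairs with distinct blood T1")
  }
  fit <- stats::lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(lambda = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       n = length(x))
}

#' Extracellular volume fraction
#'
#' ECV = lambda (1 - hematocrit).
#'
#' @param lambda Partition coefficient, > 0.
#' @param hct Hematocrit as a fraction in (0, 1).
#' @return ECV as a fraction.
#' @export
compute_ecv <- function(lambda, hct) {
  if (any(lambda <= 0)) stop("lambda must be > 0")
  if (any(hct <= 0 | hct >= 1)) stop("hematocrit must lie strictly in (0, 1)")
  lambda * (1 - hct)
}

#' ROI-level T1/ECV analysis of a MOLLI sample table
#'
#' Fits every (subject, timepoint, roi) MOLLI sample set, regresses
#' 1/T1(myo) on 1/T1(blood) per subject, and combines the slope with the
#' subject's hematocrit into ECV.
#'
#' @param samples Data frame: `subject_id`, `timepoint`, `ti_ms`, `signal`,
#'   `roi` in `{"myo","blood"}`.
#' @param hct Data frame: `subject_id`, `hct` (fraction).
#' @return Data frame: `subject_id`, `t1_native_myo`, `t1_native_blood`,
#'   `lambda`, `hct`, `ecv`, `fit_r2`, `n_timepoints`.
#' @export
ecv_analysis <- function(samples, hct) {
  need <- c("subject_id", "timepoint", "ti_ms", "signal", "roi")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(samples, samples$subject_id), function(ss) {
    tps <- unique(ss$timepoint)
    t1m <- t1b <- rep(NA_real_, length(tps))
    for (i in seq_along(tps)) {
      for (roi in c("myo", "blood")) {
        sub <- ss[ss$timepoint == tps[i] & ss$roi == roi, ]
        if (nrow(sub) < 6) next
        fit <- fit_molli(molli_samples(sub$ti_ms, sub$signal))
        if (roi == "myo") t1m[i] <- fit$t1_ms else t1b[i] <- fit$t1_ms
      }
    }
    pc <- partition_coefficient(t1m, t1b)
    h <- hct$hct[match(ss$subject_id[1], hct$subject_id)]
    nat <- match("native", tps)
    data.frame(subject_id = ss$subject_id[1],
               t1_native_myo = if (!is.na(nat)) t1m[nat] else NA_real_,
               t1_native_blood = if (!is.na(nat)) t1b[nat] else NA_real_,
               lambda = pc$lambda, hct = h,
               ecv = if (is.finite(h)) compute_ecv(pc$lambda, h) else NA_real_,
               fit_r2 = pc$r2, n_timepoints = pc$n)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
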