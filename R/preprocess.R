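#' Norm reference for personalized artifact thresholds
#'
#' Resting RMSSD norms for early adolescents used to personalize the Karlsson
#' deviation threshold. Participants are categorized relative to the norm
#' mean and SD (cutoffs at mean + k*SD, k in -2, -1, +1, +2) and the
#' threshold is 0.50 for very high, 0.45 for high, and 0.40 for all other
#' categories, which avoids overcorrecting inherently variable hearts.
#'
#' @param norm_mean norm RMSSD mean in ms (default 42.9).
#' @param norm_sd norm RMSSD SD in ms (default 13.4; must be > 0).
#' @param thresholds named deviation thresholds per category.
#' @return A list of class `norm_reference`.
#' @export
norm_reference <- function(norm_mean = 42.9, norm_sd = 13.4,
                           thresholds = c(very_low = 0.40, low = 0.40,
                                          normal = 0.40, high = 0.45,
                                          very_high = 0.50)) {
  if (norm_sd <= 0) stop("norm_sd must be > 0")
  need <- c("very_low", "low", "normal", "high", "very_high")
  if (!all(need %in% names(thresholds))) {
    stop("thresholds must name all five categories")
  }
  structure(list(norm_mean = norm_mean, norm_sd = norm_sd,
                 thresholds = thresholds[need]),
            class = "norm_reference")
}

#' Flag heart periods outside absolute physiological bounds
#'
#' Flags beats strictly below `lower` ms or strictly above `upper` ms
#' (defaults 300 and 2000); values exactly at a bound are not flagged.
#'
#' @param series an [hp_series()] or numeric vector of heart periods (ms).
#' @param lower,upper absolute bounds in ms.
#' @return Integer vector of flagged beat indices (possibly empty).
#' @export
flag_absolute_bounds <- function(series, lower = 300, upper = 2000) {
  hp <- as_hp(series)
  which(hp < lower | hp > upper)
}

#' Assign an HRV norm category and Karlsson threshold
#'
#' Places a preliminary RMSSD into one of five categories relative to the
#' norm reference (cutoffs at mean + k*SD, k = -2, -1, +1, +2; a value
#' exactly at a cutoff takes the higher category) and returns the
#' personalized deviation threshold for that category.
#'
#' @param preliminary_rmssd RMSSD in ms computed before Karlsson detection
#'   (on the bounds-cleaned series); must be >= 0.
#' @param ref a [norm_reference()].
#' @return A list with `category` (character) and `threshold` (numeric).
#' @examples
#' assign_norm_category(42.9)  # normal, 0.40
#' assign_norm_category(75)    # very_high, 0.50
#' @export
assign_norm_category <- function(preliminary_rmssd, ref = norm_reference()) {
  if (!is.finite(preliminary_rmssd) || preliminary_rmssd < 0) {
    stop("preliminary_rmssd must be finite and >= 0")
  }
  cuts <- ref$norm_mean + c(-2, -1, 1, 2) * ref$norm_sd
  category <- c("very_low", "low", "normal", "high", "very_high")[
    findInterval(preliminary_rmssd, cuts, left.open = FALSE) + 1L]
  list(category = category,
       threshold = unname(ref$thresholds[category]))
}

#' Detect deviant beats with the iterative local-mean (Karlsson) method
#'
#' A beat is flagged when its relative deviation from the local mean of the
#' nearest non-flagged preceding and subsequent beats exceeds `threshold`:
#' `|HP_i - L_i| / L_i > threshold`. Endpoints are compared against their
#' single available neighbor. Detection passes are repeated, with local means
#' recomputed over the surviving beats, until no new beat is flagged.
#'
#' @param series an [hp_series()] or numeric vector (ms); at least 3 beats.
#' @param threshold relative deviation threshold in (0, 1).
#' @param flagged_init indices already flagged upstream (e.g. absolute-bound
#'   violations); these are excluded from local means but not re-reported.
#' @return Integer vector of beat indices flagged by this detector.
#' @export
detect_karlsson <- function(series, threshold, flagged_init = integer(0)) {
  hp <- as_hp(series)
  n <- length(hp)
  if (n < 3) stop("series too short for local-mean detection (need >= 3 beats)")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  flagged <- logical(n)
  flagged[flagged_init] <- TRUE
  repeat {
    u <- which(!flagged)
    m <- length(u)
    if (m < 2) break
    hu <- hp[u]
    left <- c(NA, hu[-m])
    right <- c(hu[-1], NA)
    L <- rowMeans(cbind(left, right), na.rm = TRUE)
    new <- u[abs(hu - L) / L > threshold]
    if (!length(new)) break
    flagged[new] <- TRUE
  }
  flagged[flagged_init] <- FALSE
  which(flagged)
}

#' Replace flagged beats by linear interpolation
#'
#' Flagged heart periods are replaced by linear interpolation between the
#' nearest unflagged neighbors in beat-index coordinates; flagged runs at
#' either end take the value of the nearest unflagged beat. Series length is
#' unchanged and timestamps are rebuilt from the corrected intervals.
#'
#' @param series an [hp_series()].
#' @param flagged integer indices to replace; at least 2 beats must remain
#'   unflagged.
#' @return A corrected [hp_series()] of the same length.
#' @export
correct_artifacts <- function(series, flagged) {
  stopifnot(inherits(series, "hp_series"))
  hp <- series$hp
  n <- length(hp)
  flagged <- unique(as.integer(flagged))
  if (length(flagged) && (min(flagged) < 1 || max(flagged) > n)) {
    stop("flagged indices out of range")
  }
  if (!length(flagged)) return(series)
  clean <- setdiff(seq_len(n), flagged)
  if (length(clean) < 2) stop("fewer than 2 clean beats; cannot interpolate")
  hp[flagged] <- stats::approx(clean, hp[clean], xout = flagged,
                               method = "linear", rule = 2)$y
  hp_series(hp, participant_id = series$participant_id,
            device = series$device)
}

#' Artifact report for one participant
#'
#' @param flagged_bounds,flagged_karlsson index sets from the two detectors.
#' @param category,threshold_used norm category and personalized threshold.
#' @param excluded,exclusion_reason quality-gate verdict.
#' @return A list of class `artifact_report`; `n_artifacts` is the size of
#'   the union of the two flag sets.
#' @keywords internal
artifact_report <- function(flagged_bounds = integer(0),
                            flagged_karlsson = integer(0),
                            category = NA_character_,
                            threshold_used = NA_real_,
                            excluded = FALSE,
                            exclusion_reason = "none") {
  structure(list(
    flagged_bounds = flagged_bounds,
    flagged_karlsson = flagged_karlsson,
    n_artifacts = length(union(flagged_bounds, flagged_karlsson)),
    category = category,
    threshold_used = threshold_used,
    excluded = excluded,
    exclusion_reason = exclusion_reason
  ), class = "artifact_report")
}

#' Apply the recording quality gate
#'
#' A participant is excluded when more than `max_artifacts` beats were
#' flagged, the recording spans less than `min_duration` seconds, or it
#' contains fewer than `min_beats` beats. Exactly `max_artifacts` flags is
#' still acceptable.
#'
#' @param report an `artifact_report`.
#' @param series the participant's [hp_series()].
#' @param max_artifacts maximum acceptable artifact count (default 10).
#' @param min_duration minimum recording span in seconds (default 240).
#' @param min_beats minimum plausible beat count (default 150).
#' @return The updated `artifact_report` with `excluded` and
#'   `exclusion_reason` set.
#' @export
apply_quality_gate <- function(report, series, max_artifacts = 10,
                               min_duration = 240, min_beats = 150) {
  stopifnot(inherits(report, "artifact_report"))
  span_s <- sum(as_hp(series)) / 1000
  n <- length(as_hp(series))
  reason <- "none"
  if (report$n_artifacts > max_artifacts) {
    reason <- "too_many_artifacts"
  } else if (span_s < min_duration) {
    reason <- "too_short"
  } else if (n < min_beats) {
    reason <- "implausible_beat_count"
  }
  report$excluded <- reason != "none"
  report$exclusion_reason <- reason
  report
}

#' Root mean square of successive differences (RMSSD)
#'
#' `RMSSD = sqrt( mean( (HP_{i+1} - HP_i)^2 ) )`, the mean taken over the
#' N - 1 successive differences of the N heart periods.
#'
#' @param series an [hp_series()] or numeric vector of heart periods (ms);
#'   at least 2 beats.
#' @return RMSSD in ms.
#' @examples
#' compute_rmssd(c(800, 810, 790))  # sqrt(250)
#' @export
compute_rmssd <- function(series) {
  hp <- as_hp(series)
  if (length(hp) < 2) stop("need at least 2 beats to compute RMSSD")
  sqrt(mean(diff(hp)^2))
}

#' Mean heart rate
#'
#' `meanHR = 60000 / mean(HP)`, in beats per minute.
#'
#' @param series an [hp_series()] or numeric vector of heart periods (ms).
#' @return Mean heart rate in bpm.
#' @export
compute_mean_hr <- function(series) {
  hp <- as_hp(series)
  if (!length(hp)) stop("empty series")
  60000 / mean(hp)
}

#' Minute-wise RMSSD over a 5-minute recording
#'
#' Partitions the recording into consecutive 60-second windows by cumulative
#' timestamp (a beat belongs to the window in which it ends) and computes
#' the RMSSD per window. Windows holding fewer than 2 beats yield `NA`.
#'
#' @param series an [hp_series()].
#' @param n_windows number of windows (default 5).
#' @return Numeric vector of per-window RMSSD values (ms). If the recording
#'   is shorter than `n_windows` minutes, fewer values are returned with a
#'   warning.
#' @export
compute_minutewise_rmssd <- function(series, n_windows = 5) {
  stopifnot(inherits(series, "hp_series"))
  ts <- series$timestamp - series$timestamp[1] + series$hp[1]
  avail <- floor(ts[length(ts)] / 60000)
  k <- min(n_windows, avail)
  if (k < n_windows) {
    warning(sprintf("recording shorter than %d minutes; returning %d windows",
                    n_windows, k))
  }
  if (k < 1) return(numeric(0))
  win <- ceiling(ts / 60000)
  vapply(seq_len(k), function(w) {
    hp_w <- series$hp[win == w]
    if (length(hp_w) < 2) NA_real_ else compute_rmssd(hp_w)
  }, numeric(1))
}

#' High-frequency spectral power of the heart-period series
#'
#' Estimates power in the respiratory band (default 0.15-0.40 Hz) of the
#' mean-centered tachogram. The unevenly sampled beat series is resampled at
#' `fs` Hz by cubic spline interpolation against cumulative time, and the
#' spectrum is estimated with a Welch-type averaged periodogram (Hann
#' windowed segments with 50% overlap). The band power is the integral of
#' the one-sided density over the band, in ms^2.
#'
#' @param series an [hp_series()] spanning at least 2 minutes.
#' @param band frequency band in Hz.
#' @param fs resampling rate in Hz (default 4).
#' @param segment_s Welch segment length in seconds (default 64).
#' @return HF power in ms^2.
#' @export
compute_hf_power <- function(series, band = c(0.15, 0.40), fs = 4,
                             segment_s = 64) {
  stopifnot(inherits(series, "hp_series"))
  ts_s <- series$timestamp / 1000
  span <- ts_s[length(ts_s)] - ts_s[1]
  if (span < 120) stop("series too short for spectral estimation (< 2 min)")
  tt <- seq(ts_s[1], ts_s[length(ts_s)], by = 1 / fs)
  x <- stats::spline(ts_s, series$hp, xout = tt)$y
  x <- x - mean(x)

  nseg <- min(length(x), round(segment_s * fs))
  step <- max(1, floor(nseg / 2))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  norm <- sum(w^2)
  psd <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * w
    p <- Mod(stats::fft(seg))^2 / (norm * fs)
    psd <- psd + p[seq_len(floor(nseg / 2) + 1)]
  }
  psd <- psd / length(starts)
  psd[-c(1, length(psd))] <- 2 * psd[-c(1, length(psd))]  # one-sided
  freq <- (seq_along(psd) - 1) * fs / nseg
  sel <- freq >= band[1] & freq <= band[2]
  sum(psd[sel]) * fs / nseg
}

#' Preprocess one participant's recording and extract HRV features
#'
#' Runs the full cleaning chain: (1) flag absolute-bound violations
#' (< 300 ms or > 2000 ms); (2) compute a preliminary RMSSD on the
#' bounds-cleaned beats; (3) assign a norm category and personalized Karlsson
#' threshold; (4) run iterative local-mean detection (bound-flagged beats
#' excluded from local means); (5) replace all flagged beats by linear
#' interpolation; (6) apply the quality gate; (7) compute RMSSD, natural-log
#' RMSSD, mean HR, and minute-wise RMSSD on the corrected series.
#'
#' @param series an [hp_series()].
#' @param ref a [norm_reference()].
#' @param max_artifacts,min_duration,min_beats quality-gate settings, see
#'   [apply_quality_gate()].
#' @param compute_hf also compute HF band power (default `FALSE`).
#' @return A list with `features` (named list: `rmssd`, `log_rmssd`,
#'   `mean_hr`, `minutewise_rmssd`, `hf_power`, `n_artifacts`; `NULL` when
#'   excluded) and `report` (an `artifact_report`).
#' @export
preprocess_participant <- function(series, ref = norm_reference(),
                                   max_artifacts = 10, min_duration = 240,
                                   min_beats = 150, compute_hf = FALSE) {
  stopifnot(inherits(series, "hp_series"))
  n <- length(series$hp)
  if (n < 3) {
    rep0 <- artifact_report(excluded = TRUE,
                            exclusion_reason = "implausible_beat_count")
    return(list(features = NULL, report = rep0))
  }
  b <- flag_absolute_bounds(series)
  clean_hp <- if (length(b)) series$hp[-b] else series$hp
  if (length(clean_hp) < 2) {
    rep0 <- artifact_report(flagged_bounds = b, excluded = TRUE,
                            exclusion_reason = "too_many_artifacts")
    return(list(features = NULL, report = rep0))
  }
  prelim <- compute_rmssd(clean_hp)
  cat_thr <- assign_norm_category(prelim, ref)
  k <- detect_karlsson(series, cat_thr$threshold, flagged_init = b)
  flagged <- union(b, k)
  report <- artifact_report(flagged_bounds = b, flagged_karlsson = k,
                            category = cat_thr$category,
                            threshold_used = cat_thr$threshold)
  corrected <- if (length(flagged) && length(flagged) <= n - 2) {
    correct_artifacts(series, flagged)
  } else {
    series
  }
  report <- apply_quality_gate(report, corrected,
                               max_artifacts = max_artifacts,
                               min_duration = min_duration,
                               min_beats = min_beats)
  if (report$excluded) {
    return(list(features = NULL, report = report))
  }
  rmssd <- compute_rmssd(corrected)
  features <- list(
    rmssd = rmssd,
    log_rmssd = if (rmssd > 0) log(rmssd) else NA_real_,
    mean_hr = compute_mean_hr(corrected),
    minutewise_rmssd = suppressWarnings(compute_minutewise_rmssd(corrected)),
    hf_power = if (compute_hf) compute_hf_power(corrected) else NA_real_,
    n_artifacts = report$n_artifacts
  )
  list(features = features, report = report)
}
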