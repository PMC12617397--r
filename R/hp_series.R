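#' Heart-period series
#'
#' A `hp_series` object holds one participant's resting recording as an
#' ordered sequence of interbeat intervals (heart periods, HP, in ms) with
#' cumulative timestamps (ms from recording onset, taken at the end of each
#' beat, so `timestamp[i] == sum(hp[1:i])` for a gap-free recording).
#'
#' @param hp numeric vector of heart periods in ms; all finite and positive.
#' @param participant_id identifier carried through the pipeline.
#' @param timestamp cumulative time in ms per beat; strictly increasing.
#'   Defaults to `cumsum(hp)`.
#' @param device recording device, `"ECG_chest"` or `"PPG_ear"`.
#' @return An object of class `hp_series`.
#' @examples
#' s <- hp_series(c(800, 810, 790), participant_id = "p1")
#' compute_rmssd(s)
#' @export
hp_series <- function(hp, participant_id = "unknown", timestamp = cumsum(hp),
                      device = c("ECG_chest", "PPG_ear")) {
  device <- match.arg(device)
  hp <- as.numeric(hp)
  if (length(hp) == 0L) stop("heart-period series must be nonempty")
  if (anyNA(hp) || any(!is.finite(hp)) || any(hp <= 0)) {
    stop("all heart periods must be finite and > 0")
  }
  timestamp <- as.numeric(timestamp)
  if (length(timestamp) != length(hp)) {
    stop("timestamp and hp must have the same length")
  }
  if (any(diff(timestamp) <= 0)) stop("timestamps must be strictly increasing")
  structure(
    list(participant_id = participant_id, hp = hp, timestamp = timestamp,
         device = device),
    class = "hp_series"
  )
}

#' @export
print.hp_series <- function(x, ...) {
  cat(sprintf("<hp_series> participant %s: %d beats, %.1f s, device %s\n",
              x$participant_id, length(x$hp), x$timestamp[length(x$hp)] / 1000,
              x$device))
  invisible(x)
}

#' @export
length.hp_series <- function(x) length(x$hp)

# Accept either an hp_series or a bare numeric vector of heart periods.
as_hp <- function(series) {
  if (inherits(series, "hp_series")) series$hp else as.numeric(series)
}

#' Read a heart-period log
#'
#' Reads the two-column CSV dialect written by the HRV logger and by
#' [write_hp_log()]: a header line `timestamp_ms,rr_ms` followed by one row
#' per beat.
#'
#' @param path path to the CSV file.
#' @param participant_id identifier; defaults to the file name without
#'   extension.
#' @param device recording device label.
#' @return An [hp_series()] object.
#' @export
read_hp_log <- function(path, participant_id = NULL,
                        device = c("ECG_chest", "PPG_ear")) {
  device <- match.arg(device)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty heart-period log: ", path)
  need <- c("timestamp_ms", "rr_ms")
  if (!all(need %in% names(raw))) {
    stop("heart-period log must have columns timestamp_ms, rr_ms: ", path)
  }
  ts <- suppressWarnings(as.numeric(raw$timestamp_ms))
  rr <- suppressWarnings(as.numeric(raw$rr_ms))
  bad <- which(is.na(ts) | is.na(rr))
  if (length(bad)) {
    stop(sprintf("non-numeric cell in %s at data row %d", path, bad[1]))
  }
  mono <- which(diff(ts) <= 0)
  if (length(mono)) {
    stop(sprintf("non-monotone timestamp in %s at data row %d", path,
                 mono[1] + 1L))
  }
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  }
  hp_series(rr, participant_id = participant_id, timestamp = ts,
            device = device)
}

#' Write a heart-period log
#'
#' Writes the CSV dialect read back by [read_hp_log()] (columns
#' `timestamp_ms`, `rr_ms`).
#'
#' @param series an [hp_series()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hp_log <- function(series, path) {
  stopifnot(inherits(series, "hp_series"))
  utils::write.csv(
    data.frame(timestamp_ms = series$timestamp, rr_ms = series$hp),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Simulate a resting heart-period series
#'
#' Generates interbeat intervals as a mean heart period plus a sinusoidal
#' respiratory (RSA) modulation and AR(1) Gaussian noise:
#' `HP = mean_hp + rsa_amplitude * sin(2*pi*resp_freq*t) + e`, where `t` is
#' the beat onset time in seconds and `e` is a stationary AR(1) process with
#' marginal standard deviation `noise_sd`. Beats are emitted until the
#' cumulative recording time reaches `duration` seconds.
#'
#' With `ar_coef = 0` and no modulation the successive differences are
#' differences of iid Gaussians, so the expected RMSSD is `noise_sd * sqrt(2)`.
#'
#' @param mean_hp mean heart period in ms, in (300, 2000).
#' @param rsa_amplitude amplitude of the respiratory modulation in ms (>= 0).
#' @param resp_freq respiratory frequency in Hz (default 0.25, the center of
#'   the high-frequency band).
#' @param noise_sd marginal SD of the AR(1) beat-to-beat noise in ms (>= 0).
#' @param ar_coef AR(1) coefficient in `[0, 1)`.
#' @param duration recording duration in seconds (> 0).
#' @param seed integer seed for reproducibility (optional).
#' @param participant_id,device passed to [hp_series()].
#' @return An [hp_series()] object.
#' @examples
#' s <- simulate_hp_series(mean_hp = 850, noise_sd = 30, seed = 1)
#' compute_rmssd(s)
#' @export
simulate_hp_series <- function(mean_hp = 850, rsa_amplitude = 30,
                               resp_freq = 0.25, noise_sd = 25,
                               ar_coef = 0.3, duration = 300, seed = NULL,
                               participant_id = "sim",
                               device = "ECG_chest") {
  if (!(mean_hp > 300 && mean_hp < 2000)) stop("mean_hp must be in (300, 2000)")
  if (duration <= 0) stop("duration must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (rsa_amplitude < 0) stop("rsa_amplitude must be >= 0")
  if (ar_coef < 0 || ar_coef >= 1) stop("ar_coef must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)

  dur_ms <- duration * 1000
  # upper bound on beat count: shortest plausible beat
  n_max <- ceiling(dur_ms / max(50, mean_hp - rsa_amplitude - 6 * noise_sd)) + 8L
  innov_sd <- noise_sd * sqrt(1 - ar_coef^2)
  eps <- if (noise_sd > 0) {
    e <- stats::rnorm(n_max, 0, innov_sd)
    e[1] <- stats::rnorm(1, 0, noise_sd)  # stationary start
    as.numeric(stats::filter(e, ar_coef, method = "recursive"))
  } else {
    numeric(n_max)
  }

  hp <- numeric(n_max)
  t_ms <- 0
  n <- 0L
  while (t_ms < dur_ms && n < n_max) {
    n <- n + 1L
    beat <- mean_hp +
      rsa_amplitude * sin(2 * pi * resp_freq * t_ms / 1000) + eps[n]
    beat <- max(beat, 1)
    hp[n] <- beat
    t_ms <- t_ms + beat
  }
  hp <- hp[seq_len(n)]
  hp_series(hp, participant_id = participant_id, device = device)
}

#' Inject beat artifacts into a clean series
#'
#' Corrupts a clean heart-period series with three classic beat-detection
#' failure modes and returns the ground-truth indices of the corrupted
#' positions, for evaluating artifact detection:
#' \describe{
#'   \item{spike}{a heart period is multiplied by `spike_factor`
#'     (e.g. a missed beat doubling an interval when `spike_factor = 2`).}
#'   \item{missed}{two adjacent heart periods are merged into one
#'     (series shortens by one beat; total duration preserved).}
#'   \item{extra}{one heart period is split into two equal halves
#'     (series lengthens by one beat; total duration preserved).}
#' }
#' Corruption sites are sampled at least three beats apart so that injected
#' artifacts are isolated.
#'
#' @param series a clean [hp_series()].
#' @param n_spikes,n_missed,n_extra number of corruptions of each kind.
#' @param spike_factor multiplier applied to spiked heart periods (> 0).
#' @param seed integer seed (optional).
#' @return A list with `series` (the corrupted [hp_series()]) and `truth`
#'   (integer indices of corrupted beats in the returned series).
#' @export
inject_artifacts <- function(series, n_spikes = 0, n_missed = 0, n_extra = 0,
                             spike_factor = 2, seed = NULL) {
  stopifnot(inherits(series, "hp_series"))
  if (n_spikes < 0 || n_missed < 0 || n_extra < 0) {
    stop("corruption counts must be >= 0")
  }
  if (spike_factor <= 0) stop("spike_factor must be > 0")
  total <- n_spikes + n_missed + n_extra
  n <- length(series$hp)
  if (total == 0L) {
    return(list(series = series, truth = integer(0)))
  }
  # each site needs clearance of 3 beats; merges also consume beat i+1
  if (3 * total + 2 > n) stop("more corruptions than the series can hold")
  if (!is.null(seed)) set.seed(seed)

  # sample isolated sites (pairwise distance >= 3) in 2..(n-2)
  candidates <- 2:(n - 2)
  sites <- integer(0)
  while (length(sites) < total) {
    if (!length(candidates)) stop("could not place isolated corruptions")
    pick <- candidates[sample.int(length(candidates), 1)]
    sites <- c(sites, pick)
    candidates <- candidates[abs(candidates - pick) >= 3]
  }
  types <- sample(rep(c("spike", "missed", "extra"),
                      times = c(n_spikes, n_missed, n_extra)))
  ord <- order(sites)
  sites <- sites[ord]
  types <- types[ord]

  hp <- series$hp
  truth <- integer(0)
  delta <- 0L
  for (k in seq_along(sites)) {
    j <- sites[k] + delta
    if (types[k] == "spike") {
      hp[j] <- hp[j] * spike_factor
      truth <- c(truth, j)
    } else if (types[k] == "missed") {
      hp[j] <- hp[j] + hp[j + 1]
      hp <- hp[-(j + 1)]
      truth <- c(truth, j)
      delta <- delta - 1L
    } else { # extra
      hp <- append(hp[-j], rep(hp[j] / 2, 2), after = j - 1)
      truth <- c(truth, j, j + 1L)
      delta <- delta + 1L
    }
  }
  out <- hp_series(hp, participant_id = series$participant_id,
                   device = series$device)
  list(series = out, truth = truth)
}
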