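#' Spike train sets
#'
#' Per-trial spike times in milliseconds, relative to stimulus onset at 0.
#' The default recording window is -200 to 1100 ms with a 700 ms stimulus;
#' the 200 ms before the stimulus define the ongoing-activity window. All
#' analysis intervals are half-open `[t, t + dt)`, so a spike at exactly 0
#' belongs to the evoked period.
#'
#' @param trials list of numeric vectors of spike times (ms), each sorted
#'   strictly increasing and contained in `window`.
#' @param window recording window `c(start, end)` in ms.
#' @param stimulus_duration stimulus duration in ms (onset at 0).
#' @return an object of class `spike_train_set`.
#' @export
spike_train_set <- function(trials, window = c(-200, 1100),
                            stimulus_duration = 700) {
  if (!is.list(trials) || length(trials) < 1L)
    stop("trials must be a non-empty list of spike-time vectors")
  if (length(window) != 2L || window[1] >= window[2])
    stop("invalid recording window")
  if (window[1] > 0 || window[2] < stimulus_duration)
    stop("recording window must contain the stimulus")
  for (i in seq_along(trials)) {
    t <- trials[[i]]
    if (length(t)) {
      if (any(!is.finite(t)) || is.unsorted(t, strictly = TRUE))
        stop("trial ", i, ": spike times must be finite and strictly ",
             "increasing")
      if (t[1] < window[1] || t[length(t)] > window[2])
        stop("trial ", i, ": spike times outside the recording window")
    }
    trials[[i]] <- as.numeric(t)
  }
  structure(list(trials = trials, window = as.numeric(window),
                 stimulus_duration = stimulus_duration),
            class = "spike_train_set")
}

#' Number of trials in a spike train set
#' @param trains a [spike_train_set()].
#' @export
n_trials <- function(trains) length(trains$trials)

## internal: trial-pooled rate (Hz) in a half-open window [from, to) ms
pooled_rate <- function(trains, from, to) {
  n <- sum(vapply(trains$trials,
                  function(t) sum(t >= from & t < to), integer(1)))
  n / (n_trials(trains) * (to - from) / 1000)
}

#' Peristimulus time histogram
#'
#' Counts spikes pooled over trials in fixed-width bins spanning the
#' recording window and converts them to rates in Hz (count divided by
#' number of trials times bin width). Bins are right-open `[t, t + bw)`;
#' the last bin is closed so a spike at the window end is counted.
#'
#' @param trains a [spike_train_set()].
#' @param bin_width bin width in ms; must divide the window length (default
#'   5 ms).
#' @return an object of class `psth`: list with `rate` (Hz per bin),
#'   `edges` (bin edges, ms), `bin_width`, `n_trials`, `window` and
#'   `total_count`.
#' @export
compute_psth <- function(trains, bin_width = 5) {
  stopifnot(inherits(trains, "spike_train_set"))
  w <- trains$window
  if (abs((diff(w) / bin_width) %% 1) > 1e-9)
    stop("bin width must divide the recording window length")
  edges <- seq(w[1], w[2], by = bin_width)
  all_t <- unlist(trains$trials, use.names = FALSE)
  counts <- if (length(all_t)) {
    graphics::hist(all_t, breaks = edges, right = FALSE,
                   include.lowest = TRUE, plot = FALSE)$counts
  } else integer(length(edges) - 1L)
  structure(list(rate = counts / (n_trials(trains) * bin_width / 1000),
                 edges = edges, bin_width = bin_width,
                 n_trials = n_trials(trains), window = w,
                 total_count = length(all_t)),
            class = "psth")
}

#' Ongoing (pre-stimulus) spike rate
#'
#' Trial-pooled spike rate in the ongoing window before stimulus onset.
#'
#' @param trains a [spike_train_set()].
#' @param window ongoing window in ms, default `c(-200, 0)`.
#' @return rate in Hz.
#' @export
ongoing_rate <- function(trains, window = c(-200, 0)) {
  stopifnot(inherits(trains, "spike_train_set"))
  pooled_rate(trains, window[1], window[2])
}

#' Fraction of ongoing spikes fired in bursts
#'
#' A spike in the ongoing window is counted as part of a burst if it
#' participates in at least one inter-spike interval at or below
#' `1000 / threshold_hz` ms within the same trial's ongoing window (10 ms
#' for 100 Hz bursts, 5 ms for 200 Hz bursts). Bursts never span trials.
#'
#' @param trains a [spike_train_set()].
#' @param threshold_hz burst threshold in Hz (typically 100 or 200).
#' @param window ongoing window in ms.
#' @return percentage of ongoing spikes in bursts (0-100). If there are no
#'   ongoing spikes, returns 0 with attribute `no_ongoing_spikes = TRUE`.
#' @export
burst_fraction <- function(trains, threshold_hz, window = c(-200, 0)) {
  stopifnot(inherits(trains, "spike_train_set"), threshold_hz > 0)
  max_isi <- 1000 / threshold_hz
  n_burst <- 0L
  n_all <- 0L
  for (t in trains$trials) {
    t <- t[t >= window[1] & t < window[2]]
    n_all <- n_all + length(t)
    if (length(t) >= 2L) {
      isi <- diff(t)
      inb <- c(isi <= max_isi, FALSE) | c(FALSE, isi <= max_isi)
      n_burst <- n_burst + sum(inb)
    }
  }
  if (n_all == 0L)
    return(structure(0, no_ongoing_spikes = TRUE))
  100 * n_burst / n_all
}

#' Evoked response metrics
#'
#' Onset rate is the trial-pooled rate in the onset window minus the
#' ongoing rate; onset probability is the fraction of trials with at least
#' one spike in the onset window; sustained rate is the pooled rate in the
#' sustained window minus the ongoing rate. Negative elevations are
#' reported as-is (not clamped).
#'
#' @param trains a [spike_train_set()].
#' @param onset_window window for the onset response, default `c(0, 100)` ms.
#' @param sustained_window window for the sustained response, default
#'   `c(100, 700)` ms.
#' @param ongoing_window ongoing window, default `c(-200, 0)` ms.
#' @return list with `onset_rate` (Hz elevation), `onset_prob` and
#'   `sustained_rate` (Hz elevation).
#' @export
evoked_metrics <- function(trains, onset_window = c(0, 100),
                           sustained_window = c(100, 700),
                           ongoing_window = c(-200, 0)) {
  stopifnot(inherits(trains, "spike_train_set"))
  ong <- ongoing_rate(trains, ongoing_window)
  onset_abs <- pooled_rate(trains, onset_window[1], onset_window[2])
  sus_abs <- pooled_rate(trains, sustained_window[1], sustained_window[2])
  prob <- mean(vapply(trains$trials, function(t)
    any(t >= onset_window[1] & t < onset_window[2]), logical(1)))
  list(onset_rate = onset_abs - ong, onset_prob = prob,
       sustained_rate = sus_abs - ong)
}

#' All spiking metrics of one cell
#'
#' Convenience wrapper returning ongoing rate, 100/200 Hz burst
#' percentages, onset rate and probability and sustained rate as a one-row
#' data frame.
#'
#' @inheritParams evoked_metrics
#' @return one-row data frame.
#' @export
activity_metrics <- function(trains, onset_window = c(0, 100),
                             sustained_window = c(100, 700),
                             ongoing_window = c(-200, 0)) {
  ev <- evoked_metrics(trains, onset_window, sustained_window,
                       ongoing_window)
  data.frame(ongoing_rate = ongoing_rate(trains, ongoing_window),
             burst100_pct = as.numeric(burst_fraction(trains, 100,
                                                      ongoing_window)),
             burst200_pct = as.numeric(burst_fraction(trains, 200,
                                                      ongoing_window)),
             onset_rate = ev$onset_rate, onset_prob = ev$onset_prob,
             sustained_rate = ev$sustained_rate)
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat("Spike train set: ", n_trials(x), " trials, window [",
      x$window[1], ", ", x$window[2], "] ms, ",
      sum(lengths(x$trials)), " spikes\n", sep = "")
  invisible(x)
}

#' @export
print.psth <- function(x, ...) {
  cat("PSTH: ", length(x$rate), " bins of ", x$bin_width, " ms, ",
      x$n_trials, " trials, peak ", sprintf("%.1f", max(x$rate)),
      " Hz\n", sep = "")
  invisible(x)
}
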