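# helpers: sample indices of a time window given relative to a stimulus onset
.window_idx <- function(trace, stim_s, window) {
  from <- stim_s + window[1]
  to <- stim_s + window[2]
  n <- length(trace$samples)
  i0 <- floor(from * trace$fs) + 1
  i1 <- ceiling(to * trace$fs)
  if (i0 < 1 || i1 > n || i1 < i0) {
    stop("measurement window [", from, ", ", to, "] s lies outside the trace")
  }
  i0:i1
}

#' Optically evoked EPSC amplitude
#'
#' Amplitude of an evoked current: the absolute difference between the
#' extremum inside the post-stimulus search window and the mean of the
#' pre-stimulus baseline window. Inward currents are negative by convention;
#' the returned amplitude is a positive magnitude.
#'
#' @param trace a [sweep_trace()].
#' @param baseline_window,search_window two-element numeric windows in
#'   seconds relative to the stimulus onset (baseline before, search after).
#' @param stim_index which stimulus onset of the trace to measure.
#' @return Amplitude (same units as the trace samples), positive.
#' @export
oepsc_amplitude <- function(trace, baseline_window = c(-0.05, 0),
                            search_window = c(0.002, 0.05), stim_index = 1) {
  stopifnot(inherits(trace, "sweep_trace"))
  if (stim_index > length(trace$stim_onsets_s)) {
    stop("oepsc_amplitude: trace has no stimulus ", stim_index)
  }
  stim <- trace$stim_onsets_s[stim_index]
  base <- mean(trace$samples[.window_idx(trace, stim, baseline_window)])
  seg <- trace$samples[.window_idx(trace, stim, search_window)]
  dev <- seg - base
  abs(dev[which.max(abs(dev))])
}

#' AMPA/NMDA current ratio from a -80/+40 mV trace pair
#'
#' The AMPA component is the evoked peak amplitude at -80 mV (where NMDA
#' receptors are magnesium-blocked). The NMDA component is the
#' baseline-subtracted mean current over the 100-125 ms post-stimulus window
#' at +40 mV, where the fast AMPA current has fully decayed. When the window
#' mean does not exceed the noise floor (a multiple of the standard error of
#' the baseline estimate), the ratio is flagged undefined rather than
#' returned as a number.
#'
#' @param trace_minus80 voltage-clamp trace held at -80 mV.
#' @param trace_plus40 voltage-clamp trace held at +40 mV, same stimulus.
#' @param nmda_window NMDA measurement window, seconds post-stimulus.
#' @param baseline_window,search_window windows for the AMPA peak, as in
#'   [oepsc_amplitude()].
#' @param noise_mult the NMDA window mean must exceed `noise_mult` standard
#'   errors of the baseline noise to count as defined.
#' @return A list with `ampa`, `nmda`, `ratio` (`NA` when undefined) and
#'   `undefined`.
#' @export
ampa_nmda_ratio <- function(trace_minus80, trace_plus40,
                            nmda_window = c(0.100, 0.125),
                            baseline_window = c(-0.05, 0),
                            search_window = c(0.002, 0.05), noise_mult = 3) {
  stopifnot(inherits(trace_minus80, "sweep_trace"),
            inherits(trace_plus40, "sweep_trace"))
  if (abs(trace_minus80$holding_mV + 80) > 1e-6 ||
      abs(trace_plus40$holding_mV - 40) > 1e-6) {
    stop("ampa_nmda_ratio: traces must be held at -80 and +40 mV")
  }
  ampa <- oepsc_amplitude(trace_minus80, baseline_window, search_window)
  stim <- trace_plus40$stim_onsets_s[1]
  base_idx <- .window_idx(trace_plus40, stim, baseline_window)
  base <- mean(trace_plus40$samples[base_idx])
  win <- trace_plus40$samples[.window_idx(trace_plus40, stim, nmda_window)]
  nmda <- mean(win) - base
  floor_pA <- max(noise_mult * stats::sd(trace_plus40$samples[base_idx]) /
                    sqrt(length(win)),
                  1e-6 * ampa)  # numeric floor for noiseless traces
  undefined <- !is.finite(nmda) || nmda <= floor_pA
  list(ampa = ampa, nmda = nmda,
       ratio = if (undefined) NA_real_ else ampa / nmda,
       undefined = undefined)
}

#' Paired-pulse ratio of optically evoked EPSCs
#'
#' Two stimuli separated by 50-200 ms; up to three technical replicates are
#' averaged. First-pulse amplitudes are measured against the pre-stimulation
#' baseline; second-pulse amplitudes against the tail current immediately
#' preceding the second stimulus (so the decaying first response does not
#' inflate the second). The ratio is mean(P2) / mean(P1).
#'
#' @param replicates a [sweep_trace()] or list of 1-3 of them, each with two
#'   stimulus onsets.
#' @param baseline_window pre-stimulus baseline for the first pulse, seconds
#'   relative to the first stimulus.
#' @param tail_window window defining the tail-current baseline, seconds
#'   relative to the second stimulus (default the 5 ms just before it).
#' @param search_window post-stimulus extremum search window; for the first
#'   pulse it is truncated at the second stimulus.
#' @return A list with `ppr` (`NA` when mean P1 is 0), `p1`, `p2` (per
#'   replicate), and `undefined`.
#' @export
paired_pulse_ratio <- function(replicates, baseline_window = c(-0.05, 0),
                               tail_window = c(-0.005, 0),
                               search_window = c(0.002, 0.05)) {
  if (inherits(replicates, "sweep_trace")) replicates <- list(replicates)
  if (!length(replicates) || length(replicates) > 3) {
    stop("paired_pulse_ratio: supply 1-3 replicate traces")
  }
  p1 <- p2 <- numeric(length(replicates))
  for (i in seq_along(replicates)) {
    tr <- replicates[[i]]
    stopifnot(inherits(tr, "sweep_trace"))
    if (length(tr$stim_onsets_s) != 2) {
      stop("paired_pulse_ratio: each replicate needs exactly 2 stimuli")
    }
    isi <- diff(tr$stim_onsets_s)
    s1 <- tr$stim_onsets_s[1]
    s2 <- tr$stim_onsets_s[2]
    w1 <- c(search_window[1], min(search_window[2], isi - 1 / tr$fs))
    base1 <- mean(tr$samples[.window_idx(tr, s1, baseline_window)])
    seg1 <- tr$samples[.window_idx(tr, s1, w1)] - base1
    p1[i] <- abs(seg1[which.max(abs(seg1))])
    tail <- mean(tr$samples[.window_idx(tr, s2, tail_window)])
    seg2 <- tr$samples[.window_idx(tr, s2, search_window)] - tail
    p2[i] <- abs(seg2[which.max(abs(seg2))])
  }
  undefined <- mean(p1) == 0
  list(ppr = if (undefined) NA_real_ else mean(p2) / mean(p1),
       p1 = p1, p2 = p2, undefined = undefined)
}

#' Optically evoked population-spike amplitude
#'
#' Field-potential analogue of [oepsc_amplitude()]: the negative-going
#' population spike measured from the pre-stimulus baseline (default), or
#' peak-to-peak within the search window.
#'
#' @inheritParams oepsc_amplitude
#' @param convention `"baseline_to_peak"` (baseline minus negative peak) or
#'   `"peak_to_peak"`.
#' @return Amplitude in trace units (mV for field traces), positive.
#' @export
population_spike_amplitude <- function(trace, baseline_window = c(-0.05, 0),
                                       search_window = c(0.002, 0.05),
                                       convention = c("baseline_to_peak",
                                                      "peak_to_peak")) {
  convention <- match.arg(convention)
  stopifnot(inherits(trace, "sweep_trace"))
  stim <- trace$stim_onsets_s[1]
  base <- mean(trace$samples[.window_idx(trace, stim, baseline_window)])
  seg <- trace$samples[.window_idx(trace, stim, search_window)]
  switch(convention,
         baseline_to_peak = base - min(seg),
         peak_to_peak = max(seg) - min(seg))
}

#' Detect spontaneous EPSCs in a gap-free recording
#'
#' A transparent amplitude-threshold detector: inward (negative) deviations
#' from the local baseline that exceed `threshold` open an event; crossings
#' closer than the refractory window merge. Per event it reports the peak
#' amplitude against a local pre-onset baseline, the 10-90 percent rise time,
#' and a single-exponential decay constant fitted to the falling phase
#' (nonlinear least squares, log-linear fallback).
#'
#' @param trace a gap-free [sweep_trace()].
#' @param threshold detection threshold in pA, > 0 (should exceed the noise
#'   standard deviation).
#' @param refractory_s crossings closer than this merge into one event.
#' @param baseline_s span of the local pre-onset baseline window.
#' @param baseline_gap_s gap left between the baseline window and the
#'   threshold crossing, so the event's own rising phase does not bias the
#'   baseline.
#' @param max_decay_s longest falling-phase segment used for the tau fit.
#' @return A list of class `sepsc_events`: `events` (data frame with
#'   `time_s`, `amplitude`, `rise_10_90_s`, `decay_tau_s`),
#'   `inter_event_intervals_s`, `frequency_hz`, `n`, `duration_s`.
#' @export
detect_sepscs <- function(trace, threshold, refractory_s = 0.002,
                          baseline_s = 0.005, baseline_gap_s = 0.003,
                          max_decay_s = 0.04) {
  stopifnot(inherits(trace, "sweep_trace"))
  if (threshold <= 0) stop("detect_sepscs: threshold must be > 0")
  x <- trace$samples
  fs <- trace$fs
  n <- length(x)
  duration <- n / fs
  global_base <- stats::median(x)
  below <- (x - global_base) < -threshold
  empty <- list(events = data.frame(time_s = numeric(0),
                                    amplitude = numeric(0),
                                    rise_10_90_s = numeric(0),
                                    decay_tau_s = numeric(0)),
                inter_event_intervals_s = numeric(0), frequency_hz = 0,
                n = 0L, duration_s = duration)
  class(empty) <- "sepsc_events"
  if (!any(below)) return(empty)
  idx <- which(below)
  gap <- round(refractory_s * fs)
  starts <- idx[c(TRUE, diff(idx) > gap)]
  ends <- idx[c(diff(idx) > gap, TRUE)]
  ev <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    hi <- starts[i] - round(baseline_gap_s * fs)
    lo <- max(1, hi - round(baseline_s * fs))
    local_base <- if (hi - lo >= 5) mean(x[lo:hi]) else global_base
    seg_end <- min(n, ends[i] + round(max_decay_s * fs))
    if (i < length(starts)) seg_end <- min(seg_end, starts[i + 1] - 1)
    seg <- x[starts[i]:seg_end] - local_base
    pk <- which.min(seg)
    amp <- -seg[pk]
    # 10-90% rise over the leading edge of the event
    lead <- seg[1:pk]
    i10 <- which(-lead >= 0.1 * amp)[1]
    i90 <- which(-lead >= 0.9 * amp)[1]
    rise <- if (is.na(i10) || is.na(i90)) NA_real_ else (i90 - i10) / fs
    decay <- -seg[pk:length(seg)]
    tau <- fit_decay_tau(decay, fs)
    ev[[i]] <- data.frame(time_s = (starts[i] - 1) / fs, amplitude = amp,
                          rise_10_90_s = rise, decay_tau_s = tau)
  }
  events <- do.call(rbind, ev)
  out <- list(events = events,
              inter_event_intervals_s = diff(events$time_s),
              frequency_hz = nrow(events) / duration,
              n = nrow(events), duration_s = duration)
  class(out) <- "sepsc_events"
  out
}

# single-exponential tau for a positive decaying segment (peak first); the
# fit starts below 85% of the peak, past the residual rising-phase component
fit_decay_tau <- function(decay, fs, start_frac = 0.85) {
  peak <- decay[1]
  i0 <- which(decay <= start_frac * peak)[1]
  if (is.na(i0)) return(NA_real_)
  d <- decay[i0:length(decay)]
  t <- (seq_along(d) - 1) / fs
  keep <- d > 0.02 * peak
  if (sum(keep) < 4) return(NA_real_)
  fit <- tryCatch(
    stats::nls(y ~ A * exp(-t / tau),
               data = list(y = d[keep], t = t[keep]),
               start = list(A = d[1], tau = max(t[keep]) / 3)),
    error = function(e) NULL)
  if (!is.null(fit)) return(unname(stats::coef(fit)[["tau"]]))
  lf <- stats::lm(log(d[keep]) ~ t[keep])
  -1 / unname(stats::coef(lf)[2])
}

#' @export
print.sepsc_events <- function(x, ...) {
  cat(sprintf(
    "<sepsc_events> %d events in %.1f s (%.2f Hz), median amplitude %.1f\n",
    x$n, x$duration_s, x$frequency_hz,
    if (x$n) stats::median(x$events$amplitude) else NA_real_))
  invisible(x)
}

#' Series-resistance quality control
#'
#' A whole-cell recording is excluded when its series resistance exceeds the
#' absolute limit at either end of the recording, or drifts by more than the
#' allowed fraction of its starting value.
#'
#' @param series_resistance_start,series_resistance_end access resistance at
#'   the start and end of the recording, megaohms (vectorized).
#' @param limit_mohm absolute ceiling (default 25).
#' @param max_drift allowed fractional change (default 0.15).
#' @return Data frame with `keep` (logical) and `reason` (empty when kept).
#' @examples
#' qc_filter(c(10, 26, 20), c(10, 26, 23.5))
#' @export
qc_filter <- function(series_resistance_start, series_resistance_end,
                      limit_mohm = 25, max_drift = 0.15) {
  rs0 <- series_resistance_start
  rs1 <- series_resistance_end
  if (any(rs0 <= 0) || any(rs1 <= 0)) {
    stop("qc_filter: series resistances must be positive")
  }
  over <- rs0 > limit_mohm | rs1 > limit_mohm
  drift <- abs(rs1 - rs0) / rs0 > max_drift
  reason <- character(length(rs0))
  reason[drift] <- sprintf("drift > %.0f%%", 100 * max_drift)
  reason[over] <- sprintf("> %g MOhm", limit_mohm)
  data.frame(keep = !(over | drift), reason = reason)
}
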