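#' Sampled current/field trace container
#'
#' @param samples numeric vector of samples (pA for voltage-clamp currents,
#'   mV for field recordings), inward currents negative.
#' @param fs sampling rate, Hz (default 10 kHz).
#' @param holding_mV holding potential for voltage-clamp traces.
#' @param stim_onsets_s optical stimulus onset times, seconds from trace start.
#' @param light_power_mW LED power, if applicable.
#' @return A list of class `sweep_trace`.
#' @export
sweep_trace <- function(samples, fs = 10000, holding_mV = -60,
                        stim_onsets_s = numeric(), light_power_mW = NA_real_) {
  if (fs <= 0) stop("sweep_trace: sampling rate must be > 0")
  if (any(!is.finite(samples))) stop("sweep_trace: samples must be finite")
  dur <- length(samples) / fs
  if (length(stim_onsets_s) &&
      (any(stim_onsets_s < 0) || any(stim_onsets_s >= dur))) {
    stop("sweep_trace: stimulus onsets must lie within the trace")
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 holding_mV = holding_mV,
                 stim_onsets_s = as.numeric(stim_onsets_s),
                 light_power_mW = light_power_mW),
            class = "sweep_trace")
}

#' @export
print.sweep_trace <- function(x, ...) {
  cat(sprintf(
    "<sweep_trace> %.3f s @ %g kHz, holding %g mV, %d stimulus(es)\n",
    length(x$samples) / x$fs, x$fs / 1000, x$holding_mV,
    length(x$stim_onsets_s)))
  invisible(x)
}

# difference-of-exponentials synaptic waveform, peak-normalized to `amp`;
# positive-going template, caller applies the sign convention
synaptic_waveform <- function(t, amp, tau_rise, tau_decay) {
  if (tau_rise >= tau_decay) {
    stop("synaptic waveform: tau_rise must be shorter than tau_decay")
  }
  t_peak <- log(tau_decay / tau_rise) / (1 / tau_rise - 1 / tau_decay)
  peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  w <- ifelse(t < 0, 0, exp(-pmax(t, 0) / tau_decay) -
                exp(-pmax(t, 0) / tau_rise))
  amp * w / peak
}

# sampled waveform rescaled so the emitted trace's own peak equals `amp`
# exactly (the analytic peak falls between sample points)
sampled_event <- function(t, amp, tau_rise, tau_decay) {
  w <- synaptic_waveform(t, 1, tau_rise, tau_decay)
  m <- max(w)
  if (m > 0) w * (amp / m) else w
}

#' Generate synthetic electrophysiology sweeps with known ground truth
#'
#' Builds voltage-clamp or field traces from difference-of-exponential
#' synaptic waveforms plus Gaussian noise, with the quantity of interest
#' configured exactly: evoked input-output amplitudes (`"oepsc"`, `"ops"`),
#' paired pulses of known ratio (`"ppr"`), an AMPA peak at -80 mV together
#' with a +40 mV trace whose 100-125 ms window mean is set exactly
#' (`"ampa_nmda"`), or a Poisson train of spontaneous events (`"sepsc"`).
#'
#' @param kind one of `"oepsc"`, `"ppr"`, `"ampa_nmda"`, `"ops"`, `"sepsc"`.
#' @param params named list of overrides of the per-kind defaults (see the
#'   function body; amplitudes in pA, mV for `"ops"`, times in seconds).
#' @param seed RNG seed for the noise and event times.
#' @return A list with `kind`, `traces` (list of [sweep_trace()]; for
#'   `"ampa_nmda"` named `minus80`/`plus40`), and `ground_truth` (the
#'   configured amplitudes, ratios, window means, and event times).
#' @examples
#' sw <- generate_sweeps("ppr", list(noise_sd = 0))
#' sw$ground_truth$ppr
#' @export
generate_sweeps <- function(kind = c("oepsc", "ppr", "ampa_nmda", "ops",
                                     "sepsc"),
                            params = list(), seed = 1) {
  kind <- match.arg(kind)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  defaults <- switch(kind,
    oepsc = list(fs = 10000, stim_s = 0.1, duration_s = 0.5,
                 light_powers_mW = seq(0, 1, length.out = 6),
                 max_amp_pA = 600, half_power_mW = 0.3,
                 tau_rise = 0.001, tau_decay = 0.008, noise_sd = 2,
                 n_per_power = 3, holding_mV = -60),
    ppr = list(fs = 10000, stim_s = 0.1, duration_s = 0.5, isi_s = 0.1,
               p1_amp_pA = 200, ppr = 0.75, tau_rise = 0.001,
               tau_decay = 0.008, noise_sd = 2, n_replicates = 3,
               holding_mV = -60),
    ampa_nmda = list(fs = 10000, stim_s = 0.1, duration_s = 0.6,
                     ampa_amp_pA = 300, ampa_tau_rise = 0.001,
                     ampa_tau_decay = 0.005, ampa_plus40_pA = 100,
                     nmda_window_mean_pA = 150, nmda_tau_rise = 0.005,
                     nmda_tau_decay = 0.08, window_s = c(0.100, 0.125),
                     noise_sd = 2),
    ops = list(fs = 10000, stim_s = 0.1, duration_s = 0.3,
               light_powers_mW = seq(0, 1.15, length.out = 7),
               max_amp_mV = 1.2, half_power_mW = 0.4, tau_rise = 0.001,
               tau_decay = 0.006, noise_sd = 0.02, n_per_power = 3),
    sepsc = list(fs = 10000, duration_s = 120, rate_hz = 2,
                 amp_meanlog = log(30), amp_sdlog = 0.2, tau_rise = 0.001,
                 tau_decay = 0.005, noise_sd = 1.5, min_separation_s = 0.05,
                 holding_mV = -60)
  )
  bad <- setdiff(names(params), names(defaults))
  if (length(bad)) {
    stop("generate_sweeps(", kind, "): unknown parameter(s): ",
         paste(bad, collapse = ", "))
  }
  p <- utils::modifyList(defaults, params)
  t_of <- function() seq(0, p$duration_s - 1 / p$fs, by = 1 / p$fs)

  if (kind %in% c("oepsc", "ops")) {
    t <- t_of()
    sat <- function(pw) if (pw <= 0) 0 else
      (if (kind == "oepsc") p$max_amp_pA else p$max_amp_mV) *
      pw / (pw + p$half_power_mW)
    traces <- list()
    gt_amp <- numeric(0)
    for (pw in p$light_powers_mW) {
      a <- sat(pw)
      for (r in seq_len(p$n_per_power)) {
        clean <- -sampled_event(t - p$stim_s, a, p$tau_rise, p$tau_decay)
        traces[[length(traces) + 1]] <- sweep_trace(
          clean + stats::rnorm(length(t), 0, p$noise_sd), fs = p$fs,
          holding_mV = if (kind == "oepsc") p$holding_mV else NA_real_,
          stim_onsets_s = p$stim_s, light_power_mW = pw)
        gt_amp <- c(gt_amp, a)
      }
    }
    return(list(kind = kind, traces = traces,
                ground_truth = list(amplitude = gt_amp,
                                    light_power_mW = rep(p$light_powers_mW,
                                                         each = p$n_per_power))))
  }

  if (kind == "ppr") {
    t <- t_of()
    p2 <- p$p1_amp_pA * p$ppr
    traces <- lapply(seq_len(p$n_replicates), function(r) {
      clean <- -sampled_event(t - p$stim_s, p$p1_amp_pA, p$tau_rise,
                              p$tau_decay) -
        sampled_event(t - p$stim_s - p$isi_s, p2, p$tau_rise, p$tau_decay)
      sweep_trace(clean + stats::rnorm(length(t), 0, p$noise_sd), fs = p$fs,
                  holding_mV = p$holding_mV,
                  stim_onsets_s = c(p$stim_s, p$stim_s + p$isi_s))
    })
    return(list(kind = kind, traces = traces,
                ground_truth = list(p1_amp = p$p1_amp_pA, p2_amp = p2,
                                    ppr = p$ppr, isi_s = p$isi_s)))
  }

  if (kind == "ampa_nmda") {
    t <- t_of()
    minus80_clean <- -sampled_event(t - p$stim_s, p$ampa_amp_pA,
                                    p$ampa_tau_rise, p$ampa_tau_decay)
    # at +40 mV: fast outward AMPA component plus NMDA; scale the NMDA
    # waveform so the 100-125 ms post-stimulus window mean is exact
    win <- t >= p$stim_s + p$window_s[1] & t < p$stim_s + p$window_s[2]
    ampa40 <- sampled_event(t - p$stim_s, p$ampa_plus40_pA,
                            p$ampa_tau_rise, p$ampa_tau_decay)
    nmda_unit <- synaptic_waveform(t - p$stim_s, 1, p$nmda_tau_rise,
                                   p$nmda_tau_decay)
    scale <- (p$nmda_window_mean_pA - mean(ampa40[win])) / mean(nmda_unit[win])
    plus40_clean <- ampa40 + scale * nmda_unit
    traces <- list(
      minus80 = sweep_trace(minus80_clean +
                              stats::rnorm(length(t), 0, p$noise_sd),
                            fs = p$fs, holding_mV = -80,
                            stim_onsets_s = p$stim_s),
      plus40 = sweep_trace(plus40_clean +
                             stats::rnorm(length(t), 0, p$noise_sd),
                           fs = p$fs, holding_mV = 40,
                           stim_onsets_s = p$stim_s))
    return(list(kind = kind, traces = traces,
                ground_truth = list(ampa_amp = p$ampa_amp_pA,
                                    nmda_window_mean = p$nmda_window_mean_pA,
                                    ratio = p$ampa_amp_pA /
                                      p$nmda_window_mean_pA)))
  }

  # sepsc: Poisson event train over a gap-free recording
  t <- t_of()
  n_ev <- stats::rpois(1, p$rate_hz * p$duration_s)
  times <- sort(stats::runif(n_ev, 0.01, p$duration_s - 0.03))
  if (length(times) > 1) {
    times <- times[c(TRUE, diff(times) >= p$min_separation_s)]
  }
  amps <- stats::rlnorm(length(times), p$amp_meanlog, p$amp_sdlog)
  clean <- numeric(length(t))
  for (i in seq_along(times)) {
    clean <- clean - sampled_event(t - times[i], amps[i], p$tau_rise,
                                   p$tau_decay)
  }
  list(kind = kind,
       traces = list(sweep_trace(clean + stats::rnorm(length(t), 0,
                                                      p$noise_sd),
                                 fs = p$fs, holding_mV = p$holding_mV)),
       ground_truth = list(times_s = times, amplitudes = amps,
                           rate_hz = p$rate_hz, tau_decay = p$tau_decay,
                           tau_rise = p$tau_rise))
}
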