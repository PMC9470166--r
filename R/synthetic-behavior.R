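#' Cohort design for the synthetic drinking study
#'
#' Defines the simulated study layout: animals per fluid-by-virus class and
#' the weekly schedule of four 2 h sessions plus one 4 h session. The default
#' class sizes mirror a typical unbalanced optogenetic cohort (more
#' fluorophore-only controls in the water arm).
#'
#' @param n_per_class named integer vector over the four classes
#'   `water:ChR2`, `water:eGFP`, `alcohol:ChR2`, `alcohol:eGFP`.
#' @param weeks number of drinking weeks.
#' @param sessions_per_week sessions per week; the last session of each week
#'   is the long (4 h) one, the others are 2 h.
#' @param seed cohort-level seed. Each animal draws from its own derived
#'   substream, so adding an animal never perturbs existing animals' data.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_class = c("water:ChR2" = 8, "water:eGFP" = 11,
                                          "alcohol:ChR2" = 8,
                                          "alcohol:eGFP" = 8),
                          weeks = 6, sessions_per_week = 5, seed = 1) {
  classes <- c("water:ChR2", "water:eGFP", "alcohol:ChR2", "alcohol:eGFP")
  miss <- setdiff(classes, names(n_per_class))
  if (length(miss)) {
    stop("cohort_config: n_per_class must name: ", paste(miss, collapse = ", "))
  }
  if (any(n_per_class < 0)) stop("cohort_config: counts must be >= 0")
  structure(list(n_per_class = n_per_class[classes], weeks = as.integer(weeks),
                 sessions_per_week = as.integer(sessions_per_week),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generative parameters for drinking behavior
#'
#' The generator models each session as: a log-normal latency to the first
#' bout; bouts of log-normally distributed active-licking duration, licked at
#' a fixed within-bout rate with a fixed tongue-contact time per lick; and
#' gamma-distributed inter-bout gaps (bout end to next bout start), divided
#' by a front-loading boost during the first 30 minutes. Class structure
#' enters as multiplicative effects on the gap mean, bout duration,
#' front-loading boost and latency, with an extra channelrhodopsin-by-alcohol
#' deficit in weeks 5-6 (fewer/shorter bouts, less front-loading). Rare leak
#' and chew event clusters contaminate the stream with the long-duration /
#' few-licks and many-licks / short-duration signatures that the cleaning
#' model is built to catch. Intake is a noisy monotone function of the true
#' drinking lick duration. Effect magnitudes are free parameters chosen to
#' match the direction and week-specificity of the modelled study design, not
#' fitted to any data.
#'
#' @param ... overrides for any default parameter (see the function body for
#'   the full registry and units).
#' @param effect_scale exponent applied to every class multiplier: 0 collapses
#'   all classes onto the shared baseline (no class signal), 1 gives the
#'   default effect sizes, larger values exaggerate them.
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(..., effect_scale = 1) {
  p <- list(
    latency_meanlog = log(240), latency_sdlog = 0.5,   # s to first bout
    ibi_shape = 1.5, ibi_mean_s = 300,                 # gamma gaps, end->start
    bout_duration_meanlog = log(4), bout_duration_sdlog = 0.5,  # s of licking
    lick_rate_hz = 7, lick_contact_s = 0.05, lick_contact_jitter = 0.15,
    front_window_s = 1800, front_boost = 1.8,
    bout_rate_scale = 1,                                # 0 silences the cohort
    ml_per_lick_s = 0.03, intake_noise_cv = 0.05,
    leak_prob = 0.01, chew_prob = 0.01,                # per-session rates
    body_weight_mean_g = 27, body_weight_sd_g = 1.5,
    bottle_pre_min_g = 45, bottle_pre_max_g = 55,
    densities = list(water = 1.000, solution = 0.970, ethanol = 0.789),
    # class multipliers: gap mean, bout duration, front boost, latency
    class_effects = list(
      "water:ChR2" = c(gap = 1.18, dur = 0.95, front = 1.00, lat = 1.10),
      "water:eGFP" = c(gap = 1.00, dur = 1.00, front = 1.00, lat = 1.00),
      "alcohol:ChR2" = c(gap = 0.80, dur = 1.40, front = 1.60, lat = 0.70),
      "alcohol:eGFP" = c(gap = 0.80, dur = 1.40, front = 1.60, lat = 0.70)),
    # extra deficit for alcohol:ChR2 during stimulation weeks 5-6:
    # -30% bouts (1/0.7 on the gap mean), -30% licks, -40% front-loading
    chr2_alcohol_week56 = c(gap = 1 / 0.7, dur = 0.7, front = 0.6, lat = 1.0),
    effect_scale = effect_scale
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) {
    stop("behavior_params: unknown parameter(s): ", paste(bad, collapse = ", "))
  }
  p[names(over)] <- over
  if (p$ibi_shape <= 0 || p$ibi_mean_s <= 0 || p$lick_rate_hz <= 0 ||
      p$lick_contact_s <= 0 || p$front_boost <= 0 || p$bout_rate_scale < 0) {
    stop("behavior_params: rates, boosts and scales must be positive")
  }
  if (p$lick_contact_jitter < 0 || p$lick_contact_jitter >= 1) {
    stop("behavior_params: lick_contact_jitter must lie in [0, 1)")
  }
  if (p$lick_contact_s * (1 + p$lick_contact_jitter) >= 1 / p$lick_rate_hz) {
    stop("behavior_params: lick_contact_s must be shorter than the lick period")
  }
  if (p$leak_prob < 0 || p$leak_prob > 1 || p$chew_prob < 0 || p$chew_prob > 1) {
    stop("behavior_params: contamination probabilities must lie in [0, 1]")
  }
  structure(p, class = "behavior_params")
}

# class- and week-resolved session parameters under the effect_scale dial
resolve_session_params <- function(params, fluid, virus, week) {
  cls <- paste(fluid, virus, sep = ":")
  m <- params$class_effects[[cls]]
  if (cls == "alcohol:ChR2" && week >= 5) {
    m <- m * params$chr2_alcohol_week56
  }
  m <- m^params$effect_scale
  list(
    latency_meanlog = params$latency_meanlog + log(m[["lat"]]),
    latency_sdlog = params$latency_sdlog,
    ibi_shape = params$ibi_shape,
    ibi_mean_s = params$ibi_mean_s * m[["gap"]] /
      max(params$bout_rate_scale, .Machine$double.eps),
    bout_duration_meanlog = params$bout_duration_meanlog + log(m[["dur"]]),
    bout_duration_sdlog = params$bout_duration_sdlog,
    front_boost = params$front_boost * m[["front"]]
  )
}

# simulate one session's lick-event stream; RNG state is the caller's
simulate_session_events <- function(T_s, sp, params) {
  onsets <- numeric(0)
  offsets <- numeric(0)
  gaps <- numeric(0)
  latency <- NA_real_
  if (params$bout_rate_scale > 0) {
    latency <- stats::rlnorm(1, sp$latency_meanlog, sp$latency_sdlog)
    t <- latency
    period <- 1 / params$lick_rate_hz
    while (t + 2 <= T_s) {
      d <- stats::rlnorm(1, sp$bout_duration_meanlog, sp$bout_duration_sdlog)
      n <- max(1L, as.integer(round(d * params$lick_rate_hz)))
      on <- t + (seq_len(n) - 1) * period
      # tongue-contact time varies lick to lick, so licks-vs-duration is a
      # tight but not degenerate linear relation
      contact <- params$lick_contact_s *
        stats::runif(n, 1 - params$lick_contact_jitter,
                     1 + params$lick_contact_jitter)
      off <- on + contact
      keep <- off <= T_s
      if (!any(keep)) break
      onsets <- c(onsets, on[keep])
      offsets <- c(offsets, off[keep])
      g <- stats::rgamma(1, shape = sp$ibi_shape,
                         scale = sp$ibi_mean_s / sp$ibi_shape)
      gaps <- c(gaps, g)
      if (t < params$front_window_s) g <- g / sp$front_boost
      t <- max(off[keep]) + g
    }
  }
  contam <- data.frame(kind = character(0), start_s = numeric(0))
  for (kind in c("leak", "chew")) {
    prob <- if (kind == "leak") params$leak_prob else params$chew_prob
    if (stats::runif(1) >= prob) next
    if (kind == "leak") {
      rel_on <- c(0, 3.0); rel_off <- rel_on + 2.5   # 5 s blocked, 2 licks
    } else {
      rel_on <- (0:49) * 0.08; rel_off <- rel_on + 0.01  # 50 taps in 4 s
    }
    span <- max(rel_off)
    for (try in 1:20) {
      s0 <- stats::runif(1, 0, max(T_s - span - 3, 1))
      clear <- !any(onsets > s0 - 3 & onsets < s0 + span + 3)
      if (clear) {
        onsets <- c(onsets, s0 + rel_on)
        offsets <- c(offsets, s0 + rel_off)
        contam <- rbind(contam, data.frame(kind = kind, start_s = s0))
        break
      }
    }
  }
  ord <- order(onsets)
  list(events = data.frame(onset_s = onsets[ord], offset_s = offsets[ord]),
       latency = latency, gaps = gaps, contamination = contam)
}

#' Generate a synthetic drinking cohort
#'
#' Simulates every animal-session of the configured cohort: lick-event
#' streams with class- and week-dependent structure, the device's 2 s write
#' rule applied via [device_emulate()], bottle weights tied to the true
#' drinking lick duration, and rare leak/chew contamination. Ground truth
#' (event streams, drawn latencies and inter-bout gaps, contamination flags,
#' resolved per-session parameters) is returned alongside the sessions.
#'
#' @param config a [cohort_config()].
#' @param params a [behavior_params()].
#' @return A list of class `did_cohort` with elements `sessions` (list of
#'   [did_session()]), `ground_truth` (parallel list), `config`, `params`.
#' @examples
#' coh <- generate_cohort(cohort_config(c("water:ChR2" = 1, "water:eGFP" = 1,
#'                                        "alcohol:ChR2" = 1,
#'                                        "alcohol:eGFP" = 1), weeks = 1))
#' length(coh$sessions)
#' @export
generate_cohort <- function(config = cohort_config(),
                            params = behavior_params()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(params, "behavior_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  sessions <- list()
  truth <- list()
  n_sessions <- config$weeks * config$sessions_per_week
  classes <- names(config$n_per_class)
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    fluid <- sub(":.*", "", cls)
    virus <- sub(".*:", "", cls)
    n_animals <- config$n_per_class[[ci]]
    for (a in seq_len(n_animals)) {
      # per-animal substream: stable under cohort growth
      set.seed((config$seed * 48271 + ci * 100003 + a * 7919) %% 2147483647L)
      animal_id <- sprintf("%s_%s_%02d", fluid, virus, a)
      bw <- stats::rnorm(1, params$body_weight_mean_g, params$body_weight_sd_g)
      for (si in seq_len(n_sessions)) {
        week <- ceiling(si / config$sessions_per_week)
        long_day <- si %% config$sessions_per_week == 0
        T_h <- if (long_day) 4 else 2
        sp <- resolve_session_params(params, fluid, virus, week)
        sim <- simulate_session_events(T_h * 3600, sp, params)
        bouts <- device_emulate(sim$events)
        contam_bout <- rep(FALSE, nrow(bouts))
        for (cs in sim$contamination$start_s) {
          contam_bout <- contam_bout |
            (bouts$start_s <= cs + 1e-9 & bouts$end_s >= cs)
        }
        drink_dur <- sum(bouts$lick_duration_s[!contam_bout])
        dens <- if (fluid == "water") params$densities$water else
          params$densities$solution
        vol_ml <- params$ml_per_lick_s * drink_dur *
          max(0, 1 + stats::rnorm(1, 0, params$intake_noise_cv))
        pre <- stats::runif(1, params$bottle_pre_min_g, params$bottle_pre_max_g)
        s <- did_session(
          animal_id = animal_id, session_index = si, week = week,
          session_length_h = T_h, fluid = fluid, virus = virus,
          stim_mode = if (week >= 4) "closed_loop" else "none",
          bottle_pre_g = pre, bottle_post_g = pre - vol_ml * dens,
          body_weight_g = bw, bouts = bouts)
        sessions[[length(sessions) + 1]] <- s
        truth[[length(truth) + 1]] <- list(
          animal_id = animal_id, session_index = si, class = cls,
          events = sim$events, latency_s = sim$latency, gaps_s = sim$gaps,
          contamination = sim$contamination, contaminated_bout = contam_bout,
          resolved_params = sp)
      }
    }
  }
  structure(list(sessions = sessions, ground_truth = truth, config = config,
                 params = params),
            class = "did_cohort")
}

#' @export
print.did_cohort <- function(x, ...) {
  cat(sprintf("<did_cohort> %d animals, %d sessions (seed %d)\n",
              sum(x$config$n_per_class), length(x$sessions), x$config$seed))
  print(x$config$n_per_class)
  invisible(x)
}
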