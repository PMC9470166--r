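#' The canonical 18-feature microstructure registry
#'
#' Names, in fixed order, of the per-session drinking microstructure features
#' computed by [extract_features()]: session totals, per-bout means and
#' maxima, timing features (latency to drink, inter-drink intervals measured
#' bout-end to next bout-start), first-30-minute front-loading features, and
#' session rates.
#'
#' @return Character vector of length 18.
#' @export
feature_registry <- function() {
  c("total_licks", "total_lick_duration_s", "total_bouts",
    "mean_licks_per_bout", "mean_lick_duration_per_bout_s",
    "mean_bout_length_s", "latency_to_drink_s", "mean_inter_drink_interval_s",
    "max_bout_length_s", "max_licks_per_bout", "max_lick_duration_per_bout_s",
    "max_inter_drink_interval_s", "licks_first_30min",
    "lick_duration_first_30min_s", "bouts_first_30min", "lick_rate_per_min",
    "bout_rate_per_min", "front_loading_index")
}

#' Extract the 18 per-session microstructure features
#'
#' Computes the canonical feature vector from a session's (cleaned) bout
#' records. Degenerate sessions are imputed rather than dropped so the
#' feature matrix stays rectangular: with no bouts, totals, maxima, rates and
#' the front-loading index are 0 while latency and both inter-drink-interval
#' features are censored at the session length in seconds; with a single bout
#' the inter-drink intervals are likewise censored. A bout belongs to the
#' first 30 minutes when it starts before 1800 s.
#'
#' @param session a [did_session()] object.
#' @param front_window_s the front-loading window, seconds (default 1800).
#' @return Named numeric vector of length 18, ordered as [feature_registry()].
#' @examples
#' s <- did_session("m1", 1, 2, "water", "eGFP",
#'                  bottle_pre_g = 50, bottle_post_g = 49, body_weight_g = 25,
#'                  bouts = bout_records(60, 62, 5L, 0.25))
#' extract_features(s)
#' @export
extract_features <- function(session, front_window_s = 1800) {
  validate_did_session(session)
  b <- session$bouts
  T_s <- session$session_length_h * 3600
  T_min <- session$session_length_h * 60
  n <- nrow(b)
  f <- stats::setNames(numeric(18), feature_registry())
  if (n == 0) {
    f["latency_to_drink_s"] <- T_s
    f["mean_inter_drink_interval_s"] <- T_s
    f["max_inter_drink_interval_s"] <- T_s
    return(f)
  }
  len <- b$end_s - b$start_s
  idi <- if (n >= 2) b$start_s[-1] - b$end_s[-n] else NULL
  front <- b$start_s < front_window_s
  f["total_licks"] <- sum(b$n_licks)
  f["total_lick_duration_s"] <- sum(b$lick_duration_s)
  f["total_bouts"] <- n
  f["mean_licks_per_bout"] <- mean(b$n_licks)
  f["mean_lick_duration_per_bout_s"] <- mean(b$lick_duration_s)
  f["mean_bout_length_s"] <- mean(len)
  f["latency_to_drink_s"] <- b$start_s[1]
  f["mean_inter_drink_interval_s"] <- if (is.null(idi)) T_s else mean(idi)
  f["max_bout_length_s"] <- max(len)
  f["max_licks_per_bout"] <- max(b$n_licks)
  f["max_lick_duration_per_bout_s"] <- max(b$lick_duration_s)
  f["max_inter_drink_interval_s"] <- if (is.null(idi)) T_s else max(idi)
  f["licks_first_30min"] <- sum(b$n_licks[front])
  f["lick_duration_first_30min_s"] <- sum(b$lick_duration_s[front])
  f["bouts_first_30min"] <- sum(front)
  f["lick_rate_per_min"] <- sum(b$n_licks) / T_min
  f["bout_rate_per_min"] <- n / T_min
  f["front_loading_index"] <- sum(front) / max(n, 1)
  f
}

#' Build the per-session feature table for a cohort
#'
#' Applies [extract_features()] to every session and binds the results with
#' the identifying metadata and class labels, one row per animal-session.
#'
#' @param sessions list of [did_session()] objects.
#' @inheritParams extract_features
#' @return A data frame with columns `animal_id`, `session_index`, `week`,
#'   `session_length_h`, `fluid`, `virus`, then the 18 feature columns.
#' @export
featurize_sessions <- function(sessions, front_window_s = 1800) {
  rows <- lapply(sessions, function(s) {
    cbind(data.frame(animal_id = s$animal_id,
                     session_index = s$session_index, week = s$week,
                     session_length_h = s$session_length_h,
                     fluid = s$fluid, virus = s$virus),
          as.data.frame(as.list(extract_features(s, front_window_s))))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Fluid intake and dose from bottle weights
#'
#' Intake in grams is the pre/post difference in bottle weight. For water the
#' dose is simply grams consumed per kilogram body weight. For 20 percent
#' (v/v) alcohol, the consumed mass is converted to solution volume via the
#' solution density, and the ethanol dose is the ethanol fraction of that
#' volume times the density of ethanol, per kilogram body weight.
#'
#' @param session a [did_session()] object.
#' @param densities list with `water`, `solution` (the 20 percent v/v mix) and
#'   `ethanol` densities in g/ml.
#' @param ethanol_fraction volume fraction of ethanol in the alcohol bottle.
#' @return A list of class `intake_record` with `grams_consumed` and `dose`
#'   (g/kg: ethanol g/kg for alcohol sessions, fluid g/kg for water).
#' @examples
#' s <- did_session("m1", 1, 2, "alcohol", "ChR2",
#'                  bottle_pre_g = 50, bottle_post_g = 49.03,
#'                  body_weight_g = 25)
#' compute_intake(s)$dose  # 6.312 g/kg
#' @export
compute_intake <- function(session,
                           densities = list(water = 1.000, solution = 0.970,
                                            ethanol = 0.789),
                           ethanol_fraction = 0.20) {
  validate_did_session(session)
  if (!is.finite(session$body_weight_g) || session$body_weight_g <= 0) {
    stop("compute_intake: field body_weight_g must be > 0")
  }
  grams <- session$bottle_pre_g - session$bottle_post_g
  kg <- session$body_weight_g / 1000
  dose <- if (session$fluid == "water") {
    grams / kg
  } else {
    (grams / densities$solution) * ethanol_fraction * densities$ethanol / kg
  }
  structure(list(grams_consumed = grams, dose = dose, fluid = session$fluid),
            class = "intake_record")
}

#' Study-inclusion filter on summed early intake
#'
#' Animals must establish stable drinking during acquisition: per fluid group,
#' the intake summed across the first 15 sessions is compared against the
#' Tukey lower fence `Q1 - 1.5 * IQR` (linear-interpolation quantiles), and
#' animals strictly below the fence are excluded. Groups too small for stable
#' quartiles are passed through whole with a warning.
#'
#' @param intakes data frame with columns `animal_id`, `fluid`, and
#'   `total_intake` (summed g/kg over the acquisition sessions).
#' @param k fence multiplier (default 1.5).
#' @param min_group smallest group size on which quartiles are trusted.
#' @return A list with data frames `included` and `excluded`; `excluded`
#'   carries the fence that each animal fell below.
#' @export
inclusion_filter <- function(intakes, k = 1.5, min_group = 4) {
  stopifnot(all(c("animal_id", "fluid", "total_intake") %in% names(intakes)))
  if (nrow(intakes) == 0) {
    return(list(included = intakes, excluded = cbind(intakes,
                fence = numeric(0))))
  }
  inc <- list()
  exc <- list()
  for (fl in unique(intakes$fluid)) {
    g <- intakes[intakes$fluid == fl, , drop = FALSE]
    if (nrow(g) < min_group) {
      warning("inclusion_filter: fluid group '", fl, "' has fewer than ",
              min_group, " animals; all included", call. = FALSE)
      inc[[fl]] <- g
      next
    }
    q <- stats::quantile(g$total_intake, c(0.25, 0.75), type = 7, names = FALSE)
    fence <- q[1] - k * (q[2] - q[1])
    out <- g$total_intake < fence
    inc[[fl]] <- g[!out, , drop = FALSE]
    if (any(out)) exc[[fl]] <- cbind(g[out, , drop = FALSE], fence = fence)
  }
  empty <- intakes[0, , drop = FALSE]
  list(
    included = if (length(inc))
      do.call(rbind, c(inc, list(make.row.names = FALSE))) else empty,
    excluded = if (length(exc))
      do.call(rbind, c(exc, list(make.row.names = FALSE))) else
        cbind(empty, fence = numeric(0))
  )
}

#' Correlate lickometer totals with measured intake
#'
#' Checks that the beam-break record tracks what the bottle actually lost:
#' Pearson correlations of the session totals (licks, bouts, lick duration)
#' against the g/kg dose.
#'
#' Correlations are computed within fluid group (a water g/kg and an ethanol
#' g/kg are not on a common scale), unless `by` is overridden.
#'
#' @param feature_table output of [featurize_sessions()].
#' @param doses numeric vector of g/kg doses aligned with the rows of
#'   `feature_table`.
#' @param features which feature columns to correlate.
#' @param by grouping vector (default the table's `fluid` column; pass a
#'   constant to pool).
#' @return Data frame with columns `group`, `feature`, `r`, `p`, `n`; `r` is
#'   `NA` with `note = "zero variance"` when either variable is constant.
#' @export
intake_microstructure_correlation <- function(
    feature_table, doses,
    features = c("total_licks", "total_bouts", "total_lick_duration_s"),
    by = NULL) {
  if (length(doses) != nrow(feature_table)) {
    stop("intake_microstructure_correlation: doses must match rows")
  }
  if (is.null(by)) {
    by <- if ("fluid" %in% names(feature_table)) feature_table$fluid else
      rep("all", nrow(feature_table))
  }
  rows <- list()
  for (g in unique(by)) {
    i <- which(by == g)
    if (length(i) < 3) {
      stop("intake_microstructure_correlation: need >= 3 paired observations",
           " in group '", g, "'")
    }
    for (f in features) {
      x <- feature_table[[f]][i]
      d <- doses[i]
      rows[[paste(g, f)]] <- if (stats::sd(x) == 0 || stats::sd(d) == 0) {
        data.frame(group = g, feature = f, r = NA_real_, p = NA_real_,
                   n = length(i), note = "zero variance")
      } else {
        ct <- stats::cor.test(x, d, method = "pearson")
        data.frame(group = g, feature = f, r = unname(ct$estimate),
                   p = ct$p.value, n = length(i), note = "")
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
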