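# Independent reference implementations used as oracles. These are written
# as plain loops, deliberately avoiding the package's vectorized code paths.

# gap-scan bout segmentation: walk the event list, close a bout when the
# inter-onset gap exceeds `gap`, floor each span at `gap`
oracle_gap_scan <- function(onset, offset, gap = 2.0) {
  if (length(onset) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_licks = integer(0), lick_duration_s = numeric(0)))
  }
  bouts <- list()
  cur <- 1
  members <- 1
  for (i in seq_along(onset)[-1]) {
    if (onset[i] - onset[i - 1] > gap) {
      bouts[[length(bouts) + 1]] <- members
      members <- i
    } else {
      members <- c(members, i)
    }
  }
  bouts[[length(bouts) + 1]] <- members
  out <- lapply(bouts, function(m) {
    span <- max(offset[m]) - min(onset[m])
    if (span < gap) span <- gap
    data.frame(start_s = min(onset[m]), end_s = min(onset[m]) + span,
               n_licks = length(m), lick_duration_s = sum(offset[m] - onset[m]))
  })
  do.call(rbind, out)
}

# ordinary least squares by the normal equations, with residuals
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2],
       residuals = as.numeric(y - X %*% beta))
}

# single-pass reference feature extractor over a bout table
oracle_features <- function(bouts, session_length_h, front_window_s = 1800) {
  T_s <- session_length_h * 3600
  T_min <- session_length_h * 60
  n <- nrow(bouts)
  f <- c(total_licks = 0, total_lick_duration_s = 0, total_bouts = 0,
         mean_licks_per_bout = 0, mean_lick_duration_per_bout_s = 0,
         mean_bout_length_s = 0, latency_to_drink_s = T_s,
         mean_inter_drink_interval_s = T_s, max_bout_length_s = 0,
         max_licks_per_bout = 0, max_lick_duration_per_bout_s = 0,
         max_inter_drink_interval_s = T_s, licks_first_30min = 0,
         lick_duration_first_30min_s = 0, bouts_first_30min = 0,
         lick_rate_per_min = 0, bout_rate_per_min = 0,
         front_loading_index = 0)
  if (n == 0) return(f)
  idis <- c()
  for (i in seq_len(n)) {
    f["total_licks"] <- f["total_licks"] + bouts$n_licks[i]
    f["total_lick_duration_s"] <-
      f["total_lick_duration_s"] + bouts$lick_duration_s[i]
    len <- bouts$end_s[i] - bouts$start_s[i]
    if (len > f["max_bout_length_s"]) f["max_bout_length_s"] <- len
    if (bouts$n_licks[i] > f["max_licks_per_bout"]) {
      f["max_licks_per_bout"] <- bouts$n_licks[i]
    }
    if (bouts$lick_duration_s[i] > f["max_lick_duration_per_bout_s"]) {
      f["max_lick_duration_per_bout_s"] <- bouts$lick_duration_s[i]
    }
    if (i > 1) idis <- c(idis, bouts$start_s[i] - bouts$end_s[i - 1])
    if (bouts$start_s[i] < front_window_s) {
      f["licks_first_30min"] <- f["licks_first_30min"] + bouts$n_licks[i]
      f["lick_duration_first_30min_s"] <-
        f["lick_duration_first_30min_s"] + bouts$lick_duration_s[i]
      f["bouts_first_30min"] <- f["bouts_first_30min"] + 1
    }
  }
  f["total_bouts"] <- n
  f["mean_licks_per_bout"] <- f["total_licks"] / n
  f["mean_lick_duration_per_bout_s"] <- f["total_lick_duration_s"] / n
  f["mean_bout_length_s"] <- mean(bouts$end_s - bouts$start_s)
  f["latency_to_drink_s"] <- bouts$start_s[1]
  if (length(idis)) {
    f["mean_inter_drink_interval_s"] <- mean(idis)
    f["max_inter_drink_interval_s"] <- max(idis)
  }
  f["lick_rate_per_min"] <- f["total_licks"] / T_min
  f["bout_rate_per_min"] <- n / T_min
  f["front_loading_index"] <- f["bouts_first_30min"] / n
  f
}

# random sorted non-overlapping event stream for property tests
random_event_stream <- function(n, horizon = 600) {
  on <- sort(runif(n, 0, horizon))
  gap_to_next <- c(diff(on), Inf)
  len <- pmin(runif(n, 0.01, 0.2), gap_to_next * 0.9)
  list(onset = on, offset = on + len)
}

# random valid session for feature property tests
random_session <- function(id = "m1", idx = 1L, n_bouts = NULL) {
  len_h <- sample(c(2, 4), 1)
  if (is.null(n_bouts)) n_bouts <- sample(0:40, 1)
  if (n_bouts > 0) {
    start <- sort(runif(n_bouts, 0, len_h * 3600 - 40))
    span <- runif(n_bouts, 2, 30)
    span <- pmin(span, c(diff(start), Inf) * 0.9)
    span <- pmax(span, 2)
    # keep bouts non-overlapping: shrink any span that would cross its
    # successor's start
    for (i in seq_len(n_bouts - 1)) {
      if (start[i] + span[i] >= start[i + 1]) {
        start[i + 1] <- start[i] + span[i] + runif(1, 0.1, 5)
      }
    }
    keep <- start + span <= len_h * 3600
    start <- start[keep]; span <- span[keep]
    n_licks <- pmax(1L, as.integer(round(span * runif(length(span), 2, 7))))
    dur <- pmin(span * runif(length(span), 0.2, 0.9), span)
    b <- bout_records(start, start + span, n_licks, dur)
  } else {
    b <- bout_records()
  }
  did_session(id, idx, len_h, sample(c("water", "alcohol"), 1),
              sample(c("ChR2", "eGFP"), 1),
              bottle_pre_g = 50, bottle_post_g = 49, body_weight_g = 25,
              bouts = b)
}

# tiny balanced cohort config for classifier tests
small_cohort <- function(n = 2, weeks = 6, seed = 1) {
  cohort_config(c("water:ChR2" = n, "water:eGFP" = n, "alcohol:ChR2" = n,
                  "alcohol:eGFP" = n), weeks = weeks, seed = seed)
}
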