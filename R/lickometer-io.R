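#' Lick event streams
#'
#' A lick event is a single infrared beam-break at the spout, stored as a
#' half-open interval `[onset_s, offset_s)` in seconds from session start.
#' Events within a session must be non-overlapping and sorted by onset.
#'
#' @param onset_s,offset_s numeric vectors of beam-break onsets and offsets,
#'   in seconds from session start.
#' @return A `data.frame` of class `lick_events` with columns `onset_s`,
#'   `offset_s`.
#' @examples
#' lick_events(c(1.0, 1.4), c(1.05, 1.45))
#' @export
lick_events <- function(onset_s = numeric(), offset_s = numeric()) {
  ev <- data.frame(onset_s = as.numeric(onset_s),
                   offset_s = as.numeric(offset_s))
  validate_lick_events(ev)
  class(ev) <- c("lick_events", "data.frame")
  ev
}

#' @rdname lick_events
#' @param events a data frame with columns `onset_s` and `offset_s`.
#' @export
validate_lick_events <- function(events) {
  stopifnot(is.data.frame(events))
  need <- c("onset_s", "offset_s")
  miss <- setdiff(need, names(events))
  if (length(miss)) {
    stop("lick events: missing column(s): ", paste(miss, collapse = ", "))
  }
  on <- events$onset_s
  off <- events$offset_s
  if (any(!is.finite(on)) || any(!is.finite(off))) {
    stop("lick events: field onset_s/offset_s must be finite")
  }
  if (any(on < 0)) stop("lick events: field onset_s must be >= 0")
  if (any(off <= on)) stop("lick events: field offset_s must exceed onset_s")
  if (nrow(events) > 1) {
    if (is.unsorted(on, strictly = FALSE)) {
      stop("lick events: events must be sorted by onset_s")
    }
    # half-open intervals: an onset equal to the previous offset is legal
    if (any(on[-1] < off[-nrow(events)])) {
      stop("lick events: events must be non-overlapping")
    }
  }
  invisible(events)
}

#' Construct and validate bout records
#'
#' Bout records are the device-level aggregate the lickometer actually writes:
#' any tube interaction within a 2 s window forms one drinking bout, so a
#' recorded bout spans at least 2 s even when it holds a single lick.
#'
#' @param start_s,end_s bout start/end times in seconds from session start.
#' @param n_licks integer count of beam breaks in the bout.
#' @param lick_duration_s total beam-broken time within the bout, seconds.
#' @param min_span minimum recorded bout span in seconds (device write rule).
#' @return A `data.frame` of class `bout_records`.
#' @export
bout_records <- function(start_s = numeric(), end_s = numeric(),
                         n_licks = integer(), lick_duration_s = numeric(),
                         min_span = 2.0) {
  b <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                  n_licks = as.integer(n_licks),
                  lick_duration_s = as.numeric(lick_duration_s))
  validate_bout_records(b, min_span = min_span)
  class(b) <- c("bout_records", "data.frame")
  b
}

#' @rdname bout_records
#' @param bouts a data frame with the four bout columns.
#' @export
validate_bout_records <- function(bouts, min_span = 2.0) {
  need <- c("start_s", "end_s", "n_licks", "lick_duration_s")
  miss <- setdiff(need, names(bouts))
  if (length(miss)) {
    stop("bout records: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(bouts) == 0) return(invisible(bouts))
  span <- bouts$end_s - bouts$start_s
  if (any(span < min_span - 1e-9)) {
    stop("bout records: field end_s - start_s must be >= ", min_span, " s")
  }
  if (any(bouts$n_licks < 1)) stop("bout records: field n_licks must be >= 1")
  if (any(bouts$lick_duration_s <= 0)) {
    stop("bout records: field lick_duration_s must be > 0")
  }
  if (any(bouts$lick_duration_s > span + 1e-9)) {
    stop("bout records: field lick_duration_s must not exceed the bout span")
  }
  invisible(bouts)
}

#' A single animal-session record
#'
#' Bundles one animal's drinking-in-the-dark session: design metadata, bottle
#' weights, body weight, and the device-level bout records.
#'
#' @param animal_id character identifier.
#' @param session_index integer 1..30 within the study.
#' @param session_length_h session length in hours (2 on Mon-Thu, 4 on Fri).
#' @param fluid `"water"` or `"alcohol"`.
#' @param virus `"ChR2"` or `"eGFP"`.
#' @param stim_mode `"none"`, `"closed_loop"`, or `"open_loop"`.
#' @param bottle_pre_g,bottle_post_g bottle weight before/after, grams.
#' @param body_weight_g animal body weight, grams.
#' @param bouts a `bout_records` data frame (may have zero rows).
#' @param week drinking week; defaults to `ceiling(session_index / 5)`.
#' @return A list of class `did_session`.
#' @export
did_session <- function(animal_id, session_index, session_length_h, fluid,
                        virus, stim_mode = "none", bottle_pre_g, bottle_post_g,
                        body_weight_g, bouts = bout_records(),
                        week = ceiling(session_index / 5)) {
  s <- structure(list(
    animal_id = as.character(animal_id),
    session_index = as.integer(session_index),
    week = as.integer(week),
    session_length_h = as.numeric(session_length_h),
    fluid = as.character(fluid),
    virus = as.character(virus),
    stim_mode = as.character(stim_mode),
    bottle_pre_g = as.numeric(bottle_pre_g),
    bottle_post_g = as.numeric(bottle_post_g),
    body_weight_g = as.numeric(body_weight_g),
    bouts = bouts
  ), class = "did_session")
  validate_did_session(s)
  s
}

#' @rdname did_session
#' @param session a `did_session` object.
#' @export
validate_did_session <- function(session) {
  s <- session
  if (!s$fluid %in% c("water", "alcohol")) {
    stop("session ", s$animal_id, "/", s$session_index,
         ": field fluid must be 'water' or 'alcohol'")
  }
  if (!s$virus %in% c("ChR2", "eGFP")) {
    stop("session ", s$animal_id, "/", s$session_index,
         ": field virus must be 'ChR2' or 'eGFP'")
  }
  if (!s$stim_mode %in% c("none", "closed_loop", "open_loop")) {
    stop("session ", s$animal_id, "/", s$session_index,
         ": field stim_mode invalid")
  }
  if (!s$session_length_h %in% c(2, 4)) {
    stop("session ", s$animal_id, "/", s$session_index,
         ": field session_length_h must be 2 or 4")
  }
  if (is.na(s$bottle_post_g) || is.na(s$bottle_pre_g) ||
      s$bottle_post_g > s$bottle_pre_g + 1e-9) {
    stop("session ", s$animal_id, "/", s$session_index,
         ": field bottle_post_g must not exceed bottle_pre_g")
  }
  if (s$week != ceiling(s$session_index / 5)) {
    stop("session ", s$animal_id, "/", s$session_index,
         ": field week must equal ceiling(session_index / 5)")
  }
  validate_bout_records(s$bouts)
  if (nrow(s$bouts) && any(s$bouts$end_s > s$session_length_h * 3600 + 1e-9)) {
    stop("session ", s$animal_id, "/", s$session_index,
         ": field bouts: bout times exceed session length")
  }
  invisible(session)
}

#' @export
print.did_session <- function(x, ...) {
  cat(sprintf("<did_session> %s session %d (week %d, %g h, %s/%s, stim %s)\n",
              x$animal_id, x$session_index, x$week, x$session_length_h,
              x$fluid, x$virus, x$stim_mode))
  cat(sprintf("  %d bouts, %d licks, bottle %.2f -> %.2f g, body %.1f g\n",
              nrow(x$bouts), sum(x$bouts$n_licks), x$bottle_pre_g,
              x$bottle_post_g, x$body_weight_g))
  invisible(x)
}

#' Emulate the lickometer's 2 s device-write rule
#'
#' The device samples the beam continuously but only commits to memory at
#' minimum every 2 s, so consecutive licks whose inter-onset gaps never exceed
#' `gap` collapse into one drinking bout. A bout's recorded span is floored at
#' `gap` seconds: a solitary lick still produces a 2 s bout, and bouts can be
#' longer than 2 s but never shorter.
#'
#' @param events a `lick_events` data frame (sorted, non-overlapping).
#' @param gap the device write window in seconds (default 2.0). A new bout
#'   opens when more than `gap` seconds elapse after the previous lick onset.
#' @return A `bout_records` data frame. The sum of `n_licks` always equals
#'   `nrow(events)`.
#' @examples
#' ev <- lick_events(c(0, 0.3, 5), c(0.05, 0.35, 5.05))
#' device_emulate(ev)
#' @export
device_emulate <- function(events, gap = 2.0) {
  validate_lick_events(events)
  if (gap <= 0) stop("device_emulate: gap must be > 0")
  n <- nrow(events)
  if (n == 0) return(bout_records())
  on <- events$onset_s
  off <- events$offset_s
  new_bout <- c(TRUE, diff(on) > gap)
  id <- cumsum(new_bout)
  first <- tapply(on, id, min)
  last_off <- tapply(off, id, max)
  span <- pmax(last_off - first, gap)
  bout_records(
    start_s = as.numeric(first),
    end_s = as.numeric(first + span),
    n_licks = as.integer(tapply(on, id, length)),
    lick_duration_s = as.numeric(tapply(off - on, id, sum)),
    min_span = gap
  )
}

.session_csv_cols <- c("animal_id", "session_index", "week",
                       "session_length_h", "fluid", "virus", "stim_mode",
                       "start_s", "end_s", "n_licks", "lick_duration_s",
                       "bottle_pre_g", "bottle_post_g", "body_weight_g")

#' Read and write session tables
#'
#' Sessions are serialized one bout per row with the session metadata
#' denormalized (columns `animal_id, session_index, week, session_length_h,
#' fluid, virus, stim_mode, start_s, end_s, n_licks, lick_duration_s,
#' bottle_pre_g, bottle_post_g, body_weight_g`). A session with no bouts is
#' kept as a single row whose bout fields are empty. `read_sessions` validates
#' every invariant and reports the offending line or field on failure;
#' `write_sessions` is its exact inverse, so the pair round-trips.
#'
#' @param path CSV file path.
#' @return `read_sessions`: a list of [did_session()] objects sorted by
#'   `(animal_id, session_index)`. `write_sessions`: `path`, invisibly.
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop("read_sessions: file not found: ", path)
  # base read.csv parses doubles with strtod, which round-trips the
  # shortest decimal representation written by write_sessions bit-exactly
  df <- tryCatch(
    utils::read.csv(path, colClasses = c(
      animal_id = "character", session_index = "integer", week = "integer",
      session_length_h = "numeric", fluid = "character",
      virus = "character", stim_mode = "character", start_s = "numeric",
      end_s = "numeric", n_licks = "integer", lick_duration_s = "numeric",
      bottle_pre_g = "numeric", bottle_post_g = "numeric",
      body_weight_g = "numeric")),
    error = function(e) stop("read_sessions: parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("read_sessions: parse error in ", path, ": ",
                               conditionMessage(w), call. = FALSE)
  )
  miss <- setdiff(.session_csv_cols, names(df))
  if (length(miss)) {
    stop("read_sessions: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0) return(list())
  key <- paste(df$animal_id, df$session_index, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), key)[unique(key)], function(i) {
    rows <- df[i, , drop = FALSE]
    meta <- rows[1, ]
    has_bout <- !is.na(rows$start_s)
    b <- rows[has_bout, c("start_s", "end_s", "n_licks", "lick_duration_s")]
    b <- b[order(b$start_s), , drop = FALSE]
    rownames(b) <- NULL
    did_session(
      animal_id = meta$animal_id, session_index = meta$session_index,
      week = meta$week, session_length_h = meta$session_length_h,
      fluid = meta$fluid, virus = meta$virus, stim_mode = meta$stim_mode,
      bottle_pre_g = meta$bottle_pre_g, bottle_post_g = meta$bottle_post_g,
      body_weight_g = meta$body_weight_g,
      bouts = bout_records(b$start_s, b$end_s, b$n_licks, b$lick_duration_s)
    )
  })
  names(out) <- NULL
  ord <- order(vapply(out, `[[`, "", "animal_id"),
               vapply(out, `[[`, 0L, "session_index"))
  out[ord]
}

#' @rdname read_sessions
#' @param sessions a list of `did_session` objects.
#' @export
write_sessions <- function(sessions, path) {
  if (length(sessions) == 0) {
    empty <- as.data.frame(stats::setNames(
      rep(list(logical()), length(.session_csv_cols)), .session_csv_cols))
    readr::write_csv(empty, path, progress = FALSE)
    return(invisible(path))
  }
  rows <- lapply(sessions, function(s) {
    validate_did_session(s)
    b <- s$bouts
    if (nrow(b) == 0) {
      b <- data.frame(start_s = NA_real_, end_s = NA_real_,
                      n_licks = NA_integer_, lick_duration_s = NA_real_)
    }
    data.frame(animal_id = s$animal_id, session_index = s$session_index,
               week = s$week, session_length_h = s$session_length_h,
               fluid = s$fluid, virus = s$virus, stim_mode = s$stim_mode,
               start_s = b$start_s, end_s = b$end_s, n_licks = b$n_licks,
               lick_duration_s = b$lick_duration_s,
               bottle_pre_g = s$bottle_pre_g, bottle_post_g = s$bottle_post_g,
               body_weight_g = s$body_weight_g)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read and write lick event tables
#'
#' Raw beam-break logs: columns `animal_id, session_index, onset_s, offset_s`,
#' one beam break per row.
#'
#' @param path CSV file path.
#' @return `read_events`: a data frame with one row per beam break, event
#'   invariants checked per animal-session. `write_events`: `path`, invisibly.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("read_events: file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, colClasses = c(
      animal_id = "character", session_index = "integer",
      onset_s = "numeric", offset_s = "numeric")),
    error = function(e) stop("read_events: parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  miss <- setdiff(c("animal_id", "session_index", "onset_s", "offset_s"),
                  names(df))
  if (length(miss)) {
    stop("read_events: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df)) {
    by <- split(df, paste(df$animal_id, df$session_index))
    lapply(by, function(g) validate_lick_events(
      g[order(g$onset_s), c("onset_s", "offset_s")]))
  }
  df
}

#' @rdname read_events
#' @param events a data frame of per-session events.
#' @export
write_events <- function(events, path) {
  readr::write_csv(
    events[, c("animal_id", "session_index", "onset_s", "offset_s")],
    path, progress = FALSE)
  invisible(path)
}

#' Collect all bouts of a session list into one table
#'
#' @param sessions list of `did_session` objects.
#' @return A data frame of bout rows with denormalized session metadata
#'   (the same layout [write_sessions()] serializes), zero-bout sessions
#'   omitted.
#' @export
session_bout_table <- function(sessions) {
  rows <- lapply(sessions, function(s) {
    if (nrow(s$bouts) == 0) return(NULL)
    cbind(data.frame(animal_id = s$animal_id,
                     session_index = s$session_index, week = s$week,
                     session_length_h = s$session_length_h, fluid = s$fluid,
                     virus = s$virus, stim_mode = s$stim_mode),
          as.data.frame(s$bouts),
          data.frame(bottle_pre_g = s$bottle_pre_g,
                     bottle_post_g = s$bottle_post_g,
                     body_weight_g = s$body_weight_g))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- as.data.frame(stats::setNames(
      rep(list(logical()), length(.session_csv_cols)), .session_csv_cols))
  }
  out
}
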