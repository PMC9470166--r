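#' Fit the licks-versus-duration cleaning model
#'
#' Genuine drinking bouts show a tight linear relation between the number of
#' licks in a bout and the total beam-broken time: each tongue contact blocks
#' the beam for a roughly constant interval. Slow leaks (beam blocked for long
#' stretches with few contacts) and bottle chews (many very short contacts)
#' fall far from that line. The cleaning model is an ordinary least-squares
#' regression of `n_licks` on `lick_duration_s`, fit either once over all
#' bouts (`grouping = "global"`, the default) or separately per animal.
#'
#' @param bouts a data frame of bout records; for `grouping = "per_animal"` it
#'   must also carry an `animal_id` column.
#' @param grouping `"global"` for one pooled fit, `"per_animal"` for one fit
#'   per animal.
#' @return An object of class `lick_duration_model`: a list with
#'   `coefficients` (data frame of `group`, `intercept`, `slope`, `n`),
#'   `residuals` (one per input bout, in lick units; `NA` for bouts in
#'   degenerate groups), and `grouping`.
#' @seealso [clean_bouts()]
#' @export
fit_lick_duration_model <- function(bouts,
                                    grouping = c("global", "per_animal")) {
  grouping <- match.arg(grouping)
  if (!all(c("n_licks", "lick_duration_s") %in% names(bouts))) {
    stop("fit_lick_duration_model: bouts need n_licks and lick_duration_s")
  }
  if (grouping == "per_animal" && !"animal_id" %in% names(bouts)) {
    stop("fit_lick_duration_model: per_animal grouping needs animal_id")
  }
  grp <- if (grouping == "global") rep("all", nrow(bouts)) else
    as.character(bouts$animal_id)
  res <- rep(NA_real_, nrow(bouts))
  coefs <- list()
  for (g in unique(grp)) {
    i <- which(grp == g)
    x <- bouts$lick_duration_s[i]
    y <- bouts$n_licks[i]
    degenerate <- length(i) < 2 || stats::sd(x) == 0
    if (degenerate) {
      msg <- sprintf(
        "cleaning model: degenerate group '%s' (%d bouts%s)", g, length(i),
        if (length(i) >= 2) ", all durations equal" else "")
      if (grouping == "global") stop(msg) else {
        warning(msg, "; group skipped", call. = FALSE)
        next
      }
    }
    fit <- stats::lm(y ~ x)
    res[i] <- stats::residuals(fit)
    coefs[[g]] <- data.frame(group = g,
                             intercept = unname(stats::coef(fit)[1]),
                             slope = unname(stats::coef(fit)[2]),
                             n = length(i))
  }
  if (!length(coefs)) stop("cleaning model: no non-degenerate group to fit")
  structure(list(
    coefficients = do.call(rbind, c(coefs, list(make.row.names = FALSE))),
    residuals = res,
    grouping = grouping
  ), class = "lick_duration_model")
}

#' @export
print.lick_duration_model <- function(x, ...) {
  cat(sprintf("<lick_duration_model> %s fit, %d group(s)\n", x$grouping,
              nrow(x$coefficients)))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Remove leak and chew artifacts from bout records
#'
#' Fits the licks-versus-duration model and drops every bout whose residual
#' magnitude exceeds `threshold` licks (default 3, i.e. residuals greater than
#' or less than 3 from the model fit are removed). Bouts in degenerate groups
#' that could not be fit are retained untouched. Input order is preserved.
#'
#' @inheritParams fit_lick_duration_model
#' @param threshold residual cutoff in lick-count units.
#' @return A list with `kept` (the surviving bout rows), `removed` (the
#'   excluded rows), and `report`, a `cleaning_report` holding the counts,
#'   retention fraction, model coefficients and threshold.
#' @examples
#' b <- data.frame(n_licks = c(10L, 20L, 4L), lick_duration_s = c(0.5, 1, 2))
#' clean_bouts(b, threshold = 3)$report
#' @export
clean_bouts <- function(bouts, threshold = 3.0,
                        grouping = c("global", "per_animal")) {
  grouping <- match.arg(grouping)
  if (threshold <= 0) stop("clean_bouts: threshold must be > 0")
  model <- fit_lick_duration_model(bouts, grouping)
  res <- model$residuals
  drop <- !is.na(res) & abs(res) > threshold
  report <- structure(list(
    n_before = nrow(bouts),
    n_after = sum(!drop),
    fraction_retained = if (nrow(bouts)) sum(!drop) / nrow(bouts) else NA_real_,
    model = model$coefficients,
    grouping = grouping,
    threshold = threshold
  ), class = "cleaning_report")
  list(kept = bouts[!drop, , drop = FALSE],
       removed = bouts[drop, , drop = FALSE],
       report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "<cleaning_report> %d of %d bouts retained (%.4f%%), |residual| > %g removed\n",
    x$n_after, x$n_before, 100 * x$fraction_retained, x$threshold))
  print(x$model, row.names = FALSE)
  invisible(x)
}
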