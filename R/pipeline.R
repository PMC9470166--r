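#' Pipeline configuration
#'
#' One nested configuration drives the whole pipeline (simulate, ingest,
#' clean, featurize, train). Defaults can be overridden from a YAML file
#' and/or by named overrides, which win over the file.
#'
#' @param file optional path to a YAML file of overrides.
#' @param ... named overrides merged over the file values (nested lists merge
#'   recursively).
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(file = NULL, ...) {
  defaults <- list(
    seed = 1,
    cohort = list(n_per_class = c("water:ChR2" = 8, "water:eGFP" = 11,
                                  "alcohol:ChR2" = 8, "alcohol:eGFP" = 8),
                  weeks = 6, sessions_per_week = 5),
    behavior = list(effect_scale = 1),
    clean = list(threshold = 3, grouping = "global"),
    featurize = list(front_window_s = 1800),
    train = list(k = 6, layer_widths = c(128, 64, 32, 4), epochs = 30,
                 batch_size = 32, learning_rate = 1e-3, fold_safe = FALSE)
  )
  cfg <- defaults
  if (!is.null(file)) {
    if (!file.exists(file)) stop("pipeline_config: file not found: ", file)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(file))
  }
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  structure(cfg, class = "pipeline_config")
}

# canonical JSON (recursively name-sorted) so the hash ignores field order
canonical_json <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v)) && length(v)) {
      v <- v[order(names(v))]
      lapply(v, sort_rec)
    } else if (is.list(v)) lapply(v, sort_rec) else v
  }
  jsonlite::toJSON(sort_rec(unclass(x)), auto_unbox = TRUE, digits = NA)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(canonical_json(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full simulate-to-classifier pipeline
#'
#' Executes the stages in order -- simulate (synthetic cohort), ingest
#' (serialize and re-read the session table through the CSV schema), clean
#' (residual-based bout removal), featurize (18-feature table), train
#' (stratified k-fold network) -- persisting every stage's output under
#' `out_dir` as it completes, so a failure in stage *n* leaves the outputs of
#' earlier stages intact. Errors name the failing stage.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return A list of class `run_manifest`: config hash, seed, package
#'   version, output paths, timestamps, plus the in-memory stage results
#'   (`cleaning_report`, `cv_result`, `feature_table`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  cohort <- stage("simulate", {
    cc <- cohort_config(n_per_class = unlist(config$cohort$n_per_class),
                        weeks = config$cohort$weeks,
                        sessions_per_week = config$cohort$sessions_per_week,
                        seed = config$seed)
    bp <- do.call(behavior_params, config$behavior)
    generate_cohort(cc, bp)
  })
  paths$sessions <- file.path(out_dir, "sessions.csv")
  write_sessions(cohort$sessions, paths$sessions)

  sessions <- stage("ingest", read_sessions(paths$sessions))

  cleaned <- stage("clean", {
    bouts <- session_bout_table(sessions)
    clean_bouts(bouts, threshold = config$clean$threshold,
                grouping = config$clean$grouping)
  })
  paths$clean_report <- file.path(out_dir, "cleaning_report.json")
  jsonlite::write_json(
    list(n_before = cleaned$report$n_before, n_after = cleaned$report$n_after,
         fraction_retained = cleaned$report$fraction_retained,
         threshold = cleaned$report$threshold,
         grouping = cleaned$report$grouping, model = cleaned$report$model),
    paths$clean_report, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  paths$clean_bouts <- file.path(out_dir, "bouts_clean.csv")
  readr::write_csv(cleaned$kept, paths$clean_bouts, progress = FALSE)

  sessions <- stage("clean", apply_cleaning(sessions, cleaned$kept))

  feature_table <- stage("featurize", {
    featurize_sessions(sessions,
                       front_window_s = config$featurize$front_window_s)
  })
  paths$features <- file.path(out_dir, "features.csv")
  readr::write_csv(feature_table, paths$features, progress = FALSE)

  cv <- stage("train", {
    ds <- assemble_dataset(feature_table)
    x <- if (config$train$fold_safe) ds$x else minmax_normalize(ds$x)
    splits <- stratified_kfold(ds$labels, k = config$train$k,
                               seed = config$seed)
    spec <- network_spec(layer_widths = config$train$layer_widths,
                         epochs = config$train$epochs,
                         batch_size = config$train$batch_size,
                         learning_rate = config$train$learning_rate,
                         seed = config$seed)
    train_evaluate(x, ds$y, splits, spec,
                   fold_safe = isTRUE(config$train$fold_safe))
  })
  paths$cv_result <- file.path(out_dir, "cvresult.json")
  jsonlite::write_json(
    list(per_fold_accuracy = cv$per_fold_accuracy,
         mean_accuracy = cv$mean_accuracy, max_accuracy = cv$max_accuracy,
         chance_accuracy = cv$chance_accuracy,
         chance_uniform = cv$chance_uniform,
         accuracy_over_chance = cv$accuracy_over_chance,
         fold_sizes = cv$fold_sizes),
    paths$cv_result, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  paths$loss_curves <- file.path(out_dir, "loss_curves.csv")
  curves <- do.call(rbind, lapply(seq_along(cv$curves), function(i) {
    cbind(fold = i, cv$curves[[i]])
  }))
  readr::write_csv(curves, paths$loss_curves, progress = FALSE)

  manifest <- structure(list(
    config_hash = config_hash(config), seed = config$seed,
    package_version = as.character(utils::packageVersion("sipstruct")),
    paths = lapply(paths, normalizePath),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    cleaning_report = cleaned$report, cv_result = cv,
    feature_table = feature_table
  ), class = "run_manifest")
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(config_hash = manifest$config_hash, seed = manifest$seed,
         package_version = manifest$package_version,
         paths = manifest$paths, timestamp = manifest$timestamp,
         config = unclass(config)),
    paths$manifest, auto_unbox = TRUE, digits = NA)
  manifest$paths <- paths
  manifest
}

# subset each session's bouts to the cleaned table
apply_cleaning <- function(sessions, kept_bouts) {
  key <- paste(kept_bouts$animal_id, kept_bouts$session_index)
  lapply(sessions, function(s) {
    k <- kept_bouts[key == paste(s$animal_id, s$session_index), , drop = FALSE]
    s$bouts <- if (nrow(k)) {
      bout_records(k$start_s, k$end_s, k$n_licks, k$lick_duration_s)
    } else bout_records()
    s
  })
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %s (seed %d, sipstruct %s)\n", x$config_hash,
              x$seed, x$package_version))
  cat("  outputs:", paste(basename(unlist(x$paths)), collapse = ", "), "\n")
  print(x$cv_result)
  invisible(x)
}
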