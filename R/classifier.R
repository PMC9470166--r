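#' Assemble the classifier dataset from a feature table
#'
#' Concatenates the 18 microstructure features across all animals and
#' sessions into one numeric matrix and one-hot encodes the four
#' fluid-by-virus class labels (`water:ChR2`, `water:eGFP`, `alcohol:ChR2`,
#' `alcohol:eGFP`, in that fixed order). Rows are kept in table order;
#' duplicate rows are kept as-is.
#'
#' @param feature_table output of [featurize_sessions()] (or any data frame
#'   with the 18 feature columns plus `fluid` and `virus`).
#' @return A list with `x` (sessions-by-18 matrix), `y` (one-hot matrix with
#'   4 columns), `labels` (integer class per row) and `class_levels`.
#' @export
assemble_dataset <- function(feature_table) {
  feats <- feature_registry()
  miss <- setdiff(c(feats, "fluid", "virus"), names(feature_table))
  if (length(miss)) {
    stop("assemble_dataset: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(is.na(feature_table$fluid)) || any(is.na(feature_table$virus))) {
    stop("assemble_dataset: missing fluid/virus label")
  }
  levels <- c("water:ChR2", "water:eGFP", "alcohol:ChR2", "alcohol:eGFP")
  lab <- paste(feature_table$fluid, feature_table$virus, sep = ":")
  bad <- !lab %in% levels
  if (any(bad)) {
    stop("assemble_dataset: unknown label(s): ",
         paste(unique(lab[bad]), collapse = ", "))
  }
  x <- as.matrix(feature_table[, feats])
  storage.mode(x) <- "double"
  labels <- match(lab, levels)
  y <- matrix(0, nrow(x), length(levels),
              dimnames = list(NULL, levels))
  y[cbind(seq_len(nrow(x)), labels)] <- 1
  list(x = x, y = y, labels = labels, class_levels = levels)
}

#' Min-max normalize a feature matrix to the unit interval
#'
#' Affinely rescales each column so its minimum maps to 0 and maximum to 1.
#' Constant columns map to all zeros. Applied to the full dataset before
#' cross-validation by default (see [train_evaluate()] for the fold-safe
#' alternative).
#'
#' @param x numeric matrix with finite entries.
#' @param ranges optional list with `min` and `max` per column, as returned in
#'   the attribute `ranges`; supply to apply a previously fit scaling.
#' @return The rescaled matrix, with attribute `ranges`.
#' @export
minmax_normalize <- function(x, ranges = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("minmax_normalize: non-finite entry in matrix")
  if (is.null(ranges)) {
    ranges <- list(min = apply(x, 2, min), max = apply(x, 2, max))
  }
  span <- ranges$max - ranges$min
  out <- sweep(x, 2, ranges$min, `-`)
  out <- sweep(out, 2, ifelse(span > 0, span, 1), `/`)
  out[, span == 0] <- 0
  attr(out, "ranges") <- ranges
  out
}

#' Stratified k-fold cross-validation splits
#'
#' Shuffles each class independently (seeded) and deals its members across
#' the k folds as evenly as possible, so every test fold's class proportions
#' are within one sample of the global proportions even when the
#' fluid-by-virus classes are unbalanced.
#'
#' Classes whose size is not a multiple of k leave remainder members; those
#' go to the currently least-filled folds (lowest index on ties), so fold
#' sizes stay within one row of each other even for classes smaller than k
#' (which are spread over a subset of folds, with a warning).
#'
#' @param labels integer or factor class label per row.
#' @param k number of folds (default 6).
#' @param seed integer RNG seed for the shuffle.
#' @return A list of `k` splits, each a list with `fold`, `train`, `test`
#'   (row indices); train and test partition the rows.
#' @export
stratified_kfold <- function(labels, k = 6, seed = 1) {
  labels <- as.integer(as.factor(labels))
  if (k < 2) stop("stratified_kfold: k must be >= 2")
  n <- length(labels)
  if (k > n) stop("stratified_kfold: k must not exceed the number of rows")
  counts <- table(labels)
  if (any(counts < k)) {
    warning("stratified_kfold: smallest class has ", min(counts),
            " members, fewer than k = ", k, "; it cannot appear in every fold",
            call. = FALSE)
  }
  fold_of <- integer(n)
  fill <- integer(k)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    m <- length(idx)
    base <- m %/% k
    extra <- m %% k
    sizes <- rep(base, k)
    if (extra > 0) {
      receive <- order(fill, seq_len(k))[seq_len(extra)]
      sizes[receive] <- sizes[receive] + 1
    }
    fold_of[idx] <- rep(seq_len(k), times = sizes)
    fill <- fill + sizes
  }
  lapply(seq_len(k), function(f) {
    list(fold = f, train = which(fold_of != f), test = which(fold_of == f))
  })
}

#' Feedforward network specification
#'
#' The default architecture is a sequential dense network of 2048, 512 and 64
#' rectified-linear nodes feeding a 4-node softmax output, trained with Adam
#' on categorical cross-entropy. Epochs, batch size and step size are
#' configurable; smaller `layer_widths` give a proportionally cheaper model
#' for simulation-scale work.
#'
#' @param layer_widths widths of the dense layers; the last entry is the
#'   output layer and must match the number of classes.
#' @param epochs training epochs per fold.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed base RNG seed; each fold trains a freshly initialized network
#'   seeded from this value.
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(layer_widths = c(2048, 512, 64, 4), epochs = 100,
                         batch_size = 32, learning_rate = 1e-3, seed = 1) {
  if (any(layer_widths <= 0)) stop("network_spec: layer widths must be > 0")
  structure(list(layer_widths = as.integer(layer_widths),
                 hidden_activation = "relu", output_activation = "softmax",
                 optimizer = "adam", loss = "categorical_crossentropy",
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "<network_spec> dense %s, relu/softmax, adam(lr=%g), %d epochs, batch %d, seed %d\n",
    paste(x$layer_widths, collapse = "-"), x$learning_rate, x$epochs,
    x$batch_size, x$seed))
  invisible(x)
}

#' Train and evaluate the network under cross-validation
#'
#' Trains one freshly initialized network per fold and scores accuracy on the
#' held-out rows only, recording per-epoch train/test cross-entropy curves.
#' The chance baseline is the frequency of the modal class (the accuracy of
#' always guessing the most common label); the uniform 1/k alternative is
#' reported alongside.
#'
#' @param x normalized feature matrix (see [minmax_normalize()]).
#' @param y one-hot label matrix.
#' @param splits output of [stratified_kfold()].
#' @param spec a [network_spec()].
#' @param fold_safe if `TRUE`, refit the min-max scaler on each training fold
#'   and apply it to the fold's test rows, instead of the default full-dataset
#'   normalization (which leaks the held-out rows' ranges into training).
#' @return A list of class `cv_result`: `per_fold_accuracy`, `mean_accuracy`,
#'   `max_accuracy`, `chance_accuracy` (modal-class frequency),
#'   `chance_uniform`, `accuracy_over_chance`, `fold_sizes`, and `curves`
#'   (per-fold data frames of epoch, train and test loss).
#' @export
train_evaluate <- function(x, y, splits, spec = network_spec(),
                           fold_safe = FALSE) {
  stopifnot(is.matrix(x), is.matrix(y), nrow(x) == nrow(y))
  if (any(!is.finite(x))) stop("train_evaluate: non-finite entry in matrix")
  if (utils::tail(spec$layer_widths, 1) != ncol(y)) {
    stop("train_evaluate: output layer width must equal the number of classes")
  }
  truth <- max.col(y, ties.method = "first")
  acc <- numeric(length(splits))
  curves <- vector("list", length(splits))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    stopifnot(length(intersect(sp$train, sp$test)) == 0)
    xtr <- x[sp$train, , drop = FALSE]
    xte <- x[sp$test, , drop = FALSE]
    if (fold_safe) {
      xtr <- minmax_normalize(xtr)
      xte <- minmax_normalize(xte, ranges = attr(xtr, "ranges"))
      # applying train ranges can push test values outside [0, 1]; clip
      xte <- pmin(pmax(xte, 0), 1)
    }
    set.seed(spec$seed + i)
    fit <- mlp_train(xtr, y[sp$train, , drop = FALSE], xte,
                     y[sp$test, , drop = FALSE], spec)
    pred <- mlp_predict_class(fit$layers, xte)
    acc[i] <- mean(pred == truth[sp$test])
    curves[[i]] <- fit$curves
  }
  chance <- max(table(truth)) / length(truth)
  structure(list(
    per_fold_accuracy = acc,
    mean_accuracy = mean(acc),
    max_accuracy = max(acc),
    chance_accuracy = chance,
    chance_uniform = 1 / ncol(y),
    accuracy_over_chance = mean(acc) / chance,
    fold_sizes = data.frame(
      fold = vapply(splits, `[[`, 0L, "fold"),
      n_train = vapply(splits, function(s) length(s$train), 0L),
      n_test = vapply(splits, function(s) length(s$test), 0L)),
    curves = curves,
    spec = spec
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d folds: mean accuracy %.2f%% (max %.2f%%), chance %.2f%% -> %.2fx over chance\n",
    length(x$per_fold_accuracy), 100 * x$mean_accuracy, 100 * x$max_accuracy,
    100 * x$chance_accuracy, x$accuracy_over_chance))
  print(x$fold_sizes, row.names = FALSE)
  invisible(x)
}
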