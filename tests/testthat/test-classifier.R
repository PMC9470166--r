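fake_table <- function(fluid, virus, n = length(fluid)) {
  ft <- as.data.frame(matrix(runif(n * 18), n, 18,
                             dimnames = list(NULL, feature_registry())))
  ft$fluid <- fluid
  ft$virus <- virus
  ft
}

test_that("dataset assembly one-hot encodes the four fluid-by-virus classes", {
  set.seed(1)
  ft <- fake_table(c("water", "water", "alcohol", "alcohol"),
                   c("ChR2", "eGFP", "ChR2", "eGFP"))
  ds <- assemble_dataset(ft)
  expect_equal(dim(ds$x), c(4, 18))
  expect_equal(ds$y, diag(4), ignore_attr = TRUE)
  expect_equal(rowSums(ds$y), rep(1, 4))

  # duplicated rows are preserved, not deduplicated
  ds2 <- assemble_dataset(rbind(ft, ft[1, ]))
  expect_equal(nrow(ds2$x), 5)
  expect_equal(ds2$x[5, ], ds2$x[1, ])

  bad <- ft
  bad$virus[2] <- NA
  expect_error(assemble_dataset(bad), "label")
  bad$virus[2] <- "mCherry"
  expect_error(assemble_dataset(bad), "unknown label")
})

test_that("min-max normalization maps columns onto [0, 1]", {
  expect_equal(minmax_normalize(matrix(c(0, 5, 10))), matrix(c(0, 0.5, 1)),
               ignore_attr = TRUE)
  expect_equal(unname(minmax_normalize(cbind(a = c(3, 3, 3)))[, 1]),
               c(0, 0, 0))
  set.seed(2)
  m <- minmax_normalize(matrix(rnorm(200), 20))
  expect_equal(unname(apply(m, 2, min)), rep(0, 10))
  expect_equal(unname(apply(m, 2, max)), rep(1, 10))
  expect_error(minmax_normalize(matrix(c(1, NA))), "non-finite")
})

test_that("stratified folds reproduce the 998-row fold arithmetic", {
  lab <- rep(1:4, c(240, 278, 240, 240))  # 998 unbalanced rows
  splits <- stratified_kfold(lab, k = 6, seed = 7)
  test_sizes <- sort(vapply(splits, function(s) length(s$test), 0L))
  expect_equal(test_sizes, c(166, 166, 166, 166, 167, 167))
  modal <- as.integer(names(which.max(table(test_sizes))))
  expect_equal(998 - modal, 832)
})

test_that("stratified folds partition rows and preserve class proportions", {
  set.seed(3)
  lab <- sample(1:4, 200, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  k <- 6
  splits <- stratified_kfold(lab, k, seed = 9)
  all_test <- sort(unlist(lapply(splits, `[[`, "test")))
  expect_equal(all_test, seq_along(lab))
  for (s in splits) {
    expect_length(intersect(s$train, s$test), 0)
    expect_equal(sort(c(s$train, s$test)), seq_along(lab))
    for (cl in 1:4) {
      expected <- sum(lab == cl) / k
      expect_lte(abs(sum(lab[s$test] == cl) - expected), 1)
    }
  }
  # 12 balanced rows over 6 folds: every test fold holds 2 rows of distinct
  # classes (classes smaller than k warn and spread over a fold subset)
  lab12 <- rep(1:4, each = 3)
  expect_warning(splits12 <- stratified_kfold(lab12, 6, seed = 1),
                 "fewer than k")
  for (s in splits12) {
    expect_length(s$test, 2)
    expect_length(unique(lab12[s$test]), 2)
  }
  expect_error(stratified_kfold(lab12, k = 1), "k must be >= 2")
  expect_error(stratified_kfold(lab12, k = 13), "number of rows")
  expect_identical(stratified_kfold(lab, 6, seed = 4),
                   stratified_kfold(lab, 6, seed = 4))
})

test_that("the network learns separable blobs and reports honest fold accuracy", {
  set.seed(4)
  n <- 400
  cl <- sample(1:4, n, TRUE)
  centroids <- matrix(rnorm(4 * 18, sd = 3), 4)
  x <- centroids[cl, ] + matrix(rnorm(n * 18, sd = 0.5), n)
  y <- matrix(0, n, 4); y[cbind(seq_len(n), cl)] <- 1
  xn <- minmax_normalize(x)
  splits <- stratified_kfold(cl, 6, seed = 4)
  spec <- network_spec(c(64, 32, 16, 4), epochs = 40, seed = 4)
  cv <- train_evaluate(xn, y, splits, spec)
  expect_gte(cv$mean_accuracy, 0.95)
  expect_equal(cv$mean_accuracy, mean(cv$per_fold_accuracy))
  expect_equal(cv$max_accuracy, max(cv$per_fold_accuracy))
  expect_equal(cv$accuracy_over_chance,
               cv$mean_accuracy / cv$chance_accuracy)
  # loss curves are finite and training converges on separable data
  for (cur in cv$curves) {
    expect_true(all(is.finite(cur$train_loss)))
    expect_true(all(is.finite(cur$test_loss)))
    expect_lte(cur$train_loss[nrow(cur)], cur$train_loss[1])
  }
  # an independent single-hidden-layer classifier agrees the blobs separate
  skip_if_not_installed("nnet")
  ref <- nnet::nnet(xn, y, size = 8, softmax = TRUE, trace = FALSE,
                    maxit = 200)
  expect_gte(mean(max.col(predict(ref, xn)) == cl), 0.95)
})

test_that("training is deterministic given seed, spec and data", {
  set.seed(6)
  n <- 120
  cl <- rep(1:4, each = 30)
  x <- minmax_normalize(matrix(rnorm(n * 18), n) + cl)
  y <- matrix(0, n, 4); y[cbind(seq_len(n), cl)] <- 1
  splits <- stratified_kfold(cl, 3, seed = 2)
  spec <- network_spec(c(16, 8, 4), epochs = 5, seed = 11)
  a <- train_evaluate(x, y, splits, spec)
  b <- train_evaluate(x, y, splits, spec)
  expect_identical(a$per_fold_accuracy, b$per_fold_accuracy)
  expect_identical(a$curves, b$curves)
})

test_that("a single-class dataset is classified perfectly", {
  set.seed(8)
  n <- 40
  x <- minmax_normalize(matrix(rnorm(n * 18), n))
  y <- cbind(rep(1, n), 0, 0, 0)
  # stratification is impossible with one class; hand-built split
  splits <- list(list(fold = 1L, train = 1:30, test = 31:40))
  cv <- train_evaluate(x, y, splits, network_spec(c(8, 4), epochs = 200))
  expect_equal(cv$mean_accuracy, 1.0)
})

test_that("fold-safe scaling fits the normalizer on training rows only", {
  set.seed(10)
  n <- 80
  cl <- rep(1:4, each = 20)
  x <- matrix(rnorm(n * 18, mean = 3 * cl), n)
  y <- matrix(0, n, 4); y[cbind(seq_len(n), cl)] <- 1
  splits <- stratified_kfold(cl, 4, seed = 3)
  cv <- train_evaluate(x, y, splits, network_spec(c(16, 4), epochs = 150),
                       fold_safe = TRUE)
  expect_true(all(is.finite(cv$per_fold_accuracy)))
  expect_gte(cv$mean_accuracy, 0.5)
})
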