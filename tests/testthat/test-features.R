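empty_session <- function(len_h = 2) {
  did_session("m0", 1, len_h, "water", "eGFP", bottle_pre_g = 50,
              bottle_post_g = 50, body_weight_g = 25)
}

test_that("an empty session is imputed, not dropped", {
  f <- extract_features(empty_session())
  expect_length(f, 18)
  expect_equal(unname(f["latency_to_drink_s"]), 7200)
  expect_equal(unname(f["mean_inter_drink_interval_s"]), 7200)
  expect_equal(unname(f["max_inter_drink_interval_s"]), 7200)
  expect_equal(unname(f["total_licks"]), 0)
  expect_equal(unname(f["front_loading_index"]), 0)
  expect_equal(unname(f["lick_rate_per_min"]), 0)
  expect_true(all(is.finite(f)))
})

test_that("features match the hand-computed three-bout example", {
  b <- bout_records(c(60, 400, 2000), c(62, 402, 2002), rep(5L, 3),
                    rep(0.25, 3))
  s <- did_session("m1", 1, 2, "alcohol", "ChR2", bottle_pre_g = 50,
                   bottle_post_g = 49, body_weight_g = 25, bouts = b)
  f <- extract_features(s)
  expect_equal(unname(f["total_bouts"]), 3)
  expect_equal(unname(f["total_licks"]), 15)
  expect_equal(unname(f["latency_to_drink_s"]), 60)
  # inter-drink intervals run bout end to next bout start
  expect_equal(unname(f["mean_inter_drink_interval_s"]),
               ((400 - 62) + (2000 - 402)) / 2)  # = 968
  expect_equal(unname(f["max_inter_drink_interval_s"]), 2000 - 402)
  # the 30 min window closes at 1800 s: the 2000 s bout falls outside it
  expect_equal(unname(f["bouts_first_30min"]), 2)
  expect_equal(unname(f["front_loading_index"]), 2 / 3)
  expect_equal(unname(f["mean_bout_length_s"]), 2)
})

test_that("the extractor agrees with a single-pass reference on random sessions", {
  set.seed(13)
  for (i in 1:200) {
    s <- random_session()
    got <- extract_features(s)
    want <- oracle_features(as.data.frame(s$bouts), s$session_length_h)
    expect_equal(got, want[feature_registry()], tolerance = 1e-9)
  }
})

test_that("feature invariants hold: arity, order, maxima, front-loading window", {
  set.seed(17)
  for (i in 1:50) {
    s <- random_session()
    f <- extract_features(s)
    expect_identical(names(f), feature_registry())
    if (nrow(s$bouts) >= 1) {
      expect_gte(f[["max_bout_length_s"]], f[["mean_bout_length_s"]])
      expect_gte(f[["max_licks_per_bout"]], f[["mean_licks_per_bout"]])
      expect_gte(f[["max_lick_duration_per_bout_s"]],
                 f[["mean_lick_duration_per_bout_s"]])
    }
    expect_lte(f[["bouts_first_30min"]], f[["total_bouts"]])
    expect_lte(f[["latency_to_drink_s"]], s$session_length_h * 3600)
    if (nrow(s$bouts) && all(s$bouts$start_s < 1800)) {
      expect_equal(f[["licks_first_30min"]], f[["total_licks"]])
      expect_equal(f[["bouts_first_30min"]], f[["total_bouts"]])
    }
    # appending one late bout increments the count, never decrements licks
    if (nrow(s$bouts) && max(s$bouts$end_s) + 10 < s$session_length_h * 3600) {
      s2 <- s
      e <- max(s$bouts$end_s)
      s2$bouts <- bout_records(c(s$bouts$start_s, e + 5),
                               c(s$bouts$end_s, e + 8),
                               c(s$bouts$n_licks, 3L),
                               c(s$bouts$lick_duration_s, 0.2))
      f2 <- extract_features(s2)
      expect_equal(f2[["total_bouts"]], f[["total_bouts"]] + 1)
      expect_gte(f2[["total_licks"]], f[["total_licks"]])
    }
  }
})

test_that("intake doses follow the density arithmetic", {
  z <- did_session("m1", 1, 2, "water", "eGFP", bottle_pre_g = 50,
                   bottle_post_g = 50, body_weight_g = 25)
  expect_equal(compute_intake(z)$dose, 0)

  w <- did_session("m1", 1, 2, "water", "eGFP", bottle_pre_g = 50,
                   bottle_post_g = 49, body_weight_g = 25)
  expect_equal(compute_intake(w)$dose, 40)  # 1 g / 0.025 kg

  # 0.970 g of 20% v/v solution = 1 ml -> 0.2 ml ethanol * 0.789 g/ml
  a <- did_session("m1", 1, 2, "alcohol", "ChR2", bottle_pre_g = 50,
                   bottle_post_g = 49.030, body_weight_g = 25)
  expect_equal(compute_intake(a)$dose, (1.0 * 0.2 * 0.789) / 0.025,
               tolerance = 1e-9)
  expect_equal(compute_intake(a)$dose, 6.312, tolerance = 1e-9)

  bad <- a
  bad$body_weight_g <- 0
  expect_error(compute_intake(bad), "body_weight_g")
})

test_that("the inclusion filter excludes only drinkers below the lower fence", {
  same <- data.frame(animal_id = letters[1:5], fluid = "water",
                     total_intake = rep(55, 5))
  res <- inclusion_filter(same)
  expect_equal(nrow(res$included), 5)
  expect_equal(nrow(res$excluded), 0)

  # one near-zero drinker among normal intakes falls below Q1 - 1.5 IQR
  g <- data.frame(animal_id = letters[1:6], fluid = "alcohol",
                  total_intake = c(50, 52, 55, 58, 60, 1.28))
  q <- quantile(g$total_intake, c(0.25, 0.75), type = 7)
  fence <- unname(q[1] - 1.5 * (q[2] - q[1]))
  expect_equal(fence, 40.375)  # frozen from the quantile definition
  res <- inclusion_filter(g)
  expect_equal(res$excluded$animal_id, "f")
  expect_equal(res$excluded$total_intake, 1.28)
  expect_equal(sort(res$included$animal_id), letters[1:5])

  empty <- g[0, ]
  res0 <- inclusion_filter(empty)
  expect_equal(nrow(res0$included), 0)
  expect_equal(nrow(res0$excluded), 0)

  expect_warning(inclusion_filter(g[1:3, ]), "fewer than")
})

test_that("intake correlations behave on exact, constant and shuffled data", {
  set.seed(23)
  ft <- data.frame(fluid = "water",
                   total_licks = runif(30, 100, 1000))
  ft$total_bouts <- ft$total_licks / 20
  ft$total_lick_duration_s <- ft$total_licks * 0.05
  doses <- ft$total_licks * 0.01  # exact linear coupling
  r <- intake_microstructure_correlation(ft, doses)
  expect_equal(r$r, rep(1, 3), tolerance = 1e-12)

  const <- ft
  const$total_bouts <- 5
  r2 <- intake_microstructure_correlation(const, doses)
  expect_true(is.na(r2$r[r2$feature == "total_bouts"]))
  expect_equal(r2$note[r2$feature == "total_bouts"], "zero variance")

  # shuffling breaks the coupling: r falls inside the permutation null band
  null_r <- replicate(200, cor(ft$total_licks, sample(doses)))
  shuffled <- intake_microstructure_correlation(
    ft, sample(doses), features = "total_licks")
  expect_lt(abs(shuffled$r), quantile(abs(null_r), 0.995))
  expect_error(intake_microstructure_correlation(ft[1:2, ], doses[1:2]),
               ">= 3")
})
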