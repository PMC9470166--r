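flat_trace <- function(n = 5000, fs = 10000, stim = 0.1) {
  sweep_trace(rep(0, n), fs = fs, stim_onsets_s = stim)
}

test_that("evoked amplitudes are exact on flat and noiseless traces", {
  expect_equal(oepsc_amplitude(flat_trace()), 0)
  sw <- generate_sweeps("oepsc", list(noise_sd = 0, n_per_power = 1))
  amp <- vapply(sw$traces, oepsc_amplitude, 0)
  expect_equal(amp, sw$ground_truth$amplitude, tolerance = 1e-12)
  expect_error(oepsc_amplitude(flat_trace(), search_window = c(0.002, 10)),
               "outside")
  expect_error(oepsc_amplitude(flat_trace(), baseline_window = c(-0.2, 0)),
               "outside")
})

test_that("the noisy input-output curve recovers the saturating ground truth", {
  sw <- generate_sweeps("oepsc", list(noise_sd = 2, n_per_power = 10),
                        seed = 3)
  amp <- vapply(sw$traces, oepsc_amplitude, 0)
  truth <- sw$ground_truth$amplitude
  by_power <- tapply(amp, sw$ground_truth$light_power_mW, mean)
  truth_by_power <- tapply(truth, sw$ground_truth$light_power_mW, unique)
  # a peak-over-noise estimate is biased upward by about the expected
  # maximum of the window noise, sigma * sqrt(2 log n_window) ~ 7.4 pA
  bound <- 2 * sqrt(2 * log(481)) + 3 * 2 / sqrt(10)
  expect_true(all(abs(by_power - truth_by_power) < bound))
  # and the recovered curve preserves the saturating shape
  expect_true(all(diff(by_power) > 0))
})

test_that("AMPA/NMDA ratio recovers the configured 2.0 and flags pure-AMPA cells", {
  an <- generate_sweeps("ampa_nmda", list(noise_sd = 0))
  r0 <- ampa_nmda_ratio(an$traces$minus80, an$traces$plus40)
  expect_false(r0$undefined)
  expect_equal(r0$nmda, 150, tolerance = 1e-9)
  expect_equal(r0$ratio, 2.0, tolerance = 1e-3)

  rn <- ampa_nmda_ratio(
    generate_sweeps("ampa_nmda", list(noise_sd = 2), seed = 5)$traces$minus80,
    generate_sweeps("ampa_nmda", list(noise_sd = 2), seed = 5)$traces$plus40)
  expect_equal(rn$ratio, 2.0, tolerance = 0.02)

  # a cell whose +40 mV current is gone before 100 ms has no NMDA component
  pure <- generate_sweeps("ampa_nmda", list(noise_sd = 0,
                                            nmda_window_mean_pA = 0))
  rp <- ampa_nmda_ratio(pure$traces$minus80, pure$traces$plus40)
  expect_true(rp$undefined)
  expect_true(is.na(rp$ratio))

  # scaling both traces leaves the ratio unchanged
  scale_trace <- function(tr, c) {
    tr$samples <- tr$samples * c
    tr
  }
  rs <- ampa_nmda_ratio(scale_trace(an$traces$minus80, 3),
                        scale_trace(an$traces$plus40, 3))
  expect_equal(rs$ratio, r0$ratio, tolerance = 1e-12)
})

test_that("measurements ignore trace content outside their windows", {
  an <- generate_sweeps("ampa_nmda", list(noise_sd = 0))
  r0 <- ampa_nmda_ratio(an$traces$minus80, an$traces$plus40)
  tampered <- an$traces$plus40
  # corrupt samples after the NMDA window and long before the baseline
  n <- length(tampered$samples)
  tampered$samples[(n - 100):n] <- 500
  tampered$samples[1:100] <- -500
  r1 <- ampa_nmda_ratio(an$traces$minus80, tampered)
  expect_equal(r1$ratio, r0$ratio, tolerance = 1e-12)
})

test_that("paired-pulse ratios use tail-current baselines correctly", {
  pp_same <- generate_sweeps("ppr", list(noise_sd = 0, ppr = 1))
  expect_equal(paired_pulse_ratio(pp_same$traces)$ppr, 1.0, tolerance = 1e-3)

  pp <- generate_sweeps("ppr", list(noise_sd = 0))
  expect_equal(paired_pulse_ratio(pp$traces)$ppr, 0.75, tolerance = 1e-3)

  ppn <- generate_sweeps("ppr", list(noise_sd = 2), seed = 9)
  expect_equal(paired_pulse_ratio(ppn$traces)$ppr, 0.75, tolerance = 0.02)

  # superposition oracle: with P1 still decaying under P2 (slow decay),
  # subtracting a P1-only trace recovers the configured P2
  ov <- generate_sweeps("ppr", list(noise_sd = 0, isi_s = 0.1,
                                    tau_decay = 0.025))
  got <- paired_pulse_ratio(ov$traces)
  p1_only <- generate_sweeps("ppr", list(noise_sd = 0, isi_s = 0.1,
                                         tau_decay = 0.025, ppr = 0))
  resid <- ov$traces[[1]]$samples - p1_only$traces[[1]]$samples
  oracle_p2 <- max(abs(resid))
  expect_equal(mean(got$p2), oracle_p2, tolerance = 0.02 * oracle_p2)
  expect_equal(got$ppr, 0.75, tolerance = 0.02)

  # PPR is invariant to uniform scaling
  scaled <- lapply(pp$traces, function(tr) {
    tr$samples <- tr$samples * 5
    tr
  })
  expect_equal(paired_pulse_ratio(scaled)$ppr,
               paired_pulse_ratio(pp$traces)$ppr, tolerance = 1e-12)

  expect_error(paired_pulse_ratio(list()), "1-3")
  one_stim <- flat_trace()
  expect_error(paired_pulse_ratio(one_stim), "2 stimuli")
})

test_that("population spikes mirror the evoked-amplitude contract", {
  expect_equal(population_spike_amplitude(flat_trace()), 0)
  op <- generate_sweeps("ops", list(noise_sd = 0, n_per_power = 1))
  amp <- vapply(op$traces, population_spike_amplitude, 0)
  expect_equal(amp, op$ground_truth$amplitude, tolerance = 1e-12)
  # for a purely negative-going noiseless spike the two conventions agree
  expect_equal(population_spike_amplitude(op$traces[[7]],
                                          convention = "peak_to_peak"),
               amp[7], tolerance = 1e-2)
})

test_that("the sEPSC detector recovers planted events, rates and kinetics", {
  # noiseless planting: exact count and amplitudes
  se <- generate_sweeps("sepsc", list(noise_sd = 0, rate_hz = 0.5,
                                      duration_s = 20, amp_sdlog = 0),
                        seed = 4)
  d <- detect_sepscs(se$traces[[1]], threshold = 10)
  expect_equal(d$n, length(se$ground_truth$times_s))
  expect_equal(d$events$amplitude, rep(30, d$n), tolerance = 1e-9)
  expect_equal(d$frequency_hz, d$n / 20)

  # decay tau recovered within 0.5 ms of the configured 5 ms, clean and
  # at moderate noise; the single-exponential from-peak fit acquires an
  # upward bias as noise grows (documented), so the high-noise default is
  # only checked loosely
  expect_true(all(abs(d$events$decay_tau_s - 0.005) < 5e-4))
  mod <- detect_sepscs(generate_sweeps("sepsc", list(noise_sd = 1),
                                       seed = 6)$traces[[1]], threshold = 12)
  expect_lt(abs(median(mod$events$decay_tau_s, na.rm = TRUE) - 0.005), 5e-4)
  noisy <- generate_sweeps("sepsc", list(noise_sd = 1.5), seed = 6)
  dn <- detect_sepscs(noisy$traces[[1]], threshold = 12)
  expect_lt(abs(median(dn$events$decay_tau_s, na.rm = TRUE) - 0.005), 1e-3)

  # detected frequency within the Poisson 95% band of the configured rate
  lam <- 2 * 120
  expect_gt(dn$n, qpois(0.025, lam) * 0.9)
  expect_lt(dn$n, qpois(0.975, lam) * 1.1)

  empty <- detect_sepscs(sweep_trace(rep(0, 10000)), threshold = 10)
  expect_equal(empty$n, 0L)
  expect_equal(empty$frequency_hz, 0)
  expect_error(detect_sepscs(se$traces[[1]], threshold = 0), "> 0")
})

test_that("series-resistance QC applies the absolute and drift rules", {
  res <- qc_filter(c(10, 26, 20, 24, 25), c(10, 26, 23.5, 26, 25))
  expect_equal(res$keep, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_match(res$reason[2], "25")
  expect_match(res$reason[3], "drift")   # 17.5% change
  expect_error(qc_filter(-1, 10), "positive")
})

test_that("amplitude operations are linear in the trace", {
  sw <- generate_sweeps("oepsc", list(noise_sd = 0, n_per_power = 1))
  tr <- sw$traces[[4]]
  tr5 <- tr
  tr5$samples <- tr$samples * 5
  expect_equal(oepsc_amplitude(tr5), 5 * oepsc_amplitude(tr),
               tolerance = 1e-12)
})
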