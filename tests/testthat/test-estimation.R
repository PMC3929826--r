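make_log <- function(arrivals, station = "registration", dur = 0) {
  n <- length(arrivals)
  data.frame(patient_id = seq_len(n), class = "new", station = station,
             queue_join = arrivals, service_start = arrivals,
             service_end = arrivals + dur, stringsAsFactors = FALSE)
}

test_that("fit_interarrival computes successive-difference moments", {
  f <- fit_interarrival(make_log(c(0, 4, 8, 12)))
  expect_equal(f$mean, 4)
  expect_equal(f$sd, 0)
  expect_equal(f$n, 3L)
  expect_error(fit_interarrival(make_log(5)), "2 arrivals")
})

test_that("fit_interarrival recovers the generator's pre-truncation mean", {
  # clipped-normal gaps (the default family): censored MLE
  spec <- dist_spec("clipped_normal", 4.2, 5.8)
  set.seed(11)
  gaps <- dist_sample(spec, 4e4)
  f <- fit_interarrival(make_log(cumsum(gaps)))
  expect_equal(f$family, "clipped_normal")
  # raw mean of the gaps (the first gap is unrecoverable from arrival times)
  expect_equal(f$mean, mean(gaps), tolerance = 1e-3)
  expect_lt(abs(f$mean - dist_mean(spec)), 3 * f$se_mean)
  expect_lt(abs(f$underlying_mean - 4.2), 0.1)
  expect_lt(abs(f$underlying_sd - 5.8), 0.15)

  # conditionally truncated gaps: truncated MLE
  spec_t <- dist_spec("truncated_normal", 4.2, 5.8)
  set.seed(12)
  gaps_t <- dist_sample(spec_t, 4e4)
  ft <- fit_interarrival(make_log(cumsum(gaps_t)))
  expect_equal(ft$family, "truncated_normal")
  expect_lt(abs(ft$underlying_mean - 4.2), 0.15)
})

test_that("fit_service_times computes per-station service moments", {
  log <- make_log(c(0, 10), station = "cash", dur = c(3, 5))
  f <- fit_service_times(log, "cash")
  expect_equal(f$mean, 4)
  expect_equal(f$sd, sqrt(2))
  expect_equal(f$se_mean, 1)
  expect_error(fit_service_times(log, "senior_staff"), "senior_staff")
})

test_that("fit_* estimators are unbiased over replicated day logs", {
  # 120 synthetic clinic days at defaults (scaled down from the spec's 200
  # for test-suite runtime; the acceptance suite runs the full version)
  cfg <- default_base_case()
  est_inter <- est_nov <- numeric(120)
  for (i in seq_len(120)) {
    log <- generate_patient_log(generator_params(cfg, n_patients = 375L,
                                                 seed = 5000 + i))
    est_inter[i] <- fit_interarrival(log)$mean
    est_nov[i] <- fit_service_times(log, "novice_resident")$mean
  }
  se_i <- sd(est_inter) / sqrt(length(est_inter))
  expect_lt(abs(mean(est_inter) - dist_mean(cfg$interarrival)), 3 * se_i)
  se_n <- sd(est_nov) / sqrt(length(est_nov))
  expect_lt(abs(mean(est_nov) - 3.46), 3 * se_n)
})

test_that("runs_test reproduces hand-computable cases", {
  r <- runs_test(rep(c(1, 5), 10))         # strictly alternating, n = 20
  expect_equal(r$n_runs, 20L)
  expect_lt(r$p_value, 1e-4)
  expect_error(runs_test(rep(2, 6)), "all values equal")
  expect_error(runs_test(3), "at least 2")
})

test_that("runs_test normal approximation tracks exhaustive enumeration", {
  # all balanced +-1 sequences of length 8 (the normal approximation is
  # documented as coarse at this n; bound its error)
  combos <- utils::combn(8, 4)
  worst <- 0
  for (j in seq_len(ncol(combos))) {
    s <- rep(-1, 8); s[combos[, j]] <- 1
    approx_p <- runs_test(s)$p_value
    exact_p <- runs_exact_p(s)
    worst <- max(worst, abs(approx_p - exact_p))
  }
  expect_lt(worst, 0.05)  # the documented approximation error bound
})

test_that("runs_test holds its nominal size under the null", {
  set.seed(99)
  rej <- mean(replicate(1000, runs_test(runif(50))$p_value < 0.05))
  # binomial 3 sigma around 0.05 with 1000 trials: +-0.0207
  expect_gt(rej, 0.05 - 0.021)
  expect_lt(rej, 0.05 + 0.021)
})

test_that("validate_waits is calibrated under the null and rejects shifts", {
  cfg <- default_base_case()
  reps <- run_replications(cfg, 0, n_reps = 400, seed = 8)
  sims <- reps$rep_waits[, "novice_resident"]
  obs <- data.frame(station = "novice_resident",
                    mean = mean(sims), sd = sd(sims), n = 375L)
  v0 <- validate_waits(cfg, obs, n_reps = 400, seed = 8)
  expect_gt(v0$p_value, 0.9)     # observed == simulated mean, same seed
  # shift by +10 sd of the replication means: decisive rejection
  obs$mean <- mean(sims) + 10 * sd(sims)
  v1 <- validate_waits(cfg, obs, n_reps = 400, seed = 8)
  expect_lt(v1$p_value, 1e-3)
  # unknown station rejected
  expect_error(
    validate_waits(cfg, data.frame(station = "mri", mean = 1), seed = 1),
    "mri")
  # t-test variant uses the observed summary's standard error
  obs$mean <- mean(sims) + 0.2
  vt <- validate_waits(cfg, obs, n_reps = 50, seed = 8, test = "t")
  expect_equal(vt$statistic,
               (obs$mean - vt$simulated_mean) / (obs$sd / sqrt(375)),
               tolerance = 1e-10)
})
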