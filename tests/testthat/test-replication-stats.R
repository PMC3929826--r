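test_that("weighted_mean_waits reproduces the published scoring arithmetic", {
  w <- c(novice_resident = 2, experienced_resident = 2, senior_staff = 1)
  expect_equal(weighted_mean_waits(
    c(novice_resident = 59.60, experienced_resident = 54.03,
      senior_staff = 49.52), w), 55.36, tolerance = 0.005 / 55.36)
  expect_equal(weighted_mean_waits(
    c(novice_resident = 13.47, experienced_resident = 14.50,
      senior_staff = 23.21), w), 15.83, tolerance = 0.005 / 15.83)
  x <- c(novice_resident = 7, experienced_resident = 7, senior_staff = 7)
  expect_equal(weighted_mean_waits(x, w), 7)              # identity
  expect_error(weighted_mean_waits(c(a = 1), w), "names")
  expect_error(weighted_mean_waits(x, -w), "> 0")
})

test_that("percent_reduction matches the published headline arithmetic", {
  # the published 71.40% derives from the unrounded base-case weighted mean
  # (2*59.60 + 2*54.03 + 49.52)/5 = 55.356, printed as 55.36
  expect_equal(round(percent_reduction(276.78 / 5, 15.83), 2), 71.40)
  expect_equal(round(percent_reduction(55.36, 15.83), 2), 71.41)
  expect_equal(percent_reduction(42, 42), 0)
  expect_equal(percent_reduction(42, 0), 100)
  expect_error(percent_reduction(0, 10), "base")
})

test_that("rank_scenarios sorts ascending, stably, input-order independent", {
  wm <- reported_weighted_means()
  v <- setNames(wm$weighted_mean, wm$scenario_id)
  v <- v[names(v) != "0"]
  r <- rank_scenarios(v)
  expect_equal(r$scenario_id, c(9, 10, 7, 3, 8, 5, 6, 1, 2, 4))
  set.seed(1)
  expect_equal(rank_scenarios(sample(v)), r)              # permutation-proof
  expect_equal(rank_scenarios(c(`4` = 2.0))$scenario_id, 4L)
  # ties keep scenario-id order
  expect_equal(rank_scenarios(c(`7` = 3, `2` = 3, `5` = 1))$scenario_id,
               c(5L, 2L, 7L))
})

test_that("run_replications with n_reps = 1 equals a single simulation", {
  cfg <- default_base_case()
  s <- run_replications(cfg, 0, n_reps = 1, seed = 17)
  one <- simulate_clinic(cfg, seed = clinicflow:::stream_seeds(17, 1))
  expect_equal(unname(s$station_means["novice_resident"]),
               station_waits(one, "novice_resident"))
  expect_equal(s$n_reps, 1L)
  expect_error(run_replications(cfg, 0, n_reps = 0), "n_reps")
})

test_that("replication summaries respect the decomposition identity", {
  s <- run_replications(default_base_case(), 3, n_reps = 40, seed = 9)
  expect_equal(s$physicians$mean_total,
               s$physicians$mean_before + s$physicians$mean_after,
               tolerance = 1e-9)
  expect_equal(s$weighted_mean,
               weighted_mean_waits(
                 setNames(s$physicians$mean_total, s$physicians$station)))
  expect_identical(
    s$physicians$mean_total,
    run_replications(default_base_case(), 3, n_reps = 40, seed = 9
                     )$physicians$mean_total)             # deterministic
})

test_that("weighted-mean variance shrinks roughly like 1/n_reps", {
  cfg <- default_base_case()
  wm <- function(n_reps, seed) run_replications(cfg, 0, n_reps = n_reps,
                                                seed = seed)$weighted_mean
  seeds <- 1:20
  v_small <- var(vapply(seeds, function(s) wm(25, s), numeric(1)))
  v_large <- var(vapply(seeds + 100, function(s) wm(100, s), numeric(1)))
  # 4x replications ~ 4x variance reduction; the 0.9 bound keeps the
  # false-failure rate of the variance-ratio test below ~1e-3
  expect_lt(v_large, v_small * 0.9)
})

test_that("calibrate with budget 0 returns the input config and its error", {
  cfg <- default_base_case()
  obs <- data.frame(station = c("novice_resident", "experienced_resident"),
                    mean = c(50, 60))
  out <- calibrate(cfg, obs, budget = 0, seed = 3, n_reps = 10)
  expect_equal(validate_clinic_config(out), out, ignore_attr = TRUE)
  expect_equal(out$classes$new$mix_probability,
               cfg$classes$new$mix_probability)
  expect_true(is.finite(attr(out, "objective")))
  expect_error(calibrate(cfg, obs, free_params = character(0)), "free_params")
})

test_that("calibrate recovers waits generated by a known configuration", {
  # observed summary produced by a known mix; calibration over that mix
  # must bring simulated waits within 5% of the generating ones
  truth <- default_base_case(mix = c(new = 0.12, followup_outpatient = 0.08,
                                     followup_prev_inpatient = 0.8))
  target <- run_replications(truth, 0, n_reps = 80, seed = 100)
  obs <- data.frame(
    station = c("novice_resident", "experienced_resident", "senior_staff"),
    mean = unname(target$station_means[c("novice_resident",
                                         "experienced_resident",
                                         "senior_staff")]))
  cal <- calibrate(default_base_case(), obs, free_params = "mix",
                   budget = 40, seed = 6, n_reps = 40)
  got <- run_replications(cal, 0, n_reps = 200, seed = 100)
  for (st in obs$station) {
    expect_lt(abs(got$station_means[st] - obs$mean[obs$station == st]) /
                obs$mean[obs$station == st], 0.05, label = st)
  }
})

test_that("compare_scenarios tabulates, scores, ranks and writes CSVs", {
  cmp <- compare_scenarios(default_base_case(), scenario_ids = c(0, 1, 9),
                           n_reps = 30, seed = 4)
  expect_equal(dim(cmp$decomposition), c(9L, 3L))
  expect_equal(cmp$scores$pct_reduction[1], 0)
  expect_equal(cmp$scores$weighted_mean[2],
               cmp$summaries[["1"]]$weighted_mean)
  expect_setequal(cmp$ranking$scenario_id, c(1L, 9L))
  dir <- withr::local_tempdir()
  paths <- write_comparison(cmp, dir)
  expect_true(all(file.exists(paths)))
  tab <- read.csv(file.path(dir, "weighted_scores.csv"))
  expect_equal(nrow(tab), 3L)
})
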