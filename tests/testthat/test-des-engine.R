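test_that("degenerate days: no arrivals, or a single uncontended patient", {
  cfg <- default_base_case(admission_duration = 0)
  sim <- simulate_clinic(cfg, seed = 1)
  expect_equal(sim$n_patients, 0L)
  expect_equal(nrow(sim$log), 0L)
  expect_true(is.na(station_waits(sim, "registration")))  # flagged, not 0

  # one patient arriving after every station has opened, empty system
  cfg1 <- single_station_config(dist_spec("constant", 5),
                                dist_spec("constant", 2))
  sim1 <- simulate_clinic(cfg1, seed = 1, n_patients = 1)
  expect_equal(nrow(sim1$log), 3L)  # registration, cash, physician
  expect_equal(sim1$log$service_start - sim1$log$queue_join, rep(0, 3))
})

test_that("decompose_wait splits around attendance start and sums to total", {
  expect_equal(decompose_wait(480, 630, 600), list(before = 120, after = 30))
  expect_equal(decompose_wait(610, 625, 600), list(before = 0, after = 15))
  expect_equal(decompose_wait(540, 580, 600), list(before = 40, after = 0))
  # property: before + after always equals the full wait
  set.seed(42)
  qj <- runif(500, 400, 700)
  ss <- qj + runif(500, 0, 200)
  d <- decompose_wait(qj, ss, 600)
  expect_equal(d$before + d$after, ss - qj)
  expect_true(all(d$before >= 0 & d$after >= 0))
})

test_that("station_waits averages per-station queueing delays", {
  cfg <- single_station_config(dist_spec("constant", 1),
                               dist_spec("constant", 3))
  sim <- simulate_clinic(cfg, seed = 1, n_patients = 3)
  # arrivals at 1, 2, 3; services of 3 min back-to-back from t = 1
  ph <- sim$log[sim$log$station == "experienced_resident", ]
  expect_equal(ph$service_start - ph$queue_join, c(0, 2, 4))
  expect_equal(station_waits(sim, "experienced_resident"), 2)
  expect_error(station_waits(sim, "x_ray"), "arg")
})

test_that("engine satisfies conservation, causality and FIFO on random days", {
  for (seed in 1:8) {
    cfg <- random_config(seed + 100)
    sim <- simulate_clinic(cfg, seed = seed)
    log <- sim$log
    # conservation: every admitted patient has one complete route
    expect_equal(length(unique(log$patient_id)), sim$n_patients)
    expect_true(all(table(paste(log$patient_id, log$station)) == 1))
    # everyone admitted is eventually served everywhere on their route
    expect_false(any(is.na(log$service_start)))
    # causality incl. physician attendance starts; FIFO via the checker
    expect_true(isTRUE(check_event_log(log)), info = paste("seed", seed))
    for (ph in c("novice_resident", "experienced_resident", "senior_staff")) {
      rows <- log$station == ph
      expect_true(all(log$service_start[rows] >=
                        cfg$stations[[ph]]$schedule$start))
    }
    # route consistency with class rules
    first_phys <- vapply(
      split(log, log$patient_id),
      function(d) intersect(d$station,
                            c("novice_resident", "experienced_resident"))[1],
      character(1))
    cls <- log$class[!duplicated(log$patient_id)]
    expect_equal(unname(first_phys),
                 unname(vapply(cfg$classes[cls], `[[`, character(1),
                               "first_physician")))
  }
})

test_that("identical (config, seed) reproduces the event stream exactly", {
  cfg <- default_base_case()
  s1 <- simulate_clinic(cfg, seed = 77)
  s2 <- simulate_clinic(cfg, seed = 77)
  expect_identical(s1$log, s2$log)
  s3 <- simulate_clinic(cfg, seed = 78)
  expect_false(identical(s1$log, s3$log))
})

test_that("engine matches an independent brute-force replay on small days", {
  for (seed in 1:5) {
    cfg <- random_config(seed + 200)
    sim <- simulate_clinic(cfg, seed = seed, n_patients = 15)
    log <- sim$log[order(sim$log$patient_id, sim$log$queue_join), ]

    # reconstruct the engine's sampled inputs from its own log, then replay
    # them with the independent pure-R network simulator
    sched <- lapply(cfg$stations, `[[`, "schedule")
    routes <- lapply(split(log, log$patient_id), function(d)
      match(d$station, clinicflow:::STATION_IDS))
    services <- lapply(split(log, log$patient_id), function(d)
      d$service_end - d$service_start)
    arrival <- log$queue_join[!duplicated(log$patient_id)]
    replay <- replay_network(
      arrival, routes, services,
      open = vapply(sched, `[[`, numeric(1), "start"),
      n_servers = vapply(sched, `[[`, integer(1), "n_servers"))
    replay <- replay[order(replay$patient_id, replay$queue_join), ]
    expect_equal(replay$service_start, log$service_start,
                 info = paste("seed", seed))
    expect_equal(replay$service_end, log$service_end,
                 info = paste("seed", seed))
  }
})

test_that("M/M/1 mean wait matches the closed form within 3 MC SE", {
  # lambda = 1/2, mu = 1: Wq = rho / (mu - lambda) = 1 minute
  cfg <- single_station_config(dist_spec("exponential", 2),
                               dist_spec("exponential", 1))
  sim <- simulate_clinic(cfg, seed = 901, n_patients = 2e4)
  ph <- sim$log[sim$log$station == "experienced_resident", ]
  w <- ph$service_start - ph$queue_join
  se <- batch_se(w)
  expect_lt(abs(mean(w) - erlang_c_wq(0.5, 1, 1)), 3 * se)
})

test_that("hard schedule cutoff stops new services after closing", {
  cfg <- single_station_config(dist_spec("constant", 1),
                               dist_spec("constant", 10))
  cfg$overtime <- FALSE
  cfg$stations$experienced_resident$schedule <- server_schedule(0, 25, 1L)
  sim <- simulate_clinic(cfg, seed = 1, n_patients = 5)
  ph <- sim$log[sim$log$station == "experienced_resident", ]
  # services at 1, 11, 21 start on/before close (t=25); the rest never start
  expect_equal(sum(!is.na(ph$service_start)), 3L)
  expect_true(all(ph$service_start[!is.na(ph$service_start)] <= 25))
  # overtime = TRUE serves everyone
  cfg$overtime <- TRUE
  simo <- simulate_clinic(cfg, seed = 1, n_patients = 5)
  expect_false(any(is.na(simo$log$service_start[
    simo$log$station == "experienced_resident"])))
})

test_that("Little's law holds in a stationary single-station day", {
  cfg <- single_station_config(dist_spec("exponential", 2),
                               dist_spec("exponential", 1))
  sim <- simulate_clinic(cfg, seed = 31, n_patients = 1e4)
  log <- sim$log
  arrive <- tapply(log$queue_join, log$patient_id, min)
  exit <- tapply(log$service_end, log$patient_id, max)
  t_end <- max(exit)
  # L from step-function integration of the headcount process (independent
  # of the per-patient W bookkeeping)
  L <- time_average_headcount(arrive, exit)
  lambda <- length(arrive) / t_end
  W <- mean(exit - arrive)
  expect_equal(L, lambda * W, tolerance = 0.02)
})

test_that("event-log CSV writer and reader round-trip", {
  sim <- simulate_clinic(default_base_case(), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_log(sim$log, path)
  back <- read_event_log(path)
  expect_equal(back$patient_id, sim$log$patient_id)
  expect_equal(back$queue_join, round(sim$log$queue_join, 3))
  # checker flags corrupted logs
  bad <- back
  bad$service_start[2] <- bad$queue_join[2] - 5
  expect_match(paste(check_event_log(bad), collapse = " "), "causality")
})
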