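# Independent oracles and fixture builders used across the suite.

# A single-station always-open clinic: every patient is routed to the
# experienced resident only (mix puts all mass on class "new", registration
# and cash made instantaneous so they are transparent).
single_station_config <- function(interarrival, service, n_servers = 1L,
                                  admission_duration = 1e6) {
  cfg <- default_base_case(admission_duration = admission_duration)
  cfg$interarrival <- interarrival
  cfg$classes$new$mix_probability <- 1
  cfg$classes$followup_outpatient$mix_probability <- 0
  cfg$classes$followup_prev_inpatient$mix_probability <- 0
  for (cl in names(cfg$classes)) {
    cfg$classes[[cl]]$p_consult_senior <- 0
    cfg$classes[[cl]]$p_paraclinic <- 0
  }
  cfg$admission_start <- 0
  for (st in names(cfg$stations)) cfg$stations[[st]]$schedule$start <- 0
  cfg$stations$registration$service <- dist_spec("constant", 0)
  cfg$stations$cash$service <- dist_spec("constant", 0)
  cfg$stations$experienced_resident$service <- service
  cfg$stations$experienced_resident$schedule <-
    server_schedule(0, 2e6, n_servers)
  for (st in setdiff(names(cfg$stations),
                     c("registration", "cash", "experienced_resident")))
    cfg$stations[[st]]$schedule <- server_schedule(0, 2e6, 1L)
  validate_clinic_config(cfg)
}

# Erlang-C mean queueing delay for M/M/c.
erlang_c_wq <- function(lambda, mu, c) {
  rho <- lambda / (c * mu)
  stopifnot(rho < 1)
  a <- lambda / mu
  terms <- vapply(0:(c - 1), function(k) a^k / factorial(k), numeric(1))
  erlc <- (a^c / factorial(c)) / (1 - rho) /
    (sum(terms) + (a^c / factorial(c)) / (1 - rho))
  erlc / (c * mu - lambda)
}

# Batch-means standard error of the mean of an autocorrelated series.
batch_se <- function(x, n_batches = 50L) {
  n <- length(x)
  bs <- floor(n / n_batches)
  m <- vapply(seq_len(n_batches),
              function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), numeric(1))
  stats::sd(m) / sqrt(n_batches)
}

# Brute-force event-log replay: an independent (slow, pure-R) re-simulation
# of a FIFO multi-server network from pre-sampled arrivals/routes/services.
# Advances patient by patient in time order using per-server free times.
replay_network <- function(arrival, routes, services, open, n_servers,
                           overtime = TRUE, close = NULL) {
  n <- length(arrival)
  n_st <- length(open)
  free <- lapply(seq_len(n_st), function(s) rep(open[s], n_servers[s]))
  # pending[[p]] = next step; event-driven by repeatedly picking the
  # earliest (queue_join, patient) among patients ready to be served.
  step <- rep(1L, n)
  ready_time <- arrival  # time patient joins queue of routes[[p]][step[p]]
  done <- vapply(routes, length, integer(1)) == 0L
  out <- lapply(seq_len(n), function(p)
    data.frame(station = routes[[p]],
               queue_join = NA_real_, service_start = NA_real_,
               service_end = NA_real_))
  while (!all(done)) {
    # Among unfinished patients, FIFO per station: the engine serves, at
    # each station, in order of (queue_join, patient id). Globally we can
    # always safely process the patient whose (station service_start
    # candidate) is smallest... simpler: pick the patient with the smallest
    # (ready_time, id) whose station has no other waiting patient with a
    # smaller (ready_time, id).
    idx <- which(!done)
    st_of <- vapply(idx, function(p) routes[[p]][step[p]], numeric(1))
    pick <- NULL
    for (s in unique(st_of)) {
      cand <- idx[st_of == s]
      o <- cand[order(ready_time[cand], cand)]
      pick <- rbind(pick, c(o[1L], s))
    }
    # serve the head-of-line patient with the earliest service start
    starts <- apply(pick, 1L, function(row) {
      p <- row[1L]; s <- row[2L]
      max(ready_time[p], min(free[[s]]))
    })
    k <- which.min(starts + 1e-9 * pick[, 1L])  # tie -> smaller patient id
    p <- pick[k, 1L]; s <- pick[k, 2L]
    srv <- which.min(free[[s]])
    t_start <- max(ready_time[p], free[[s]][srv])
    dur <- services[[p]][step[p]]
    out[[p]]$queue_join[step[p]] <- ready_time[p]
    out[[p]]$service_start[step[p]] <- t_start
    out[[p]]$service_end[step[p]] <- t_start + dur
    free[[s]][srv] <- t_start + dur
    ready_time[p] <- t_start + dur
    step[p] <- step[p] + 1L
    if (step[p] > length(routes[[p]])) done[p] <- TRUE
  }
  do.call(rbind, lapply(seq_len(n), function(p) {
    df <- out[[p]]; df$patient_id <- p; df
  }))
}

# Time-average headcount L of a system from per-patient arrival/exit times,
# via a cumsum sweep over the +1/-1 event step function (independent of the
# engine's per-visit bookkeeping).
time_average_headcount <- function(arrive, exit) {
  t <- c(arrive, exit)
  d <- c(rep(1, length(arrive)), rep(-1, length(exit)))
  o <- order(t, d)
  t <- t[o]
  n_in <- cumsum(d[o])
  sum(n_in[-length(n_in)] * diff(t)) / max(exit)
}

# Exact two-sided runs-test p-value by exhaustive enumeration of all
# arrangements with the observed (n1, n2), conditioning as the normal
# approximation does.
runs_exact_p <- function(s) {
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  runs_of <- function(x) 1L + sum(diff(x) != 0)
  perms <- utils::combn(n, n1)
  rs <- apply(perms, 2L, function(pos) {
    x <- rep(-1L, n); x[pos] <- 1L; runs_of(x)
  })
  mu <- 1 + 2 * n1 * n2 / n
  r_obs <- runs_of(s)
  mean(abs(rs - mu) >= abs(r_obs - mu) - 1e-12)
}

# Tiny valid config with randomized numeric fields (for round-trip tests).
random_config <- function(seed) {
  set.seed(seed)
  mix <- signif(as.numeric(stats::runif(3)), 6)
  mix <- round(mix / sum(mix), 6)
  mix[3] <- 1 - mix[1] - mix[2]
  names(mix) <- c("new", "followup_outpatient", "followup_prev_inpatient")
  cfg <- default_base_case(
    mix = mix,
    p_consult_senior = round(stats::runif(1), 6),
    p_paraclinic = round(stats::runif(1), 6),
    admission_duration = round(stats::runif(1, 60, 400), 4))
  cfg$stations$novice_resident$schedule <-
    server_schedule(round(stats::runif(1, 400, 700), 4),
                    round(stats::runif(1, 50, 300), 4),
                    sample(1:4, 1))
  cfg$stations$cash$service <-
    dist_spec("lognormal", round(stats::runif(1, 0.1, 3), 6),
              round(stats::runif(1, 0.01, 2), 6))
  fam <- sample(c("clipped_normal", "truncated_normal", "exponential"), 1)
  m <- round(stats::runif(1, 2, 8), 6)
  cfg$interarrival <- dist_spec(fam, m,
                                if (fam == "exponential") m
                                else round(stats::runif(1, 1, 6), 6))
  validate_clinic_config(cfg)
}
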