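#' Distribution fit summary
#'
#' @param family Distribution family label.
#' @param mean,sd Sample mean and standard deviation (minutes).
#' @param n Number of observations.
#' @param extra Optional named list of additional estimates.
#' @return A `dist_fit` object with fields `family`, `mean`, `sd`, `n`,
#'   `se_mean` (`sd / sqrt(n)`), plus any extras.
#' @keywords internal
new_dist_fit <- function(family, mean, sd, n, extra = list()) {
  structure(c(list(family = family, mean = mean, sd = sd, n = as.integer(n),
                   se_mean = sd / sqrt(n)), extra), class = "dist_fit")
}

#' @export
print.dist_fit <- function(x, ...) {
  cat(sprintf("<dist_fit %s: mean %.4g (sd %.4g, n %d, se %.3g)>\n",
              x$family, x$mean, x$sd, x$n, x$se_mean))
  if (!is.null(x$underlying_mean))
    cat(sprintf("  de-truncated normal: mean %.4g, sd %.4g\n",
                x$underlying_mean, x$underlying_sd))
  invisible(x)
}

# Arrival time of each patient = queue_join at the first visited station.
log_arrival_times <- function(log) {
  first <- !duplicated(log$patient_id)
  sort(log$queue_join[first])
}

#' Fit the interarrival-time distribution from an event log
#'
#' Takes successive differences of the sorted patient arrival times (the
#' queue-join time at each patient's first station) and reports their sample
#' mean and standard deviation. Because the clinic's interarrival process is
#' a normal distribution kept above `lower` — either by clipping negative
#' draws to the bound (the default generator family, which leaves a point
#' mass of zero gaps) or by conditional truncation — the raw moments do not
#' estimate the underlying normal parameters. The fit therefore also
#' recovers the *pre-truncation* normal mean and SD by maximum likelihood
#' (`underlying_mean`, `underlying_sd`): a censored-normal (Tobit)
#' likelihood when gaps at the bound are present, a truncated-normal
#' likelihood otherwise.
#'
#' @param log An event-log data.frame (see [write_event_log()] schema).
#' @param lower Truncation bound of the fitted family (minutes, default 0).
#' @return A `dist_fit` with family `"clipped_normal"` or
#'   `"truncated_normal"` (chosen by whether gaps sit exactly at the bound),
#'   the raw moments of the gaps, and `underlying_mean`, `underlying_sd`
#'   from the MLE.
#' @export
fit_interarrival <- function(log, lower = 0) {
  arr <- log_arrival_times(log)
  if (length(arr) < 2L)
    stop("fit_interarrival: need at least 2 arrivals, got ", length(arr),
         call. = FALSE)
  gaps <- diff(arr)
  m <- mean(gaps); s <- stats::sd(gaps)
  censored <- gaps <= lower + 1e-9
  family <- if (any(censored)) "clipped_normal" else "truncated_normal"
  mle <- fit_boundednorm_mle(gaps, censored, lower,
                             start = c(m, max(s, 1e-3)))
  new_dist_fit(family, m, s, length(gaps),
               extra = list(underlying_mean = mle[1L],
                            underlying_sd = mle[2L], lower = lower))
}

# MLE of the underlying N(mu, sigma) given gaps bounded below at `lower`:
# censored (Tobit) likelihood for observations flagged `censored`, truncated
# likelihood when none are.
fit_boundednorm_mle <- function(x, censored, lower, start) {
  if (stats::sd(x) == 0) return(c(mean(x), 0))
  n_cens <- sum(censored)
  xo <- x[!censored]
  nll <- function(par) {
    mu <- par[1L]; sig <- exp(par[2L])
    ll <- sum(stats::dnorm(xo, mu, sig, log = TRUE))
    ll <- ll + if (n_cens > 0L)
      n_cens * stats::pnorm(lower, mu, sig, log.p = TRUE)
    else
      -length(x) * stats::pnorm(lower, mu, sig, lower.tail = FALSE,
                                log.p = TRUE)
    -ll
  }
  fit <- stats::optim(c(start[1L], log(start[2L])), nll,
                      method = "Nelder-Mead")
  c(fit$par[1L], exp(fit$par[2L]))
}

#' Fit a station's service-time distribution from an event log
#'
#' @param log An event-log data.frame.
#' @param station_id Station to fit.
#' @return A `dist_fit` with the sample mean/sd of
#'   `service_end - service_start` at the station (family `"lognormal"`, the
#'   default service family).
#' @export
fit_service_times <- function(log, station_id) {
  station_id <- match.arg(station_id, STATION_IDS)
  rows <- log$station == station_id & !is.na(log$service_end)
  dur <- log$service_end[rows] - log$service_start[rows]
  if (length(dur) < 2L)
    stop("fit_service_times: fewer than 2 completed services at station `",
         station_id, "`", call. = FALSE)
  new_dist_fit("lognormal", mean(dur), stats::sd(dur), length(dur))
}

#' Wald-Wolfowitz runs test for randomness
#'
#' Dichotomizes the sequence about its median (values equal to the median are
#' dropped), counts runs of consecutive values on the same side, and applies
#' the normal approximation with a continuity correction: with `n1`, `n2`
#' values above/below and `R` runs, `E[R] = 1 + 2 n1 n2 / n`,
#' `Var[R] = 2 n1 n2 (2 n1 n2 - n) / (n^2 (n-1))`, and
#' `z = sign(R - E[R]) max(0, |R - E[R]| - 0.5) / sqrt(Var[R])`.
#' The two-sided p from this approximation stays within 0.05 of the exact
#' enumeration p for balanced sequences as short as 8 (asserted against
#' exhaustive enumeration in the test suite); the discrepancy shrinks
#' rapidly with n and is negligible for long sequences.
#'
#' @param values Ordered numeric sequence (e.g. service times in collection
#'   order).
#' @return A list with `n_runs`, `n1`, `n2`, `z` and the two-sided `p_value`.
#' @examples
#' runs_test(rep(c(1, 2), 10))$n_runs  # 20: strictly alternating
#' @export
runs_test <- function(values) {
  if (length(values) < 2L)
    stop("runs_test: need at least 2 values", call. = FALSE)
  med <- stats::median(values)
  s <- sign(values - med)
  s <- s[s != 0]
  if (length(s) < 2L)
    stop("runs_test: all values equal (no variation about the median)",
         call. = FALSE)
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  r <- 1L + sum(diff(s) != 0)
  mu <- 1 + 2 * n1 * n2 / n
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- if (v > 0) sign(r - mu) * max(0, abs(r - mu) - 0.5) / sqrt(v) else 0
  list(n_runs = r, n1 = n1, n2 = n2, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Validate simulated waits against observed per-station summaries
#'
#' Replicates the clinic day `n_reps` times and, for each observed station,
#' tests the observed mean wait against the simulation. The default `"z"`
#' test scores the observed mean against the *distribution of
#' per-replication day means*: `z = (obs - mean(reps)) / sd(reps)`. Under
#' the null (the observed day generated by the configured model) the observed
#' day mean is one more draw from that distribution, so p is uniform. The
#' `"t"` alternative is a one-sample t-test from the observed summary
#' (`se = sd / sqrt(n)`) against the simulated grand mean.
#'
#' @param config A [clinic_config()].
#' @param observed A data.frame with columns `station`, `mean` and (for the
#'   `"t"` test) `sd`, `n`. See [observed_station_summary()] for the study's
#'   published values.
#' @param n_reps Number of replications (default from `config$n_reps`).
#' @param seed Root seed.
#' @param test `"z"` (default, against the replication distribution) or
#'   `"t"` (from the observed summary).
#' @return A `validation_report` data.frame with one row per observed
#'   station: `observed_mean`, `observed_sd`, `simulated_mean`, `statistic`,
#'   `p_value`, plus attribute `pass` (`TRUE` when all p > 0.05).
#' @export
validate_waits <- function(config, observed, n_reps = config$n_reps, seed = 1L,
                           test = c("z", "t")) {
  test <- match.arg(test)
  validate_clinic_config(config)
  unknown <- setdiff(observed$station, STATION_IDS)
  if (length(unknown))
    stop("validate_waits: observed station(s) absent from config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  reps <- run_replications(config, 0L, n_reps = n_reps, seed = seed)
  out <- observed[, "station", drop = FALSE]
  out$observed_mean <- observed$mean
  out$observed_sd <- if ("sd" %in% names(observed)) observed$sd else NA_real_
  out$simulated_mean <- out$statistic <- out$p_value <- NA_real_
  for (i in seq_len(nrow(out))) {
    st <- out$station[i]
    sims <- reps$rep_waits[, st]
    sims <- sims[!is.na(sims)]
    sim_mean <- mean(sims)
    out$simulated_mean[i] <- sim_mean
    if (test == "z") {
      stat <- (out$observed_mean[i] - sim_mean) / stats::sd(sims)
      out$statistic[i] <- stat
      out$p_value[i] <- 2 * stats::pnorm(-abs(stat))
    } else {
      if (!("n" %in% names(observed)) || !("sd" %in% names(observed)))
        stop("validate_waits: the 't' test needs `sd` and `n` in `observed`",
             call. = FALSE)
      se <- observed$sd[i] / sqrt(observed$n[i])
      stat <- (out$observed_mean[i] - sim_mean) / se
      out$statistic[i] <- stat
      out$p_value[i] <- 2 * stats::pt(-abs(stat), df = observed$n[i] - 1)
    }
  }
  structure(out, class = c("validation_report", "data.frame"),
            pass = all(out$p_value > 0.05))
}
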