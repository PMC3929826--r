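#' Replicate a scenario and aggregate decomposed waits
#'
#' Runs `n_reps` independent clinic days under `config` with the scenario's
#' deltas applied and averages, over replications, each replication's mean
#' waits: per-station totals, and at each physician station the
#' before/after-attendance decomposition. Replication seeds derive from the
#' root `seed` only, so two scenarios summarized with the same seed run on
#' common random numbers.
#'
#' @param config A [clinic_config()].
#' @param scenario Scenario id or object (default 0, the base case).
#' @param n_reps Number of replications (default `config$n_reps`, 1000).
#' @param seed Root seed.
#' @return A `replication_summary`: list with `scenario_id`, `n_reps`,
#'   `physicians` (data.frame of `mean_before`, `mean_after`, `mean_total`
#'   per physician station), `station_means` (named vector over all
#'   stations), `weighted_mean` (the 2:2:1 score), and the per-replication
#'   matrices `rep_waits`, `rep_before`, `rep_after` used by
#'   [validate_waits()] and the variance diagnostics.
#' @examples
#' \donttest{
#' s <- run_replications(default_base_case(), 0, n_reps = 100, seed = 1)
#' s$weighted_mean
#' }
#' @export
run_replications <- function(config, scenario = 0L, n_reps = config$n_reps,
                             seed = 1L) {
  if (n_reps < 1) stop("run_replications: `n_reps` must be >= 1", call. = FALSE)
  scenario <- get_scenario(scenario)
  cfg <- apply_scenario(config, scenario)
  rep_seeds <- stream_seeds(seed, n_reps)
  n_st <- length(STATION_IDS)
  rep_waits <- rep_before <- rep_after <- matrix(
    NA_real_, n_reps, n_st, dimnames = list(NULL, STATION_IDS))
  n_patients <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    sm <- summarize_raw(simulate_raw(cfg, rep_seeds[r]))
    rep_waits[r, ] <- sm$wait
    rep_before[r, ] <- sm$before
    rep_after[r, ] <- sm$after
    n_patients[r] <- sm$n_patients
  }
  station_means <- colMeans(rep_waits, na.rm = TRUE)
  before <- colMeans(rep_before, na.rm = TRUE)[PHYSICIAN_IDS]
  after <- colMeans(rep_after, na.rm = TRUE)[PHYSICIAN_IDS]
  physicians <- data.frame(station = PHYSICIAN_IDS,
                           mean_before = unname(before),
                           mean_after = unname(after),
                           mean_total = unname(before + after),
                           row.names = NULL, stringsAsFactors = FALSE)
  totals <- stats::setNames(physicians$mean_total, PHYSICIAN_IDS)
  structure(list(scenario_id = scenario$id, label = scenario$label,
                 n_reps = as.integer(n_reps),
                 physicians = physicians, station_means = station_means,
                 weighted_mean = weighted_mean_waits(totals, config$weights),
                 mean_n_patients = mean(n_patients),
                 rep_waits = rep_waits, rep_before = rep_before,
                 rep_after = rep_after, seed = seed),
            class = "replication_summary")
}

#' @export
print.replication_summary <- function(x, ...) {
  cat(sprintf("<replication_summary: scenario %d (%s), %d reps, ~%.1f patients/day>\n",
              x$scenario_id, x$label, x$n_reps, x$mean_n_patients))
  ph <- x$physicians
  for (i in seq_len(nrow(ph)))
    cat(sprintf("  %-21s before %6.2f  after %6.2f  total %6.2f min\n",
                ph$station[i], ph$mean_before[i], ph$mean_after[i],
                ph$mean_total[i]))
  cat(sprintf("  weighted mean (2:2:1): %.2f min\n", x$weighted_mean))
  invisible(x)
}

#' Weighted mean of per-server waiting times
#'
#' The clinic's single-number scenario score: `sum(w_i t_i) / sum(w_i)`,
#' with the default weights 2 (novice resident), 2 (experienced resident),
#' 1 (senior staff physician) reflecting each server's share of patients.
#'
#' @param totals Named numeric vector of per-server total mean waits
#'   (minutes).
#' @param weights Named numeric weights; must have exactly the same names as
#'   `totals` and be positive.
#' @return The weighted mean, in minutes.
#' @examples
#' weighted_mean_waits(
#'   c(novice_resident = 59.60, experienced_resident = 54.03,
#'     senior_staff = 49.52),
#'   c(novice_resident = 2, experienced_resident = 2, senior_staff = 1))
#' @export
weighted_mean_waits <- function(totals,
                                weights = c(novice_resident = 2,
                                            experienced_resident = 2,
                                            senior_staff = 1)) {
  if (is.null(names(totals)) || is.null(names(weights)) ||
      !setequal(names(totals), names(weights)))
    stop("weighted_mean_waits: `totals` and `weights` must share the same ",
         "names", call. = FALSE)
  if (any(weights <= 0))
    stop("weighted_mean_waits: weights must be > 0", call. = FALSE)
  w <- weights[names(totals)]
  sum(w * totals) / sum(w)
}

#' Percent reduction of a waiting time relative to the base case
#'
#' @param base Base-case value (minutes); must be > 0.
#' @param alternative Scenario value (minutes).
#' @return `100 * (base - alternative) / base`.
#' @examples
#' percent_reduction(55.36, 15.83)  # 71.40 at 2 dp
#' @export
percent_reduction <- function(base, alternative) {
  if (any(base <= 0))
    stop("percent_reduction: `base` must be > 0", call. = FALSE)
  100 * (base - alternative) / base
}

#' Rank scenarios by weighted-mean waiting time
#'
#' @param summaries A list of `replication_summary` objects, or a named
#'   numeric vector of weighted means (names = scenario ids).
#' @return A data.frame sorted ascending by `weighted_mean` (best scenario
#'   first); ties keep scenario-id order regardless of input order.
#' @export
rank_scenarios <- function(summaries) {
  if (is.numeric(summaries)) {
    df <- data.frame(scenario_id = as.integer(names(summaries)),
                     weighted_mean = unname(summaries))
  } else {
    if (!length(summaries)) stop("rank_scenarios: no summaries", call. = FALSE)
    df <- data.frame(
      scenario_id = vapply(summaries, `[[`, integer(1), "scenario_id"),
      weighted_mean = vapply(summaries, `[[`, numeric(1), "weighted_mean"))
  }
  df <- df[order(df$weighted_mean, df$scenario_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Compare scenarios against the base case
#'
#' Runs every requested scenario with common random numbers (same root seed)
#' and tabulates the decomposed waits, the weighted-mean score, the percent
#' reduction relative to the base scenario and the ranking.
#'
#' @param config A [clinic_config()].
#' @param scenario_ids Scenario ids to run (default `0:10`).
#' @param n_reps Replications per scenario.
#' @param seed Root seed shared by all scenarios.
#' @param base_id Id of the reference scenario for percent reductions.
#' @return A `scenario_comparison`: list with `summaries`, `decomposition`
#'   (Table-2-style data.frame: rows = before/after/total per physician,
#'   columns = scenarios), `scores` (totals + weighted mean + percent
#'   reduction per scenario) and `ranking`.
#' @export
compare_scenarios <- function(config, scenario_ids = 0:10,
                              n_reps = config$n_reps, seed = 1L,
                              base_id = 0L) {
  summaries <- lapply(scenario_ids, function(id)
    run_replications(config, id, n_reps = n_reps, seed = seed))
  names(summaries) <- as.character(scenario_ids)
  decomp <- do.call(cbind, lapply(summaries, function(s) {
    ph <- s$physicians
    stats::setNames(c(rbind(ph$mean_before, ph$mean_after, ph$mean_total)),
                    c(t(outer(ph$station, c("before", "after", "total"),
                              paste, sep = "_"))))
  }))
  decomp <- as.data.frame(decomp)
  names(decomp) <- paste0("scenario_", scenario_ids)
  wm <- vapply(summaries, `[[`, numeric(1), "weighted_mean")
  scores <- data.frame(
    scenario_id = scenario_ids,
    label = vapply(summaries, `[[`, character(1), "label"),
    novice_resident = as.numeric(decomp["novice_resident_total", ]),
    experienced_resident = as.numeric(decomp["experienced_resident_total", ]),
    senior_staff = as.numeric(decomp["senior_staff_total", ]),
    weighted_mean = unname(wm),
    row.names = NULL, stringsAsFactors = FALSE)
  base_wm <- wm[[as.character(base_id)]]
  scores$pct_reduction <- ifelse(scores$scenario_id == base_id, 0,
                                 percent_reduction(base_wm,
                                                   scores$weighted_mean))
  structure(list(summaries = summaries, decomposition = decomp,
                 scores = scores,
                 ranking = rank_scenarios(wm[names(wm) != as.character(base_id)]),
                 base_id = base_id, n_reps = n_reps, seed = seed),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("<scenario_comparison: %d scenarios x %d reps>\n",
              nrow(x$scores), x$n_reps))
  df <- x$scores
  df$weighted_mean <- round(df$weighted_mean, 2)
  df$pct_reduction <- round(df$pct_reduction, 2)
  print(df[, c("scenario_id", "weighted_mean", "pct_reduction")],
        row.names = FALSE)
  cat("best scenario:", x$ranking$scenario_id[1L], "\n")
  invisible(x)
}

#' Write scenario-comparison tables to CSV
#'
#' Writes the waiting-time decomposition (rows = before/after/total per
#' physician server, columns = scenarios) and the score table (totals,
#' weighted mean, percent reduction), both rounded to 2 decimals as reported;
#' internal arithmetic keeps full precision.
#'
#' @param comparison A `scenario_comparison`.
#' @param dir Output directory.
#' @return Character vector of the written paths, invisibly.
#' @export
write_comparison <- function(comparison, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "waiting_decomposition.csv")
  p2 <- file.path(dir, "weighted_scores.csv")
  utils::write.csv(round(comparison$decomposition, 2), p1)
  sc <- comparison$scores
  num <- vapply(sc, is.numeric, logical(1))
  sc[num] <- lapply(sc[num], round, 2)
  utils::write.csv(sc, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Calibrate unpublished clinic parameters against observed waits
#'
#' The patient-class mix, consultation and paraclinic probabilities and the
#' admission window length were not published; this routine tunes any subset
#' of them so the simulated per-station mean waits match an observed summary.
#' Seeded random search over the free-parameter box, followed by local
#' refinement around the incumbent with shrinking steps, minimizing the sum
#' of squared *relative* errors (so short-wait stations such as registration
#' are not swamped by the hour-scale physician waits).
#'
#' @param config Starting [clinic_config()].
#' @param observed Data.frame with columns `station`, `mean` (minutes).
#' @param free_params Subset of `c("mix", "p_consult_senior", "p_paraclinic",
#'   "admission_duration")`. `"mix"` tunes the share of previously-inpatient
#'   follow-ups (novice-resident patients); the remaining mass keeps the
#'   new : follow-up-outpatient ratio of the starting config.
#' @param budget Number of candidate evaluations (0 = score the input only).
#' @param seed Root seed for both the search and the simulations.
#' @param n_reps Replications per objective evaluation.
#' @return The calibrated `clinic_config`, with attributes `objective`
#'   (achieved error), `history` (evaluated candidates) and `params` (the
#'   chosen free-parameter values).
#' @export
calibrate <- function(config, observed,
                      free_params = c("mix", "p_consult_senior",
                                      "p_paraclinic", "admission_duration"),
                      budget = 100L, seed = 1L, n_reps = 30L) {
  if (!length(free_params))
    stop("calibrate: `free_params` must not be empty", call. = FALSE)
  free_params <- match.arg(free_params, several.ok = TRUE)
  if (!length(free_params))
    stop("calibrate: `free_params` must not be empty", call. = FALSE)
  validate_clinic_config(config)

  bounds <- list(mix = c(0.02, 0.98), p_consult_senior = c(0.02, 0.98),
                 p_paraclinic = c(0.02, 0.98),
                 admission_duration = c(120, 480))
  start <- c(
    mix = config$classes$followup_prev_inpatient$mix_probability,
    p_consult_senior = config$classes$new$p_consult_senior,
    p_paraclinic = config$classes$new$p_paraclinic,
    admission_duration = config$admission_duration)
  ratio_new <- config$classes$new$mix_probability /
    max(1e-12, 1 - start[["mix"]])

  build <- function(par) {
    cfg <- config
    if ("mix" %in% names(par)) {
      m <- par[["mix"]]
      cfg$classes$followup_prev_inpatient$mix_probability <- m
      cfg$classes$new$mix_probability <- (1 - m) * ratio_new
      cfg$classes$followup_outpatient$mix_probability <-
        (1 - m) * (1 - ratio_new)
    }
    for (k in intersect(names(par), c("p_consult_senior", "p_paraclinic")))
      for (cl in names(cfg$classes)) cfg$classes[[cl]][[k]] <- par[[k]]
    if ("admission_duration" %in% names(par))
      cfg$admission_duration <- par[["admission_duration"]]
    validate_clinic_config(cfg)
    cfg
  }
  objective <- function(cfg) {
    reps <- run_replications(cfg, 0L, n_reps = n_reps, seed = seed)
    sim <- reps$station_means[observed$station]
    sum(((sim - observed$mean) / observed$mean)^2)
  }

  cur <- start[free_params]
  best_par <- cur
  best_obj <- objective(build(cur))
  history <- data.frame(t(c(cur, objective = best_obj)))
  if (budget > 0L) {
    search_seeds <- stream_seeds(seed + 7L, max(budget, 1L))
    n_explore <- ceiling(budget * 0.6)
    for (i in seq_len(budget)) {
      set.seed(search_seeds[i])
      cand <- if (i <= n_explore) {
        vapply(free_params, function(k)
          stats::runif(1, bounds[[k]][1L], bounds[[k]][2L]), numeric(1))
      } else {
        step <- 0.5^((i - n_explore) / (budget - n_explore) * 4)
        vapply(free_params, function(k) {
          w <- (bounds[[k]][2L] - bounds[[k]][1L]) * 0.25 * step
          min(bounds[[k]][2L],
              max(bounds[[k]][1L], best_par[[k]] + stats::rnorm(1, 0, w)))
        }, numeric(1))
      }
      names(cand) <- free_params
      obj <- objective(build(cand))
      history <- rbind(history, data.frame(t(c(cand, objective = obj))))
      if (obj < best_obj) {
        best_obj <- obj
        best_par <- cand
      }
    }
  }
  out <- build(best_par)
  attr(out, "objective") <- best_obj
  attr(out, "history") <- history
  attr(out, "params") <- best_par
  out
}
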