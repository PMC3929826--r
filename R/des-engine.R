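# Substream seeds: one RNG stream per stochastic source (arrivals, class mix,
# routing draws, each station's services), all derived from one root seed.
# Scenario deltas leave the draws untouched, so paired scenario comparisons
# run on common random numbers.
stream_seeds <- function(seed, n = 16L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Sample every stochastic input of one clinic day. Returns NULL inputs for an
# empty day. `n_patients` overrides the admission window (arrivals keep
# coming at the interarrival process until n_patients have been admitted).
sample_day_inputs <- function(config, seed, n_patients = NULL,
                              service_scale = NULL) {
  ss <- stream_seeds(seed)
  inter <- config$interarrival
  t0 <- config$admission_start

  set.seed(ss[1L])
  if (is.null(n_patients)) {
    horizon <- config$admission_duration
    if (horizon <= 0) return(NULL)
    m <- dist_mean(inter)
    gaps <- numeric(0)
    while (sum(gaps) <= horizon) {
      need <- ceiling((horizon - sum(gaps)) / m * 1.5) + 20L
      gaps <- c(gaps, dist_sample(inter, need))
    }
    arr <- t0 + cumsum(gaps)
    arr <- arr[arr <= t0 + horizon]
  } else {
    if (n_patients == 0L) return(NULL)
    arr <- t0 + cumsum(dist_sample(inter, n_patients))
  }
  n <- length(arr)
  if (n == 0L) return(NULL)

  cls_ids <- names(config$classes)
  mix <- vapply(config$classes, function(k) k$mix_probability, numeric(1))
  set.seed(ss[2L])
  cls <- cls_ids[sample.int(length(cls_ids), n, replace = TRUE, prob = mix)]
  p_consult <- vapply(config$classes, function(k) k$p_consult_senior, numeric(1))[cls]
  p_para <- vapply(config$classes, function(k) k$p_paraclinic, numeric(1))[cls]
  set.seed(ss[3L]); consult <- stats::runif(n) < p_consult
  set.seed(ss[4L]); para <- stats::runif(n) < p_para

  n_st <- length(STATION_IDS)
  svc <- matrix(0, n, n_st, dimnames = list(NULL, STATION_IDS))
  svc2 <- matrix(0, n, n_st)  # second physician visit after paraclinic return
  for (j in seq_len(n_st)) {
    spec <- config$stations[[STATION_IDS[j]]]$service
    if (!is.null(service_scale) && service_scale[j] != 1) {
      spec$mean <- spec$mean * service_scale[j]
      spec$sd <- spec$sd * service_scale[j]
    }
    set.seed(ss[4L + j])
    svc[, j] <- dist_sample(spec, n)
    if (config$paraclinic_return) svc2[, j] <- dist_sample(spec, n)
  }

  first_phys <- vapply(config$classes, function(k) k$first_physician,
                       character(1))[cls]
  phys_j <- match(first_phys, STATION_IDS)
  senior_j <- match("senior_staff", STATION_IDS)
  para_j <- match("paraclinic", STATION_IDS)

  route_mat <- cbind(1L, 2L, phys_j,
                     ifelse(consult, senior_j, NA_integer_),
                     ifelse(para, para_j, NA_integer_),
                     if (config$paraclinic_return)
                       ifelse(para, phys_j, NA_integer_)
                     else NA_integer_)
  svc_mat <- cbind(svc[, 1L], svc[, 2L], svc[cbind(seq_len(n), phys_j)],
                   svc[, senior_j], svc[, para_j],
                   svc2[cbind(seq_len(n), phys_j)])
  keep <- t(!is.na(route_mat))
  route <- t(route_mat)[keep]
  service <- t(svc_mat)[keep]
  route_len <- rowSums(!is.na(route_mat))

  list(n = n, arrival = arr, class = cls, route = route,
       route_len = route_len, route_off = c(0L, cumsum(route_len))[seq_len(n)],
       service = service)
}

# Run one replication; returns flat per-visit vectors (fast path used by
# run_replications). station is an integer index into STATION_IDS.
simulate_raw <- function(config, seed, n_patients = NULL,
                         service_scale = NULL) {
  inp <- sample_day_inputs(config, seed, n_patients, service_scale)
  sched <- lapply(config$stations, `[[`, "schedule")
  if (is.null(inp))
    return(list(n_patients = 0L, patient = integer(0), class = character(0),
                station = integer(0), queue_join = numeric(0),
                service_start = numeric(0), service_end = numeric(0),
                arrival = numeric(0),
                open = vapply(sched, `[[`, numeric(1), "start")))
  res <- .des_core(inp$arrival, inp$route - 1L, inp$route_off, inp$route_len,
                   inp$service,
                   vapply(sched, `[[`, numeric(1), "start"),
                   vapply(sched, `[[`, numeric(1), "end"),
                   vapply(sched, `[[`, integer(1), "n_servers"),
                   rep(config$overtime, length(sched)))
  list(n_patients = inp$n,
       patient = rep.int(seq_len(inp$n), inp$route_len),
       class = inp$class,
       station = inp$route,
       queue_join = res$queue_join,
       service_start = res$service_start,
       service_end = res$service_end,
       arrival = inp$arrival,
       open = vapply(sched, `[[`, numeric(1), "start"))
}

#' Simulate one clinic day
#'
#' Runs one replication of the clinic network: patients arrive during the
#' admission window, pass registration and the cash desk, are examined by a
#' resident (novice or experienced according to class), possibly consult the
#' senior staff physician, possibly use paraclinic services, then exit.
#' Physician queues may form before the physician's attendance start; service
#' begins only once the station opens. Deterministic given `(config, seed)`.
#'
#' @param config A [clinic_config()].
#' @param seed Integer root seed; every stochastic source gets its own
#'   substream so scenario comparisons share common random numbers.
#' @param n_patients Optional fixed number of admissions; overrides the
#'   admission window (used by the synthetic-log generator).
#' @return A `clinic_sim` object: a list with `$log` (data.frame with one row
#'   per patient-station visit: `patient_id`, `class`, `station`,
#'   `queue_join`, `service_start`, `service_end`, in minutes since
#'   midnight), `$n_patients`, and `$attendance` (station opening times).
#' @examples
#' sim <- simulate_clinic(default_base_case(), seed = 42)
#' head(sim$log)
#' station_waits(sim, "novice_resident")
#' @export
simulate_clinic <- function(config, seed, n_patients = NULL) {
  validate_clinic_config(config)
  raw <- simulate_raw(config, seed, n_patients)
  log <- data.frame(
    patient_id = raw$patient,
    class = if (raw$n_patients) raw$class[raw$patient] else character(0),
    station = if (length(raw$station)) STATION_IDS[raw$station] else character(0),
    queue_join = raw$queue_join,
    service_start = raw$service_start,
    service_end = raw$service_end,
    stringsAsFactors = FALSE
  )
  structure(list(log = log, n_patients = raw$n_patients,
                 attendance = raw$open, config = config, seed = seed),
            class = "clinic_sim")
}

#' @export
print.clinic_sim <- function(x, ...) {
  cat(sprintf("<clinic_sim: %d patients, %d station visits (seed %s)>\n",
              x$n_patients, nrow(x$log), format(x$seed)))
  invisible(x)
}

#' Split a wait around the physician's attendance start
#'
#' The queueing time at a physician station decomposes into the part accrued
#' before the physician arrives at the clinic and the part after:
#' `before = max(0, min(service_start, attendance_start) - queue_join)`,
#' `after  = max(0, service_start - max(queue_join, attendance_start))`,
#' so `before + after == service_start - queue_join` always.
#'
#' @param queue_join Time(s) the patient joined the queue (minutes).
#' @param service_start Time(s) service began; must be `>= queue_join`.
#' @param attendance_start The station's opening time.
#' @return A list with numeric components `before` and `after`.
#' @examples
#' decompose_wait(480, 630, 600)  # list(before = 120, after = 30)
#' @export
decompose_wait <- function(queue_join, service_start, attendance_start) {
  stopifnot(all(service_start >= queue_join, na.rm = TRUE))
  before <- pmax(0, pmin(service_start, attendance_start) - queue_join)
  after <- pmax(0, service_start - pmax(queue_join, attendance_start))
  list(before = before, after = after)
}

#' Mean waiting time at a station
#'
#' @param sim A `clinic_sim` from [simulate_clinic()].
#' @param station_id A station id.
#' @return Arithmetic mean over patients of `service_start - queue_join` at
#'   the station, in minutes; `NA` (flagged empty, not 0) if no patient
#'   visited the station.
#' @export
station_waits <- function(sim, station_id) {
  station_id <- match.arg(station_id, STATION_IDS)
  rows <- sim$log$station == station_id & !is.na(sim$log$service_start)
  if (!any(rows)) return(NA_real_)
  mean(sim$log$service_start[rows] - sim$log$queue_join[rows])
}

# Per-replication summaries on the raw (flat-vector) result: mean wait per
# station, and the before/after decomposition at the physician stations.
summarize_raw <- function(raw) {
  n_st <- length(STATION_IDS)
  wait_mean <- rep(NA_real_, n_st)
  before_mean <- rep(NA_real_, n_st)
  after_mean <- rep(NA_real_, n_st)
  if (length(raw$station)) {
    ok <- !is.na(raw$service_start)
    st <- raw$station[ok]
    wait <- raw$service_start[ok] - raw$queue_join[ok]
    cnt <- tabulate(st, n_st)
    sums <- unname(rowsum(wait, st)[, 1L])
    wait_mean[sort(unique(st))] <- sums / cnt[cnt > 0]
    for (j in match(PHYSICIAN_IDS, STATION_IDS)) {
      rows <- st == j
      if (!any(rows)) next
      d <- decompose_wait(raw$queue_join[ok][rows],
                          raw$service_start[ok][rows], raw$open[j])
      before_mean[j] <- mean(d$before)
      after_mean[j] <- mean(d$after)
    }
  }
  names(wait_mean) <- names(before_mean) <- names(after_mean) <- STATION_IDS
  list(wait = wait_mean, before = before_mean, after = after_mean,
       n_patients = raw$n_patients)
}

# ---- event-log I/O and checking --------------------------------------------

#' Write a patient event log to CSV
#'
#' One row per patient-station visit, columns `patient_id`, `class`,
#' `station`, `queue_join`, `service_start`, `service_end`
#' (minutes since midnight, 3 decimals).
#'
#' @param log A log data.frame (from [simulate_clinic()]'s `$log` or
#'   [generate_patient_log()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  out <- log
  for (col in c("queue_join", "service_start", "service_end"))
    out[[col]] <- sprintf("%.3f", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a patient event log from CSV
#'
#' @param path CSV path in the [write_event_log()] schema.
#' @return A log data.frame.
#' @export
read_event_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "integer",
                                        class = "character",
                                        station = "character",
                                        queue_join = "numeric",
                                        service_start = "numeric",
                                        service_end = "numeric"))
  needed <- c("patient_id", "class", "station", "queue_join",
              "service_start", "service_end")
  missing <- setdiff(needed, names(log))
  if (length(missing))
    stop("read_event_log: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  log
}

#' Check an event log against the engine's structural invariants
#'
#' Verifies, independently of the simulation core, that a log is internally
#' consistent: causality (`queue_join <= service_start <= service_end` on
#' every visit) and the FIFO discipline within each station (service order
#' equals queue-join order, ties by patient id).
#'
#' @param log A log data.frame.
#' @return `TRUE` if the log is consistent, otherwise a character vector
#'   describing each violation.
#' @export
check_event_log <- function(log) {
  problems <- character(0)
  bad <- log$queue_join > log$service_start | log$service_start > log$service_end
  if (any(bad, na.rm = TRUE))
    problems <- c(problems, sprintf(
      "causality violated on %d visit(s)", sum(bad, na.rm = TRUE)))
  for (st in unique(log$station)) {
    rows <- log[log$station == st & !is.na(log$service_start), , drop = FALSE]
    if (nrow(rows) < 2L) next
    o <- order(rows$queue_join, rows$patient_id)
    if (is.unsorted(rows$service_start[o]))
      problems <- c(problems, sprintf("FIFO violated at station %s", st))
  }
  if (length(problems)) problems else TRUE
}
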