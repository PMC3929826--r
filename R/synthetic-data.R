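#' Parameters for the synthetic event-log generator
#'
#' The generator stands in for the study's checklist of 375 observed
#' patients: it runs the simulation engine once and emits the per-patient,
#' per-station timestamps, so synthetic "observed" logs are internally
#' consistent (waits arise from congestion and schedules, not drawn i.i.d.).
#' Defaults equal [default_base_case()] exactly.
#'
#' @param config A [clinic_config()]; defaults to [default_base_case()].
#' @param n_patients Number of admitted patients (default 375, the study's
#'   checklist size). `NULL` lets the admission window decide.
#' @param seed Root seed.
#' @param service_scale Optional multiplicative perturbation of the service
#'   scale, one value per station (recycled); values other than 1 produce
#'   logs the unperturbed config cannot fit, to exercise the rejection path
#'   of [validate_waits()].
#' @return A `generator_params` list.
#' @export
generator_params <- function(config = default_base_case(), n_patients = 375L,
                             seed = 1L, service_scale = 1) {
  validate_clinic_config(config)
  if (!is.null(n_patients) && n_patients < 0)
    stop("generator_params: `n_patients` must be >= 0", call. = FALSE)
  structure(list(config = config,
                 n_patients = if (is.null(n_patients)) NULL
                              else as.integer(n_patients),
                 seed = as.integer(seed),
                 service_scale = rep_len(service_scale,
                                         length(STATION_IDS))),
            class = "generator_params")
}

#' Generate a synthetic patient event log
#'
#' @param params A [generator_params()] (a bare [clinic_config()] is also
#'   accepted and wrapped with defaults).
#' @param path Optional CSV path; if given the log is also written with
#'   [write_event_log()].
#' @return The event-log data.frame (zero rows, header only, when
#'   `n_patients = 0`). Deterministic given the seed; writing the same
#'   parameters twice yields byte-identical CSVs.
#' @examples
#' log <- generate_patient_log(generator_params(n_patients = 50, seed = 7))
#' nrow(log) >= 150  # >= 3 visits per patient
#' @export
generate_patient_log <- function(params, path = NULL) {
  if (inherits(params, "clinic_config")) params <- generator_params(params)
  stopifnot(inherits(params, "generator_params"))
  raw <- simulate_raw(params$config, params$seed,
                      n_patients = params$n_patients,
                      service_scale = params$service_scale)
  log <- data.frame(
    patient_id = raw$patient,
    class = if (raw$n_patients) raw$class[raw$patient] else character(0),
    station = if (length(raw$station)) STATION_IDS[raw$station] else character(0),
    queue_join = raw$queue_join,
    service_start = raw$service_start,
    service_end = raw$service_end,
    stringsAsFactors = FALSE)
  if (!is.null(path)) write_event_log(log, path)
  log
}

#' Summarize an event log into a per-station observed-waits table
#'
#' Produces the summary schema consumed by [validate_waits()] and
#' [calibrate()]: one row per visited station with the mean, standard
#' deviation and count of the waits (`service_start - queue_join`).
#'
#' @param log A non-empty event-log data.frame.
#' @return Data.frame with columns `station`, `mean`, `sd`, `n`.
#' @export
generate_observed_summary <- function(log) {
  if (!nrow(log))
    stop("generate_observed_summary: empty log", call. = FALSE)
  ok <- !is.na(log$service_start)
  wait <- log$service_start[ok] - log$queue_join[ok]
  st <- log$station[ok]
  agg <- vapply(split(wait, st), function(w)
    c(mean(w), if (length(w) > 1L) stats::sd(w) else 0, length(w)),
    numeric(3))
  out <- data.frame(station = colnames(agg), mean = agg[1L, ],
                    sd = agg[2L, ], n = as.integer(agg[3L, ]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(match(out$station, STATION_IDS)), , drop = FALSE]
}
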