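#' @useDynLib clinicflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical station and patient-class identifiers. Order matters: it is the
# station index used by the simulation core.
STATION_IDS <- c("registration", "cash", "novice_resident",
                 "experienced_resident", "senior_staff", "paraclinic")
PHYSICIAN_IDS <- c("novice_resident", "experienced_resident", "senior_staff")
CLASS_IDS <- c("new", "followup_outpatient", "followup_prev_inpatient")

#' Server schedule
#'
#' @param start Opening time in minutes since midnight (e.g. 600 = 10:00).
#' @param duration Scheduled length of attendance in minutes.
#' @param n_servers Number of parallel servers (physicians, desks).
#' @return A `server_schedule` list with an `end` field (`start + duration`).
#' @export
server_schedule <- function(start, duration, n_servers = 1L) {
  if (!is.numeric(duration) || duration < 0)
    stop("server_schedule: `duration` must be >= 0", call. = FALSE)
  if (!is.numeric(n_servers) || n_servers < 1)
    stop("server_schedule: `n_servers` must be >= 1", call. = FALSE)
  structure(list(start = as.numeric(start), duration = as.numeric(duration),
                 n_servers = as.integer(n_servers),
                 end = as.numeric(start + duration)),
            class = "server_schedule")
}

#' Service station
#'
#' @param id One of `r paste0('"', STATION_IDS, '"', collapse = ", ")`.
#' @param schedule A [server_schedule()].
#' @param service A [dist_spec()] for the service time.
#' @param discipline Queue discipline; only `"fifo"` is supported.
#' @return A `station` object.
#' @export
station <- function(id, schedule, service, discipline = "fifo") {
  id <- match.arg(id, STATION_IDS)
  stopifnot(inherits(schedule, "server_schedule"), inherits(service, "dist_spec"))
  if (!identical(discipline, "fifo"))
    stop("station: only the 'fifo' discipline is supported", call. = FALSE)
  structure(list(id = id, schedule = schedule, service = service,
                 discipline = discipline), class = "station")
}

#' Patient class
#'
#' Patient classes differ in which resident examines them first (previously
#' admitted inpatients are seen by novice residents, new and follow-up
#' outpatients by experienced residents), and in their routing probabilities.
#'
#' @param id One of `"new"`, `"followup_outpatient"`, `"followup_prev_inpatient"`.
#' @param mix_probability Fraction of arriving patients in this class.
#' @param first_physician Station id of the first examining physician.
#' @param p_consult_senior Probability the resident refers the patient to the
#'   senior staff physician after the examination.
#' @param p_paraclinic Probability the patient needs paraclinic services
#'   (imaging, lab) after the physician stage.
#' @return A `patient_class` object.
#' @export
patient_class <- function(id, mix_probability, first_physician,
                          p_consult_senior = 0.25, p_paraclinic = 0.3) {
  id <- match.arg(id, CLASS_IDS)
  first_physician <- match.arg(first_physician,
                               c("novice_resident", "experienced_resident"))
  for (nm in c("mix_probability", "p_consult_senior", "p_paraclinic")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("patient_class: `", nm, "` must be a probability in [0, 1]",
           call. = FALSE)
  }
  structure(list(id = id, mix_probability = mix_probability,
                 first_physician = first_physician,
                 p_consult_senior = p_consult_senior,
                 p_paraclinic = p_paraclinic), class = "patient_class")
}

#' Clinic configuration
#'
#' The full parameterization of the clinic network: one entry per station,
#' the patient-class mix and routing, the interarrival process, the admission
#' window, the weighted-mean weights, and run options.
#'
#' @param stations Named list of [station()] objects, one per station id.
#' @param classes Named list of [patient_class()] objects; mix probabilities
#'   must sum to 1.
#' @param interarrival A [dist_spec()] for patient interarrival times.
#' @param admission_start Minutes since midnight when patient admission opens.
#' @param admission_duration Length of the admission window in minutes.
#' @param weights Named weights over the physician stations used by the
#'   weighted-mean waiting-time score.
#' @param n_reps Default number of replications for summaries.
#' @param overtime If `TRUE` (default) servers finish every queued patient
#'   after the scheduled end; if `FALSE` no service may start after the end
#'   (in-progress services always complete).
#' @param paraclinic_return If `TRUE` paraclinic patients return to their
#'   first physician afterwards; default `FALSE` (exit after paraclinic).
#' @return A validated `clinic_config` object.
#' @seealso [default_base_case()], [load_config()], [save_config()]
#' @export
clinic_config <- function(stations, classes, interarrival,
                          admission_start = 450, admission_duration = 240,
                          weights = c(novice_resident = 2,
                                      experienced_resident = 2,
                                      senior_staff = 1),
                          n_reps = 1000L, overtime = TRUE,
                          paraclinic_return = FALSE) {
  cfg <- structure(list(stations = stations, classes = classes,
                        interarrival = interarrival,
                        admission_start = as.numeric(admission_start),
                        admission_duration = as.numeric(admission_duration),
                        weights = weights, n_reps = as.integer(n_reps),
                        overtime = isTRUE(overtime),
                        paraclinic_return = isTRUE(paraclinic_return)),
                   class = "clinic_config")
  validate_clinic_config(cfg)
}

#' Validate a clinic configuration
#'
#' Checks every structural invariant (station set, class mix summing to 1,
#' probability ranges, schedule sanity, positive weights) and returns the
#' config invisibly; violations raise an error naming the offending field.
#'
#' @param config A `clinic_config`.
#' @return The config, invisibly, if valid.
#' @export
validate_clinic_config <- function(config) {
  if (!inherits(config, "clinic_config"))
    stop("not a clinic_config object", call. = FALSE)
  ids <- vapply(config$stations, function(s) s$id, character(1))
  if (!setequal(ids, STATION_IDS) || anyDuplicated(ids))
    stop("clinic_config: `stations` must contain each station id exactly ",
         "once; got {", paste(ids, collapse = ", "), "}", call. = FALSE)
  if (!identical(names(config$stations), unname(ids)))
    names(config$stations) <- ids
  for (s in config$stations) {
    if (!inherits(s$service, "dist_spec"))
      stop("clinic_config: station `", s$id, "` has no service dist_spec",
           call. = FALSE)
    if (s$schedule$duration <= 0)
      stop("clinic_config: station `", s$id, "`: schedule `duration` must ",
           "be > 0", call. = FALSE)
  }
  cls_ids <- vapply(config$classes, function(k) k$id, character(1))
  if (anyDuplicated(cls_ids))
    stop("clinic_config: duplicated patient class ids", call. = FALSE)
  names(config$classes) <- cls_ids
  mix <- vapply(config$classes, function(k) k$mix_probability, numeric(1))
  if (abs(sum(mix) - 1) > 1e-8)
    stop("clinic_config: class `mix_probability` values must sum to 1 (got ",
         format(sum(mix)), ")", call. = FALSE)
  if (!inherits(config$interarrival, "dist_spec"))
    stop("clinic_config: `interarrival` must be a dist_spec", call. = FALSE)
  if (config$admission_duration < 0)
    stop("clinic_config: `admission_duration` must be >= 0", call. = FALSE)
  w <- config$weights
  if (is.null(names(w)) || !all(names(w) %in% STATION_IDS))
    stop("clinic_config: `weights` must be named by physician station ids",
         call. = FALSE)
  if (any(w <= 0))
    stop("clinic_config: `weights` must be > 0", call. = FALSE)
  if (config$n_reps < 1)
    stop("clinic_config: `n_reps` must be >= 1", call. = FALSE)
  invisible(config)
}

#' The base-case clinic configuration
#'
#' Returns the current-state parameterization of the orthopedic outpatient
#' clinic: normal interarrival times (mean 4.2, SD 5.8 min) with negative
#' draws clipped to zero (simultaneous arrivals; see [dist_spec()] — the
#' conditional `truncated_normal` family is available per config), lognormal
#' service times moment-matched to the observed
#' means/SDs (registration 1.13/0.44, cash 0.20/0.3, novice resident
#' 3.46/2.06, experienced resident 4.91/0.93, senior staff 4.20/0.93 minutes),
#' admission opening at 07:30, residents attending from 10:00 for 200 min
#' (2 novice, 1 experienced), the senior staff physician from 10:45 for
#' 100 min, and score weights 2:2:1 (novice, experienced, senior).
#'
#' The patient-class mix and the consultation/paraclinic routing
#' probabilities were not published; the defaults here are calibration
#' targets (see [calibrate()]) rather than observed values, as are the
#' paraclinic service parameters and the admission window length.
#'
#' @param mix Length-3 class mix over (new, follow-up outpatient, previously
#'   inpatient follow-up); must sum to 1.
#' @param p_consult_senior Probability of referral to the senior staff
#'   physician after the resident examination (all classes).
#' @param p_paraclinic Probability of needing paraclinic services (all
#'   classes).
#' @param admission_duration Admission window length in minutes.
#' @return A validated [clinic_config()].
#' @examples
#' cfg <- default_base_case()
#' cfg$stations$novice_resident$service$mean   # 3.46
#' cfg$stations$registration$schedule$start    # 450 (= 07:30)
#' @export
default_base_case <- function(mix = c(new = 0.4, followup_outpatient = 0.3,
                                      followup_prev_inpatient = 0.3),
                              p_consult_senior = 0.25, p_paraclinic = 0.3,
                              admission_duration = 240) {
  all_day <- 600  # support stations stay open through the clinic day
  st <- list(
    registration = station("registration",
      server_schedule(450, all_day, 1L),
      dist_spec("lognormal", mean = 1.13, sd = 0.44)),
    cash = station("cash",
      server_schedule(450, all_day, 1L),
      dist_spec("lognormal", mean = 0.20, sd = 0.3)),
    novice_resident = station("novice_resident",
      server_schedule(600, 200, 2L),
      dist_spec("lognormal", mean = 3.46, sd = 2.06)),
    experienced_resident = station("experienced_resident",
      server_schedule(600, 200, 1L),
      dist_spec("lognormal", mean = 4.91, sd = 0.93)),
    senior_staff = station("senior_staff",
      server_schedule(645, 100, 1L),
      dist_spec("lognormal", mean = 4.20, sd = 0.93)),
    paraclinic = station("paraclinic",
      server_schedule(450, all_day, 1L),
      dist_spec("lognormal", mean = 12, sd = 8))
  )
  first_phys <- c(new = "experienced_resident",
                  followup_outpatient = "experienced_resident",
                  followup_prev_inpatient = "novice_resident")
  cls <- lapply(CLASS_IDS, function(id)
    patient_class(id, unname(mix[id]), first_phys[[id]],
                  p_consult_senior = p_consult_senior,
                  p_paraclinic = p_paraclinic))
  names(cls) <- CLASS_IDS
  clinic_config(stations = st, classes = cls,
                interarrival = dist_spec("clipped_normal", 4.2, 5.8),
                admission_start = 450,
                admission_duration = admission_duration)
}

#' The calibrated base-case configuration
#'
#' [default_base_case()] with the unpublished parameters (class mix,
#' consultation and paraclinic probabilities, admission window) replaced by
#' the shipped calibration result: one frozen [calibrate()] run against the
#' observed per-station mean waits ([observed_station_summary()]), random
#' search budget 2000, 100 replications per evaluation, seed 42. See the
#' methods vignette for what this calibration can and cannot reproduce.
#'
#' @return A validated [clinic_config()].
#' @export
calibrated_base_case <- function() {
  load_config(system.file("configs", "calibrated_base_case.yaml",
                          package = "clinicflow"))
}

#' @export
print.clinic_config <- function(x, ...) {
  cat("<clinic_config>\n")
  cat(sprintf("  admission: %s + %g min, interarrival %s(%g, %g)\n",
              fmt_clock(x$admission_start), x$admission_duration,
              x$interarrival$family, x$interarrival$mean, x$interarrival$sd))
  for (s in x$stations)
    cat(sprintf("  %-21s %d server(s) %s-%s  service %s(%g, %g)\n", s$id,
                s$schedule$n_servers, fmt_clock(s$schedule$start),
                fmt_clock(s$schedule$end), s$service$family, s$service$mean,
                s$service$sd))
  mix <- vapply(x$classes, function(k) k$mix_probability, numeric(1))
  cat("  class mix:", paste(sprintf("%s=%.3g", names(mix), mix),
                            collapse = ", "), "\n")
  invisible(x)
}

fmt_clock <- function(m) sprintf("%02d:%02d", floor(m / 60) %% 24,
                                 round(m %% 60))

# ---- configuration file I/O -------------------------------------------------

dist_to_list <- function(d) list(family = d$family, mean = d$mean, sd = d$sd,
                                 lower = d$lower)
dist_from_list <- function(x, field) {
  check_keys(x, c("family", "mean", "sd", "lower"), field,
             required = c("family", "mean"))
  dist_spec(x$family, x$mean, x$sd %||% 0, x$lower %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(x, allowed, field, required = allowed) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("config: unknown key(s) in `", field, "`: ",
         paste(extra, collapse = ", "), call. = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("config: `", field, "` is missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(x)
}

config_to_list <- function(config) {
  list(
    stations = lapply(config$stations, function(s) list(
      schedule = list(start = s$schedule$start,
                      duration = s$schedule$duration,
                      n_servers = s$schedule$n_servers),
      service = dist_to_list(s$service),
      discipline = s$discipline)),
    classes = lapply(config$classes, function(k) list(
      mix_probability = k$mix_probability,
      first_physician = k$first_physician,
      p_consult_senior = k$p_consult_senior,
      p_paraclinic = k$p_paraclinic)),
    interarrival = dist_to_list(config$interarrival),
    admission_start = config$admission_start,
    admission_duration = config$admission_duration,
    weights = as.list(config$weights),
    n_reps = config$n_reps,
    overtime = config$overtime,
    paraclinic_return = config$paraclinic_return
  )
}

config_from_list <- function(x) {
  check_keys(x, c("stations", "classes", "interarrival", "admission_start",
                  "admission_duration", "weights", "n_reps", "overtime",
                  "paraclinic_return"),
             "clinic_config",
             required = c("stations", "classes", "interarrival"))
  stations <- lapply(names(x$stations), function(id) {
    s <- x$stations[[id]]
    check_keys(s, c("schedule", "service", "discipline"), paste0("stations.", id),
               required = c("schedule", "service"))
    check_keys(s$schedule, c("start", "duration", "n_servers"),
               paste0("stations.", id, ".schedule"))
    station(id,
            server_schedule(s$schedule$start, s$schedule$duration,
                            s$schedule$n_servers),
            dist_from_list(s$service, paste0("stations.", id, ".service")),
            s$discipline %||% "fifo")
  })
  names(stations) <- names(x$stations)
  classes <- lapply(names(x$classes), function(id) {
    k <- x$classes[[id]]
    check_keys(k, c("mix_probability", "first_physician", "p_consult_senior",
                    "p_paraclinic"), paste0("classes.", id),
               required = c("mix_probability", "first_physician"))
    patient_class(id, k$mix_probability, k$first_physician,
                  k$p_consult_senior %||% 0.25, k$p_paraclinic %||% 0.3)
  })
  names(classes) <- names(x$classes)
  clinic_config(stations = stations, classes = classes,
                interarrival = dist_from_list(x$interarrival, "interarrival"),
                admission_start = x$admission_start %||% 450,
                admission_duration = x$admission_duration %||% 240,
                weights = unlist(x$weights %||%
                                   list(novice_resident = 2,
                                        experienced_resident = 2,
                                        senior_staff = 1)),
                n_reps = x$n_reps %||% 1000L,
                overtime = x$overtime %||% TRUE,
                paraclinic_return = x$paraclinic_return %||% FALSE)
}

#' Read a clinic configuration file
#'
#' Reads a YAML (or JSON) clinic configuration, validates every invariant and
#' returns the [clinic_config()]. Unknown keys are rejected with an error
#' naming the field, as are invariant violations (e.g. a class mix that does
#' not sum to 1).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated `clinic_config`.
#' @examples
#' cfg <- load_config(system.file("configs", "base_case.yaml",
#'                                package = "clinicflow"))
#' cfg$interarrival$mean  # 4.2
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("load_config: no such file: ", path, call. = FALSE)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else
    yaml::read_yaml(path)
  config_from_list(x)
}

#' Write a clinic configuration file
#'
#' The written file round-trips: `load_config(save_config(cfg, path))`
#' reproduces `cfg` exactly.
#'
#' @param config A `clinic_config`.
#' @param path Output path; format chosen by extension (`.json` for JSON,
#'   anything else is YAML).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  validate_clinic_config(config)
  x <- config_to_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}
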