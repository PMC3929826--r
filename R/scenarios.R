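# The ten waiting-time-reduction scenarios, encoded as data: each is a list
# of (field-path, value) deltas on a clinic_config. Composites are unions of
# their components' deltas, so composition is order-independent.
scenario_deltas <- function() {
  s1 <- list("stations.novice_resident.schedule.n_servers" = 3L)
  s2 <- list("stations.experienced_resident.schedule.n_servers" = 2L)
  s3 <- list("stations.novice_resident.schedule.start" = 540,
             "stations.novice_resident.schedule.duration" = 260,
             "stations.experienced_resident.schedule.start" = 540,
             "stations.experienced_resident.schedule.duration" = 260)
  s4 <- list("stations.senior_staff.schedule.start" = 600,
             "stations.senior_staff.schedule.duration" = 160)
  s5 <- list("admission_start" = 480)
  list(`0` = list(), `1` = s1, `2` = s2, `3` = s3, `4` = s4, `5` = s5,
       `6` = c(s1, s2), `7` = c(s3, s4), `8` = c(s1, s2, s5),
       `9` = c(s3, s4, s5), `10` = c(s1, s2, s3, s4))
}

scenario_labels <- c(
  `0` = "Base case (current state)",
  `1` = "Novice residents 2 -> 3",
  `2` = "Experienced residents 1 -> 2",
  `3` = "Residents attend 10:00 -> 09:00, 200 -> 260 min",
  `4` = "Senior staff attends 10:45 -> 10:00, 100 -> 160 min",
  `5` = "Admission start 07:30 -> 08:00",
  `6` = "Mix of scenarios 1 and 2",
  `7` = "Mix of scenarios 3 and 4",
  `8` = "Mix of scenarios 1, 2 and 5",
  `9` = "Mix of scenarios 3, 4 and 5",
  `10` = "Mix of scenarios 1, 2, 3 and 4")

#' Retrieve one of the built-in what-if scenarios
#'
#' Scenario 0 is the base case (empty delta list). Scenarios 1-5 are the
#' elementary changes (one more novice resident; one more experienced
#' resident; residents attending from 09:00 for 260 min instead of 10:00 for
#' 200; the senior staff physician attending from 10:00 for 160 min instead
#' of 10:45 for 100; admission opening at 08:00 instead of 07:30) and 6-10
#' their combinations (6 = 1+2, 7 = 3+4, 8 = 1+2+5, 9 = 3+4+5, 10 = 1+2+3+4).
#'
#' @param id Integer scenario id in `0:10`.
#' @return A `scenario` object: list with `id`, `label` and `deltas` (a named
#'   list mapping dotted config field paths to new values).
#' @examples
#' get_scenario(3)$deltas[["stations.novice_resident.schedule.duration"]]  # 260
#' @export
get_scenario <- function(id) {
  if (inherits(id, "scenario")) return(id)
  if (length(id) != 1L || is.na(id) || id %% 1 != 0 || id < 0 || id > 10)
    stop("get_scenario: unknown scenario id: ", format(id), call. = FALSE)
  key <- as.character(as.integer(id))
  new_scenario(as.integer(id), scenario_labels[[key]], scenario_deltas()[[key]])
}

new_scenario <- function(id, label, deltas) {
  structure(list(id = id, label = label, deltas = deltas), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario %d: %s>\n", x$id, x$label))
  for (p in names(x$deltas)) cat("  ", p, " = ", format(x$deltas[[p]]), "\n",
                                 sep = "")
  invisible(x)
}

#' Load scenario definitions from a file
#'
#' Reads a YAML (or JSON) file of scenario definitions in the schema of the
#' bundled `configs/scenarios.yaml`: a list of entries with `id`, `label` and
#' a `deltas` map from dotted config paths to values. Users can define new
#' scenarios in the same schema.
#'
#' @param path Path to a scenario file; defaults to the bundled definitions.
#' @return A list of `scenario` objects named by id.
#' @export
load_scenarios <- function(path = system.file("configs", "scenarios.yaml",
                                              package = "clinicflow")) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else
    yaml::read_yaml(path)
  out <- lapply(x, function(s) {
    check_keys(s, c("id", "label", "deltas"), "scenario",
               required = c("id", "deltas"))
    new_scenario(as.integer(s$id), s$label %||% paste("scenario", s$id),
                 as.list(s$deltas))
  })
  names(out) <- vapply(out, function(s) as.character(s$id), character(1))
  out
}

set_config_path <- function(config, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  rec <- function(node, parts, trail) {
    key <- parts[1L]
    if (is.null(node[[key]]))
      stop("apply_scenario: delta path not found in config: ",
           paste(c(trail, key), collapse = "."), call. = FALSE)
    if (length(parts) == 1L) {
      node[[key]] <- if (is.integer(node[[key]])) as.integer(value)
                     else value
    } else {
      node[[key]] <- rec(node[[key]], parts[-1L], c(trail, key))
    }
    node
  }
  rec(config, parts, character(0))
}

#' Apply a scenario's deltas to a clinic configuration
#'
#' Returns a new, revalidated configuration; the input is untouched. Station
#' schedule `end` times are recomputed after the deltas. Applying scenario 0
#' returns an equal configuration.
#'
#' @param config A [clinic_config()].
#' @param scenario A `scenario` object or an id accepted by [get_scenario()].
#' @return The modified `clinic_config`.
#' @examples
#' cfg <- apply_scenario(default_base_case(), 1)
#' cfg$stations$novice_resident$schedule$n_servers  # 3
#' @export
apply_scenario <- function(config, scenario) {
  validate_clinic_config(config)
  scenario <- get_scenario(scenario)
  out <- unclass(config)
  for (p in names(scenario$deltas))
    out <- set_config_path(out, p, scenario$deltas[[p]])
  for (s in names(out$stations)) {
    sch <- out$stations[[s]]$schedule
    out$stations[[s]]$schedule <- server_schedule(sch$start, sch$duration,
                                                  sch$n_servers)
  }
  class(out) <- "clinic_config"
  validate_clinic_config(out)
  out
}
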