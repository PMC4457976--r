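#' Define a repricing scenario
#'
#' A scenario is the package's dynamic cost-estimate mechanism: a pure,
#' declarative perturbation of the inputs — salary/price changes as
#' expenditure multipliers, demand changes as volume multipliers, revised
#' service protocols as workload overrides, newly added services with their
#' expected volumes, a changed government allocation, or population growth.
#' Applying a scenario never modifies its inputs; repricing is re-running
#' [cost_report()] on the transformed data.
#'
#' @param name Scenario label.
#' @param expenditure_multipliers Named numeric, names among
#'   `human_resources`, `materials`, `public_funds`; all factors > 0.
#' @param volume_multipliers Named numeric; names are service ids or
#'   measured category labels; factors > 0.
#' @param workload_overrides Data frame with columns `service_id`,
#'   `stratum`, `workload` (person-minutes, > 0).
#' @param added_services List of entries, each a list with `service` (the
#'   catalog fields `service_id`, `name`, `category`, `delivery_unit`, and
#'   a `workload` map stratum -> person-minutes) and `volume` (a map
#'   stratum -> expected annual volume, distributed across that stratum's
#'   facilities proportionally to population served).
#' @param allocation_per_capita Scenario allocation, USD/person (optional).
#' @param population_multiplier Factor applied to every facility's
#'   population served; > 0.
#' @return An object of class `ev_scenario`.
#' @seealso [apply_scenario()], [read_scenario()], [incremental_cost()]
#' @export
#' @examples
#' scenario("salaries +10%",
#'          expenditure_multipliers = c(human_resources = 1.1))
scenario <- function(name = "scenario",
                     expenditure_multipliers = NULL,
                     volume_multipliers = NULL,
                     workload_overrides = NULL,
                     added_services = NULL,
                     allocation_per_capita = NULL,
                     population_multiplier = 1) {
  check_factors <- function(x, what, allowed_names = NULL) {
    if (is.null(x)) return(NULL)
    x <- unlist(x)
    if (is.null(names(x)) || any(names(x) == "")) {
      ev_abort(sprintf("`%s` must be a named numeric vector.", what),
               "evcost_error_type")
    }
    if (any(!is.finite(x) | x <= 0)) {
      ev_abort(sprintf("All `%s` factors must be > 0.", what),
               "evcost_error_domain")
    }
    if (!is.null(allowed_names)) {
      bad <- setdiff(names(x), allowed_names)
      if (length(bad) > 0) {
        ev_abort(sprintf("Unknown %s name(s): %s.", what,
                         paste(bad, collapse = ", ")),
                 "evcost_error_schema")
      }
    }
    x
  }
  expenditure_multipliers <- check_factors(
    expenditure_multipliers, "expenditure_multipliers",
    expenditure_categories()
  )
  volume_multipliers <- check_factors(volume_multipliers,
                                      "volume_multipliers")
  if (!is.null(workload_overrides)) {
    workload_overrides <- tibble::as_tibble(workload_overrides)
    ev_require_columns(workload_overrides,
                       c("service_id", "stratum", "workload"),
                       "workload_overrides")
    if (any(workload_overrides$workload <= 0)) {
      ev_abort("Workload overrides must be > 0 person-minutes.",
               "evcost_error_domain")
    }
  }
  ev_stopifnot_scalar_number(population_multiplier, "population_multiplier",
                             positive = TRUE)
  if (!is.null(allocation_per_capita)) {
    ev_stopifnot_scalar_number(allocation_per_capita,
                               "allocation_per_capita", nonnegative = TRUE)
  }
  structure(
    list(name = name,
         expenditure_multipliers = expenditure_multipliers,
         volume_multipliers = volume_multipliers,
         workload_overrides = workload_overrides,
         added_services = added_services,
         allocation_per_capita = allocation_per_capita,
         population_multiplier = population_multiplier),
    class = "ev_scenario"
  )
}

#' @export
print.ev_scenario <- function(x, ...) {
  cat(sprintf("<ev_scenario> %s\n", x$name))
  if (!is.null(x$expenditure_multipliers)) {
    cat("  expenditure:",
        paste(sprintf("%s x%g", names(x$expenditure_multipliers),
                      x$expenditure_multipliers), collapse = ", "), "\n")
  }
  if (!is.null(x$volume_multipliers)) {
    cat("  volumes:",
        paste(sprintf("%s x%g", names(x$volume_multipliers),
                      x$volume_multipliers), collapse = ", "), "\n")
  }
  if (!is.null(x$workload_overrides)) {
    cat(sprintf("  %d workload override(s)\n", nrow(x$workload_overrides)))
  }
  if (length(x$added_services) > 0) {
    cat(sprintf("  %d added service(s)\n", length(x$added_services)))
  }
  if (!is.null(x$allocation_per_capita)) {
    cat(sprintf("  allocation: %g USD/person\n", x$allocation_per_capita))
  }
  if (x$population_multiplier != 1) {
    cat(sprintf("  population x%g\n", x$population_multiplier))
  }
  invisible(x)
}

#' Read a scenario from YAML or JSON
#'
#' Recognized keys: `name`, `expenditure_multipliers`,
#' `volume_multipliers`, `workload_overrides` (list of
#' `{service_id, stratum, workload}`), `added_services`,
#' `allocation_per_capita`, `population_multiplier`.
#'
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @param format `"auto"`, `"yaml"`, or `"json"`.
#' @return An `ev_scenario`.
#' @export
read_scenario <- function(path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (format == "auto") format <- ev_guess_format(path)
  x <- if (format == "yaml") yaml::read_yaml(path) else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  overrides <- NULL
  if (!is.null(x$workload_overrides)) {
    overrides <- purrr::map_dfr(x$workload_overrides, tibble::as_tibble)
  }
  scenario(
    name = x$name %||% basename(path),
    expenditure_multipliers = x$expenditure_multipliers,
    volume_multipliers = x$volume_multipliers,
    workload_overrides = overrides,
    added_services = x$added_services,
    allocation_per_capita = x$allocation_per_capita,
    population_multiplier = x$population_multiplier %||% 1
  )
}

#' Apply a scenario to a panel and catalog
#'
#' Pure transformation: returns perturbed copies, leaving the inputs
#' untouched. Expenditure and population multipliers scale the facility
#' table componentwise; volume multipliers scale the volumes of a named
#' service or of every service in a named category; workload overrides
#' rewrite catalog entries; added services are appended to the catalog and
#' their expected stratum volumes are distributed across that stratum's
#' facilities proportionally to population served. The other-services
#' uplift share is deliberately not a scenario field: it came from
#' provider interviews, not from the perturbed quantities, so it stays
#' fixed unless changed explicitly at costing time.
#'
#' @param panel An `ev_facility_panel`.
#' @param cat An `ev_catalog`.
#' @param scn An `ev_scenario`.
#' @return A list with elements `panel` and `catalog`.
#' @export
apply_scenario <- function(panel, cat, scn) {
  if (!inherits(scn, "ev_scenario")) {
    ev_abort("`scn` must be an ev_scenario.", "evcost_error_type")
  }
  validate_panel(panel, cat)
  fac <- panel$facilities
  vol <- panel$volumes
  services <- cat$services

  for (nm in names(scn$expenditure_multipliers)) {
    col <- paste0("exp_", nm)
    fac[[col]] <- fac[[col]] * scn$expenditure_multipliers[[nm]]
  }
  fac$population_served <- fac$population_served * scn$population_multiplier

  if (!is.null(scn$volume_multipliers)) {
    svc_cat <- stats::setNames(services$category, services$service_id)
    for (nm in names(scn$volume_multipliers)) {
      k <- scn$volume_multipliers[[nm]]
      if (nm %in% ev_measured_categories()) {
        hit <- vol$service_id %in% names(svc_cat)[svc_cat == nm]
      } else if (nm %in% services$service_id) {
        hit <- vol$service_id == nm
      } else {
        ev_abort(sprintf(
          "Volume multiplier '%s' is neither a service id nor a category.",
          nm
        ), "evcost_error_schema")
      }
      vol$volume[hit] <- vol$volume[hit] * k
    }
  }

  if (!is.null(scn$workload_overrides)) {
    for (i in seq_len(nrow(scn$workload_overrides))) {
      ov <- scn$workload_overrides[i, ]
      if (!ov$service_id %in% services$service_id) {
        ev_abort(sprintf("Workload override for unknown service '%s'.",
                         ov$service_id), "evcost_error_schema")
      }
      if (!ov$stratum %in% cat$strata) {
        ev_abort(sprintf("Workload override for unknown stratum '%s'.",
                         ov$stratum), "evcost_error_schema")
      }
      services[services$service_id == ov$service_id,
               paste0("workload_", ov$stratum)] <- ov$workload
    }
  }

  for (add in scn$added_services) {
    s <- add$service
    if (s$service_id %in% services$service_id) {
      ev_abort(sprintf("Added service id '%s' already exists.",
                       s$service_id), "evcost_error_schema")
    }
    row <- tibble::tibble(
      service_id = s$service_id, name = s$name %||% s$service_id,
      category = s$category, delivery_unit = s$delivery_unit %||% "per unit",
      in_nephsp = identical(s$category, "nephsp")
    )
    for (st in cat$strata) {
      w <- s$workload[[st]]
      if (is.null(w)) {
        ev_abort(sprintf(
          "Added service '%s' lacks a workload for stratum '%s'.",
          s$service_id, st
        ), "evcost_error_schema")
      }
      row[[paste0("workload_", st)]] <- w
    }
    services <- dplyr::bind_rows(services, row)
    for (st in names(add$volume)) {
      total_v <- add$volume[[st]]
      in_stratum <- fac[fac$stratum == st, ]
      if (nrow(in_stratum) == 0 || total_v <= 0) next
      vol <- dplyr::bind_rows(vol, tibble::tibble(
        facility_id = in_stratum$facility_id,
        service_id = s$service_id,
        volume = total_v * in_stratum$population_served /
          sum(in_stratum$population_served)
      ))
    }
  }

  new_cat <- catalog(services, benchmark = cat$benchmark,
                     strata = cat$strata)
  new_panel <- facility_panel(fac, vol)
  validate_panel(new_panel, new_cat)
  list(panel = new_panel, catalog = new_cat)
}

#' Difference between two cost reports
#'
#' Field-wise deltas (scenario minus base) for every numeric report
#' column, per scope — e.g. the incremental cost of an added service or
#' the change in the per-capita funding gap under a new allocation.
#'
#' @param base,scenario_report `ev_cost_report` objects sharing scopes and
#'   policy mode.
#' @return A tibble with `scope` and one delta column per numeric report
#'   field.
#' @export
incremental_cost <- function(base, scenario_report) {
  if (!inherits(base, "ev_cost_report") ||
      !inherits(scenario_report, "ev_cost_report")) {
    ev_abort("Both arguments must be ev_cost_report objects.",
             "evcost_error_type")
  }
  if (!identical(base$report$scope, scenario_report$report$scope)) {
    ev_abort("Reports cover different scopes; cannot difference.",
             "evcost_error_domain")
  }
  if (!identical(base$policy$mode, scenario_report$policy$mode)) {
    ev_abort("Reports use different reporting policies; cannot difference.",
             "evcost_error_domain")
  }
  num_cols <- setdiff(names(base$report), "scope")
  out <- tibble::tibble(scope = base$report$scope)
  for (col in num_cols) {
    out[[paste0("delta_", col)]] <-
      scenario_report$report[[col]] - base$report[[col]]
  }
  out
}
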