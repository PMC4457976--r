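#' Build a facility panel
#'
#' A panel is one center-year of observation per facility: the stratum it
#' operates in, the resident population it serves (residents of at least
#' six months), annual expenditure split into the three government input
#' categories (human resources, materials, public funds; USD/year), and
#' annual service volumes in each service's delivery unit.
#'
#' @param facilities Data frame with columns `facility_id`, `stratum`,
#'   `population_served`, `exp_human_resources`, `exp_materials`,
#'   `exp_public_funds`, and optionally `n_employees`.
#' @param volumes Long-format data frame with columns `facility_id`,
#'   `service_id`, `volume` (count/year, nonnegative).
#' @return An object of class `ev_facility_panel` with tibble elements
#'   `facilities` and `volumes`.
#' @seealso [validate_panel()] for catalog-aware checks,
#'   [aggregate_facilities()] for the stratum roll-up.
#' @export
facility_panel <- function(facilities, volumes) {
  facilities <- tibble::as_tibble(facilities)
  volumes <- tibble::as_tibble(volumes)
  exp_cols <- paste0("exp_", expenditure_categories())
  ev_require_columns(
    facilities, c("facility_id", "stratum", "population_served", exp_cols),
    "Facility table"
  )
  ev_require_columns(volumes, c("facility_id", "service_id", "volume"),
                     "Volume table")
  if (!"n_employees" %in% names(facilities)) {
    facilities$n_employees <- NA_real_
  }
  dup <- facilities$facility_id[duplicated(facilities$facility_id)]
  if (length(dup) > 0) {
    ev_abort(sprintf("Duplicate facility id(s): %s.",
                     paste(unique(dup), collapse = ", ")),
             "evcost_error_schema")
  }
  for (col in exp_cols) {
    bad <- !is.finite(facilities[[col]]) | facilities[[col]] < 0
    if (any(bad)) {
      ev_abort(
        sprintf("Negative or missing %s for facility(ies): %s.", col,
                paste(facilities$facility_id[bad], collapse = ", ")),
        "evcost_error_domain"
      )
    }
  }
  bad_pop <- !is.finite(facilities$population_served) |
    facilities$population_served <= 0
  if (any(bad_pop)) {
    ev_abort(
      sprintf("population_served must be > 0; facility(ies): %s.",
              paste(facilities$facility_id[bad_pop], collapse = ", ")),
      "evcost_error_domain"
    )
  }
  bad_vol <- !is.finite(volumes$volume) | volumes$volume < 0
  if (any(bad_vol)) {
    ev_abort(
      sprintf("Volumes must be >= 0; offending facility(ies): %s.",
              paste(unique(volumes$facility_id[bad_vol]), collapse = ", ")),
      "evcost_error_domain"
    )
  }
  orphan <- setdiff(volumes$facility_id, facilities$facility_id)
  if (length(orphan) > 0) {
    ev_abort(sprintf("Volumes reference unknown facility id(s): %s.",
                     paste(orphan, collapse = ", ")),
             "evcost_error_schema")
  }
  facilities <- facilities[, c("facility_id", "stratum", "population_served",
                               "n_employees", exp_cols)]
  structure(list(facilities = facilities, volumes = volumes),
            class = "ev_facility_panel")
}

#' @export
print.ev_facility_panel <- function(x, ...) {
  cat(sprintf("<ev_facility_panel> %d facilities (%s), %d volume records\n",
              nrow(x$facilities),
              paste(sprintf("%d %s", table(x$facilities$stratum),
                            names(table(x$facilities$stratum))),
                    collapse = ", "),
              nrow(x$volumes)))
  print(x$facilities, ...)
  invisible(x)
}

#' Validate a panel against a catalog
#'
#' Beyond the structural checks done by [facility_panel()], verifies that
#' every volume's service id exists in the catalog and every facility's
#' stratum is one of the catalog's strata. Errors name the facility and
#' offending ids.
#'
#' @param panel An `ev_facility_panel`.
#' @param cat An `ev_catalog`.
#' @return The panel, invisibly.
#' @export
validate_panel <- function(panel, cat) {
  if (!inherits(panel, "ev_facility_panel")) {
    ev_abort("`panel` must be an ev_facility_panel.", "evcost_error_type")
  }
  validate_catalog(cat)
  bad_stratum <- !panel$facilities$stratum %in% cat$strata
  if (any(bad_stratum)) {
    ev_abort(
      sprintf(
        "Unknown stratum label(s) %s for facility(ies) %s (catalog strata: %s).",
        paste(unique(panel$facilities$stratum[bad_stratum]), collapse = ", "),
        paste(panel$facilities$facility_id[bad_stratum], collapse = ", "),
        paste(cat$strata, collapse = ", ")
      ),
      "evcost_error_schema"
    )
  }
  unknown <- dplyr::anti_join(
    panel$volumes, cat$services, by = "service_id"
  )
  if (nrow(unknown) > 0) {
    ev_abort(
      sprintf(
        "Volume(s) for service id(s) absent from the catalog: %s (facility %s).",
        paste(unique(unknown$service_id), collapse = ", "),
        paste(unique(unknown$facility_id), collapse = ", ")
      ),
      "evcost_error_schema"
    )
  }
  invisible(panel)
}

#' Read and write facility panels
#'
#' The CSV representation is a pair of files: a facility table
#' (`facility_id,stratum,population_served,n_employees,exp_human_resources,exp_materials,exp_public_funds`)
#' and a long volume table (`facility_id,service_id,volume`). The JSON
#' mirror is a single file nesting each facility's volume map. Validation
#' runs on load; write-then-read is the identity on the data model.
#'
#' @param path Path to the facility CSV or the JSON file.
#' @param volumes_path Path to the volumes CSV (CSV format only).
#' @param format `"csv"`, `"json"`, or `"auto"`.
#' @return `read_facilities()` returns an `ev_facility_panel`;
#'   `write_facilities()` returns the panel invisibly.
#' @export
read_facilities <- function(path, volumes_path = NULL,
                            format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") format <- ev_guess_format(path)
  if (format == "csv") {
    if (is.null(volumes_path)) {
      ev_abort("CSV panels need `volumes_path` for the long volume table.",
               "evcost_error_schema")
    }
    fac <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    vol <- readr::read_csv(volumes_path, show_col_types = FALSE,
                           progress = FALSE)
    return(facility_panel(fac, vol))
  }
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  fac <- purrr::map_dfr(x$facilities, function(f) {
    tibble::tibble(
      facility_id = f$facility_id, stratum = f$stratum,
      population_served = f$population_served,
      n_employees = f$n_employees %||% NA_real_,
      exp_human_resources = f$expenditure$human_resources,
      exp_materials = f$expenditure$materials,
      exp_public_funds = f$expenditure$public_funds
    )
  })
  vol <- purrr::map_dfr(x$facilities, function(f) {
    if (length(f$volumes) == 0) return(NULL)
    tibble::tibble(
      facility_id = f$facility_id,
      service_id = names(f$volumes),
      volume = as.numeric(unlist(f$volumes))
    )
  })
  facility_panel(fac, vol)
}

#' @rdname read_facilities
#' @param panel An `ev_facility_panel` to write.
#' @export
write_facilities <- function(panel, path, volumes_path = NULL,
                             format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") format <- ev_guess_format(path)
  if (format == "csv") {
    if (is.null(volumes_path)) {
      ev_abort("CSV panels need `volumes_path` for the long volume table.",
               "evcost_error_schema")
    }
    readr::write_csv(panel$facilities, path, progress = FALSE)
    readr::write_csv(panel$volumes, volumes_path, progress = FALSE)
  } else {
    vols_by_fac <- split(panel$volumes, panel$volumes$facility_id)
    x <- list(facilities = purrr::pmap(panel$facilities, function(...) {
      f <- list(...)
      v <- vols_by_fac[[f$facility_id]]
      list(
        facility_id = f$facility_id, stratum = f$stratum,
        population_served = f$population_served,
        n_employees = if (is.na(f$n_employees)) NULL else f$n_employees,
        expenditure = list(human_resources = f$exp_human_resources,
                           materials = f$exp_materials,
                           public_funds = f$exp_public_funds),
        volumes = if (is.null(v)) {
          stats::setNames(list(), character())
        } else {
          as.list(stats::setNames(v$volume, v$service_id))
        }
      )
    }))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(panel)
}
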