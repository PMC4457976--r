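#' Define the standard-clinic-visit benchmark
#'
#' One equivalent value (EV) is the workload of a benchmark service: by
#' default a standard clinic visit, a family physician consulting one
#' patient for 15 person-minutes. Every other service's EV is its workload
#' divided by this benchmark workload.
#'
#' @param workload_minutes Workload of the benchmark service, in
#'   person-minutes. Must be > 0. Default 15.
#' @param label Human-readable name of the benchmark service.
#' @return An object of class `ev_benchmark`.
#' @export
#' @examples
#' benchmark()
#' compute_ev(60, benchmark())  # a 60-minute home visit is 4 EV
benchmark <- function(workload_minutes = 15, label = "standard clinic visit") {
  ev_stopifnot_scalar_number(workload_minutes, "workload_minutes",
                             positive = TRUE)
  structure(
    list(workload_minutes = as.numeric(workload_minutes),
         label = as.character(label)),
    class = "ev_benchmark"
  )
}

#' @export
print.ev_benchmark <- function(x, ...) {
  cat(sprintf("<ev_benchmark> %s = %g person-minutes = 1 EV\n",
              x$label, x$workload_minutes))
  invisible(x)
}

#' Convert a workload indicator to equivalent values (EV)
#'
#' The EV of a service is its workload indicator (person-minutes per
#' delivery unit) divided by the benchmark workload; a 60-minute home visit
#' against the 15-minute standard clinic visit has EV 60/15 = 4. The result
#' is returned at full precision; rounding to two decimals is a display
#' concern handled by the reporting policy.
#'
#' @param workload Numeric vector of workload indicators, person-minutes.
#'   All values must be > 0.
#' @param benchmark An [benchmark()] object.
#' @return Numeric vector of dimensionless EVs.
#' @export
#' @examples
#' compute_ev(c(60, 15, 40.35))
compute_ev <- function(workload, benchmark = evcost::benchmark()) {
  if (!inherits(benchmark, "ev_benchmark")) {
    ev_abort("`benchmark` must be created with benchmark().",
             "evcost_error_type")
  }
  if (!is.numeric(workload) || any(!is.finite(workload))) {
    ev_abort("`workload` must be finite numeric.", "evcost_error_type")
  }
  if (any(workload <= 0)) {
    ev_abort(
      sprintf("All workloads must be > 0; offending value(s): %s.",
              paste(utils::head(workload[workload <= 0], 5), collapse = ", ")),
      "evcost_error_domain"
    )
  }
  workload / benchmark$workload_minutes
}

#' Build a service catalog
#'
#' A catalog holds the service taxonomy: one row per service with its
#' category, delivery unit, program membership, and one workload column per
#' stratum (`workload_<stratum>`, person-minutes). Strata are free-form
#' labels; the bundled Beijing data uses `urban` and `suburban`, reflecting
#' that the same service needs different staff time under different
#' population densities and delivery models.
#'
#' @param services Data frame with columns `service_id`, `name`, `category`,
#'   `delivery_unit`, optionally `in_nephsp`, and `workload_<stratum>`
#'   columns. `in_nephsp` defaults to `category == "nephsp"` and must agree
#'   with it when given.
#' @param benchmark An [benchmark()] object; the EV denominator.
#' @param strata Character vector of stratum labels. Defaults to the strata
#'   implied by the `workload_` columns, in column order.
#' @return An object of class `ev_catalog` with elements `services`
#'   (tibble), `benchmark`, and `strata`.
#' @seealso [ev_table()], [read_catalog()]
#' @export
#' @examples
#' cat <- catalog(data.frame(
#'   service_id = "home_visit", name = "Home visit",
#'   category = "basic_medical", delivery_unit = "per visit",
#'   workload_urban = 60, workload_suburban = 60
#' ))
#' ev_table(cat)
catalog <- function(services, benchmark = evcost::benchmark(), strata = NULL) {
  services <- tibble::as_tibble(services)
  ev_require_columns(
    services, c("service_id", "name", "category", "delivery_unit"),
    "Service table"
  )
  workload_cols <- grep("^workload_", names(services), value = TRUE)
  if (is.null(strata)) {
    strata <- sub("^workload_", "", workload_cols)
  }
  if (length(strata) == 0) {
    ev_abort("Catalog needs at least one `workload_<stratum>` column.",
             "evcost_error_schema")
  }
  if (!"in_nephsp" %in% names(services)) {
    services$in_nephsp <- services$category == "nephsp"
  }
  services$in_nephsp <- as.logical(services$in_nephsp)
  services <- services[, c("service_id", "name", "category", "delivery_unit",
                           "in_nephsp", paste0("workload_", strata))]
  out <- structure(
    list(services = services, benchmark = benchmark,
         strata = as.character(strata)),
    class = "ev_catalog"
  )
  validate_catalog(out)
  out
}

#' Validate a catalog
#'
#' Checks the catalog invariants: unique service ids, categories drawn from
#' the closed six-label vocabulary, strictly positive workloads covering
#' every stratum, and `in_nephsp` consistent with the `nephsp` category.
#' Violations raise a classed error naming the offending rows or services.
#'
#' @param cat An `ev_catalog`.
#' @return The catalog, invisibly usable in a pipe (returned unchanged).
#' @export
validate_catalog <- function(cat) {
  if (!inherits(cat, "ev_catalog")) {
    ev_abort("`cat` must be an ev_catalog.", "evcost_error_type")
  }
  sv <- cat$services
  if (nrow(sv) == 0) {
    ev_abort("Catalog contains no services.", "evcost_error_schema")
  }
  dup <- sv$service_id[duplicated(sv$service_id)]
  if (length(dup) > 0) {
    ev_abort(sprintf("Duplicate service id(s): %s.",
                     paste(unique(dup), collapse = ", ")),
             "evcost_error_schema")
  }
  bad_cat <- !sv$category %in% ev_categories()
  if (any(bad_cat)) {
    ev_abort(
      sprintf("Unknown category label(s) in row(s) %s: %s.",
              paste(which(bad_cat), collapse = ", "),
              paste(unique(sv$category[bad_cat]), collapse = ", ")),
      "evcost_error_schema"
    )
  }
  mismatch <- xor(sv$in_nephsp, sv$category == "nephsp")
  if (any(mismatch)) {
    ev_abort(
      sprintf("`in_nephsp` must equal `category == \"nephsp\"`; services: %s.",
              paste(sv$service_id[mismatch], collapse = ", ")),
      "evcost_error_schema"
    )
  }
  missing_cols <- setdiff(paste0("workload_", cat$strata), names(sv))
  if (length(missing_cols) > 0) {
    ev_abort(sprintf("Catalog lacks workload column(s): %s.",
                     paste(missing_cols, collapse = ", ")),
             "evcost_error_schema")
  }
  for (s in cat$strata) {
    w <- sv[[paste0("workload_", s)]]
    bad <- !is.finite(w) | w <= 0
    if (any(bad)) {
      ev_abort(
        sprintf("Non-positive or missing workload for stratum '%s': %s.",
                s, paste(sv$service_id[bad], collapse = ", ")),
        "evcost_error_domain"
      )
    }
  }
  invisible(cat)
}

#' @export
print.ev_catalog <- function(x, ...) {
  cat(sprintf(
    "<ev_catalog> %d services, %d categories, strata: %s\n",
    nrow(x$services), dplyr::n_distinct(x$services$category),
    paste(x$strata, collapse = ", ")
  ))
  cat(sprintf("  benchmark: %s (%g person-minutes = 1 EV)\n",
              x$benchmark$label, x$benchmark$workload_minutes))
  print(x$services, ...)
  invisible(x)
}

#' Equivalent values of every service in every stratum
#'
#' Expands a catalog into a long tibble with one row per service x stratum,
#' carrying the stored workload and its EV at full precision. Printed EVs
#' in the source tables are these values rounded to two decimals for
#' display; no rounding is applied here.
#'
#' @param cat An `ev_catalog`.
#' @return A tibble with columns `service_id`, `name`, `category`,
#'   `in_nephsp`, `stratum`, `workload`, `ev`.
#' @export
#' @examples
#' ev_table(beijing_fixture()$catalog)
ev_table <- function(cat) {
  validate_catalog(cat)
  cat$services |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(paste0("workload_", cat$strata)),
      names_to = "stratum", names_prefix = "workload_",
      values_to = "workload"
    ) |>
    dplyr::mutate(ev = compute_ev(.data$workload, cat$benchmark)) |>
    dplyr::select("service_id", "name", "category", "in_nephsp",
                  "stratum", "workload", "ev")
}

#' Read and write catalog files
#'
#' CSV catalogs have columns
#' `service_id,name,category,delivery_unit,in_nephsp,workload_<stratum>`
#' (one workload column per stratum) and implicitly use the default
#' 15-minute benchmark. The JSON mirror nests per-service workload maps and
#' carries an explicit `benchmark` object `{workload_minutes, label}` and a
#' `strata` array. `read_catalog()` validates on load;
#' `write_catalog()` then `read_catalog()` round-trips the data model
#' exactly.
#'
#' @param path File path.
#' @param format `"csv"`, `"json"`, or `"auto"` (from the extension).
#' @param benchmark Benchmark to attach when reading CSV (which stores
#'   none). Ignored for JSON.
#' @return `read_catalog()` returns an `ev_catalog`; `write_catalog()`
#'   returns `cat` invisibly.
#' @export
read_catalog <- function(path, format = c("auto", "csv", "json"),
                         benchmark = evcost::benchmark()) {
  format <- match.arg(format)
  if (format == "auto") format <- ev_guess_format(path)
  if (format == "csv") {
    sv <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    return(catalog(sv, benchmark = benchmark))
  }
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  bm <- benchmark
  if (!is.null(x$benchmark)) {
    bm <- evcost::benchmark(x$benchmark$workload_minutes, x$benchmark$label)
  }
  strata <- as.character(unlist(x$strata))
  sv <- purrr::map_dfr(x$services, function(s) {
    row <- tibble::tibble(
      service_id = s$service_id, name = s$name, category = s$category,
      delivery_unit = s$delivery_unit, in_nephsp = isTRUE(s$in_nephsp)
    )
    for (st in strata) {
      w <- s$workload[[st]]
      row[[paste0("workload_", st)]] <- if (is.null(w)) NA_real_ else w
    }
    row
  })
  catalog(sv, benchmark = bm, strata = strata)
}

#' @rdname read_catalog
#' @param cat An `ev_catalog` to write.
#' @export
write_catalog <- function(cat, path, format = c("auto", "csv", "json")) {
  validate_catalog(cat)
  format <- match.arg(format)
  if (format == "auto") format <- ev_guess_format(path)
  if (format == "csv") {
    readr::write_csv(cat$services, path, progress = FALSE)
  } else {
    x <- list(
      benchmark = list(workload_minutes = cat$benchmark$workload_minutes,
                       label = cat$benchmark$label),
      strata = as.list(cat$strata),
      services = purrr::pmap(cat$services, function(...) {
        s <- list(...)
        w <- s[paste0("workload_", cat$strata)]
        names(w) <- cat$strata
        list(service_id = s$service_id, name = s$name,
             category = s$category, delivery_unit = s$delivery_unit,
             in_nephsp = s$in_nephsp, workload = w)
      })
    )
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(cat)
}
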