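#' Total EV after the other-services uplift
#'
#' The measured EV total covers only the five enumerated service
#' categories. Residual services outside the taxonomy were judged (by
#' provider group interviews) to account for a fixed share of total
#' workload — 10% by default — so the uplift is a share of the *total*,
#' not a markup on the measured sum:
#' `total = round(measured / (1 - uplift_share))`, half-up to a whole EV.
#' Equivalently, the imputed "other" workload is `measured / 9` at the
#' default share.
#'
#' @param measured_ev Measured EV total (five enumerated categories).
#' @param uplift_share Fraction of total workload attributed to residual
#'   services; `0 <= uplift_share < 1`.
#' @return Integer-valued total EV.
#' @export
#' @examples
#' uplifted_total_ev(12650762)   # 14,056,402
uplifted_total_ev <- function(measured_ev, uplift_share = 0.1) {
  ev_stopifnot_scalar_number(uplift_share, "uplift_share", nonnegative = TRUE)
  if (uplift_share >= 1) {
    ev_abort("`uplift_share` must be < 1.", "evcost_error_domain")
  }
  round_half_up(measured_ev / (1 - uplift_share))
}

ev_wide_category_cols <- function() paste0("ev_", ev_measured_categories())

# Shared builder: strata table (may carry an explicit "all" row whose
# printed expenditures/population override the re-summed stratum values)
# plus per-stratum measured category EVs -> aggregate tibble.
build_aggregates <- function(strata, category_ev, uplift_share,
                             service_ev = NULL) {
  exp_cols <- paste0("exp_", expenditure_categories())
  ev_require_columns(strata, c("stratum", "n_facilities", "population",
                               exp_cols), "Strata table")
  ev_require_columns(category_ev, c("stratum", "category", "measured_ev"),
                     "Category EV table")
  stratum_rows <- dplyr::filter(strata, .data$stratum != "all")
  if (any(category_ev$stratum == "all")) {
    ev_abort("Category EVs must be per stratum; the pooled row is derived.",
             "evcost_error_schema")
  }
  wide <- category_ev |>
    dplyr::mutate(category = paste0("ev_", .data$category)) |>
    tidyr::pivot_wider(names_from = "category",
                       values_from = "measured_ev", values_fill = 0)
  for (col in ev_wide_category_cols()) {
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  per_stratum <- stratum_rows |>
    dplyr::left_join(wide, by = "stratum") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(ev_wide_category_cols()),
                                ~ tidyr::replace_na(.x, 0)))

  pooled <- per_stratum |>
    dplyr::summarise(
      stratum = "all",
      dplyr::across(dplyr::all_of(c("n_facilities", "population", exp_cols,
                                    ev_wide_category_cols())), sum)
    )
  # Printed pooled expenditures/population take precedence over the
  # re-summed stratum columns when the source provides them.
  given_all <- dplyr::filter(strata, .data$stratum == "all")
  if (nrow(given_all) == 1) {
    pooled[c("population", exp_cols)] <-
      given_all[c("population", exp_cols)]
    pooled$n_facilities <- given_all$n_facilities
  }

  out <- dplyr::bind_rows(per_stratum, pooled) |>
    dplyr::mutate(
      measured_ev_total = rowSums(dplyr::pick(dplyr::all_of(
        ev_wide_category_cols()
      ))),
      total_ev = uplifted_total_ev(.data$measured_ev_total, uplift_share),
      ev_other = .data$total_ev - .data$measured_ev_total
    ) |>
    dplyr::select(dplyr::all_of(c(
      "stratum", "n_facilities", "population", exp_cols,
      ev_wide_category_cols(), "ev_other", "measured_ev_total", "total_ev"
    )))
  structure(out, uplift_share = uplift_share, service_ev = service_ev,
            class = c("ev_stratum_aggregates", class(out)))
}

#' Stratum aggregates from published category-level data
#'
#' Builds the stratum-level aggregate table directly from pooled
#' expenditures and measured category EV totals — the form in which the
#' Beijing reference study publishes its data. Use
#' [aggregate_facilities()] instead when facility-level volumes are
#' available.
#'
#' @param strata Data frame with columns `stratum`, `n_facilities`,
#'   `population`, `exp_human_resources`, `exp_materials`,
#'   `exp_public_funds`. An optional row with stratum `"all"` supplies the
#'   published pooled expenditures and population, which then override the
#'   re-summed stratum values (published tables round each cell, so the
#'   pooled row need not equal the sum of its columns to the cent).
#' @param category_ev Data frame with columns `stratum`, `category`,
#'   `measured_ev`: the measured EV total of each enumerated category per
#'   stratum. The pooled row is always derived by summation.
#' @param uplift_share Residual-services share of total workload; see
#'   [uplifted_total_ev()].
#' @return A tibble of class `ev_stratum_aggregates`: one row per stratum
#'   plus a pooled `"all"` row, with expenditures, per-category measured
#'   EVs, the imputed `ev_other`, `measured_ev_total`, and the uplifted
#'   integer `total_ev`.
#' @export
#' @examples
#' fx <- beijing_fixture()
#' stratum_aggregates(fx$strata, fx$category_ev)
stratum_aggregates <- function(strata, category_ev, uplift_share = 0.1) {
  build_aggregates(tibble::as_tibble(strata),
                   tibble::as_tibble(category_ev), uplift_share)
}

#' Aggregate a facility panel into stratum totals
#'
#' Rolls one center-year of records per facility up to the stratum level:
#' each service volume is multiplied by that service's EV in the
#' facility's stratum and summed within category
#' (`measured EV = sum over services of volume x EV`), expenditures and
#' populations are summed, and the other-services uplift converts the
#' measured EV total into the total EV (applied once per stratum and once
#' for the pooled row — never per facility, since the uplift share
#' describes the sample's total workload). The pooled row sums the
#' per-stratum measured EVs before applying the uplift.
#'
#' @param panel An `ev_facility_panel`.
#' @param cat An `ev_catalog`; every volume's service id must resolve and
#'   every facility's stratum must be one of the catalog's strata.
#' @param uplift_share See [uplifted_total_ev()].
#' @return A tibble of class `ev_stratum_aggregates` (see
#'   [stratum_aggregates()]). Per-service EV totals by stratum are kept in
#'   the `"service_ev"` attribute for service-level program selection.
#' @export
aggregate_facilities <- function(panel, cat, uplift_share = 0.1) {
  validate_panel(panel, cat)
  if (nrow(panel$facilities) == 0) {
    ev_abort("Cannot aggregate an empty facility set.", "evcost_error_domain")
  }
  evs <- ev_table(cat)
  scored <- panel$volumes |>
    dplyr::inner_join(
      dplyr::select(panel$facilities, "facility_id", "stratum"),
      by = "facility_id"
    ) |>
    dplyr::inner_join(
      dplyr::select(evs, "service_id", "stratum", "category", "ev"),
      by = c("service_id", "stratum")
    ) |>
    dplyr::mutate(ev_amount = .data$volume * .data$ev)

  category_ev <- scored |>
    dplyr::group_by(.data$stratum, .data$category) |>
    dplyr::summarise(measured_ev = sum(.data$ev_amount), .groups = "drop")

  service_ev <- scored |>
    dplyr::group_by(.data$stratum, .data$service_id) |>
    dplyr::summarise(ev_total = sum(.data$ev_amount), .groups = "drop")
  service_ev <- dplyr::bind_rows(
    service_ev,
    service_ev |>
      dplyr::group_by(.data$service_id) |>
      dplyr::summarise(stratum = "all", ev_total = sum(.data$ev_total),
                       .groups = "drop")
  )

  strata_tbl <- panel$facilities |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n_facilities = dplyr::n(),
      population = sum(.data$population_served),
      dplyr::across(dplyr::all_of(paste0("exp_", expenditure_categories())),
                    sum),
      .groups = "drop"
    ) |>
    # preserve catalog stratum order for stable output
    dplyr::arrange(match(.data$stratum, cat$strata))

  build_aggregates(strata_tbl, category_ev, uplift_share,
                   service_ev = service_ev)
}

#' @export
print.ev_stratum_aggregates <- function(x, ...) {
  cat(sprintf("<ev_stratum_aggregates> uplift_share = %g\n",
              attr(x, "uplift_share")))
  NextMethod()
}
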