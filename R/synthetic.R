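#' Configure the synthetic-panel generator
#'
#' The generator emulates the study conditions of the bundled Beijing
#' reference data: 7 urban and 10 suburban centers, a catalog of 27
#' services across the five measured categories, category EV shares near
#' the reference workload profile, and expenditure split roughly 66/10/24
#' across human resources, materials, and public funds. Crucially,
#' expenditures are *constructed* from a planted cost per EV, so the
#' costing engine's recovery of that value is exact by design and serves
#' as an end-to-end correctness check.
#'
#' @param seed Integer RNG seed; fixed seed gives bit-identical panels.
#' @param n_facilities_by_stratum Named integer vector, stratum -> count.
#' @param n_services_by_category Named integer vector over measured
#'   categories; all counts >= 1.
#' @param workload_range Person-minutes interval for drawn workload
#'   indicators.
#' @param volume_meanlog,volume_sdlog Log-normal volume parameters; scalars
#'   or named per measured category.
#' @param category_ev_shares Target share of measured EV per category;
#'   must sum to 1.
#' @param planted_cost_per_ev Named numeric, stratum -> USD per EV; the
#'   ground truth the engine must recover.
#' @param expenditure_shares Input-category split of expenditure; must sum
#'   to 1.
#' @param population_range Persons interval for facility populations.
#' @param uplift_share Residual-services share; see [uplifted_total_ev()].
#' @return An object of class `ev_synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 7)
#' panel <- generate_panel(cfg)
#' glance(cost_report(panel$panel, panel$catalog,
#'                    policy = reporting_policy("full_precision")))
synthetic_config <- function(seed = 7L,
                             n_facilities_by_stratum = c(urban = 7L,
                                                         suburban = 10L),
                             n_services_by_category = c(basic_medical = 5L,
                                                        nursing = 5L,
                                                        pharmacy = 2L,
                                                        auxiliary_exam = 5L,
                                                        nephsp = 10L),
                             workload_range = c(4.5, 480),
                             volume_meanlog = 8,
                             volume_sdlog = 1,
                             category_ev_shares = c(basic_medical = 0.3566,
                                                    nursing = 0.0425,
                                                    pharmacy = 0.1016,
                                                    auxiliary_exam = 0.0634,
                                                    nephsp = 0.4359),
                             planted_cost_per_ev = c(urban = 1.71,
                                                     suburban = 2.05),
                             expenditure_shares = c(human_resources = 0.66,
                                                    materials = 0.10,
                                                    public_funds = 0.24),
                             population_range = c(30000, 160000),
                             uplift_share = 0.1) {
  if (any(n_facilities_by_stratum < 1) ||
      is.null(names(n_facilities_by_stratum))) {
    ev_abort("`n_facilities_by_stratum` must be named counts >= 1.",
             "evcost_error_domain")
  }
  if (any(n_services_by_category < 1) ||
      !all(names(n_services_by_category) %in% ev_measured_categories())) {
    ev_abort(
      "`n_services_by_category` must be counts >= 1 over measured categories.",
      "evcost_error_domain"
    )
  }
  check_shares <- function(x, what) {
    if (abs(sum(x) - 1) > 1e-8 || any(x < 0)) {
      ev_abort(sprintf("`%s` must be nonnegative and sum to 1.", what),
               "evcost_error_domain")
    }
  }
  check_shares(category_ev_shares, "category_ev_shares")
  check_shares(expenditure_shares, "expenditure_shares")
  if (any(workload_range <= 0) || diff(workload_range) < 0 ||
      any(population_range <= 0) || diff(population_range) < 0) {
    ev_abort("Ranges must be positive and nondecreasing.",
             "evcost_error_domain")
  }
  strata <- names(n_facilities_by_stratum)
  if (!setequal(names(planted_cost_per_ev), strata) ||
      any(planted_cost_per_ev <= 0)) {
    ev_abort("`planted_cost_per_ev` must give a positive value per stratum.",
             "evcost_error_domain")
  }
  expand <- function(x) {
    cats <- names(n_services_by_category)
    if (length(x) == 1 && is.null(names(x))) {
      return(stats::setNames(rep(x, length(cats)), cats))
    }
    x[cats]
  }
  structure(
    list(seed = as.integer(seed),
         n_facilities_by_stratum = n_facilities_by_stratum,
         n_services_by_category = n_services_by_category,
         workload_range = workload_range,
         volume_meanlog = expand(volume_meanlog),
         volume_sdlog = expand(volume_sdlog),
         category_ev_shares = category_ev_shares,
         planted_cost_per_ev = planted_cost_per_ev[strata],
         expenditure_shares = expenditure_shares,
         population_range = population_range,
         uplift_share = uplift_share),
    class = "ev_synthetic_config"
  )
}

#' Generate a synthetic catalog and facility panel with planted truth
#'
#' Workload indicators are drawn uniformly per service and stratum; raw
#' volumes are drawn log-normally per facility and service, then rescaled
#' within each stratum so category EV shares match the configured profile,
#' and rounded to whole delivery units. Stratum expenditure is then set to
#' `planted cost per EV x total EV` (total EV taken after the uplift and
#' its integer rounding), split across input categories by the configured
#' shares and across facilities proportionally to each facility's measured
#' EV — so a full-precision [cost_report()] recovers the planted cost per
#' EV exactly.
#'
#' @param config An [synthetic_config()].
#' @return A list with elements `catalog` (an `ev_catalog`), `panel` (an
#'   `ev_facility_panel`), and `config`.
#' @export
generate_panel <- function(config = synthetic_config()) {
  if (!inherits(config, "ev_synthetic_config")) {
    ev_abort("`config` must come from synthetic_config().",
             "evcost_error_type")
  }
  set.seed(config$seed)
  strata <- names(config$n_facilities_by_stratum)
  cats <- names(config$n_services_by_category)

  services <- purrr::map_dfr(cats, function(cg) {
    n <- config$n_services_by_category[[cg]]
    tibble::tibble(
      service_id = sprintf("%s_%02d", cg, seq_len(n)),
      name = sprintf("Synthetic %s service %d", gsub("_", " ", cg),
                     seq_len(n)),
      category = cg,
      delivery_unit = "per unit"
    )
  })
  for (st in strata) {
    services[[paste0("workload_", st)]] <- round_half_up(
      runif(nrow(services), config$workload_range[1],
            config$workload_range[2]), 2
    )
  }
  cat <- catalog(services, strata = strata)

  fac <- purrr::map_dfr(strata, function(st) {
    n <- config$n_facilities_by_stratum[[st]]
    tibble::tibble(
      facility_id = sprintf("%s_%02d", st, seq_len(n)),
      stratum = st,
      population_served = round_half_up(
        runif(n, config$population_range[1], config$population_range[2])
      ),
      n_employees = round_half_up(runif(n, 50, 200))
    )
  })

  vol <- tidyr::crossing(
    facility_id = fac$facility_id,
    service_id = services$service_id
  ) |>
    dplyr::left_join(dplyr::select(services, "service_id", "category"),
                     by = "service_id") |>
    dplyr::left_join(dplyr::select(fac, "facility_id", "stratum"),
                     by = "facility_id") |>
    dplyr::arrange(.data$facility_id, .data$service_id)
  vol$volume <- rlnorm(nrow(vol),
                       config$volume_meanlog[vol$category],
                       config$volume_sdlog[vol$category])

  evs <- dplyr::select(ev_table(cat), "service_id", "stratum", "ev")
  vol <- dplyr::left_join(vol, evs, by = c("service_id", "stratum"))

  # Rescale category volumes within each stratum toward the target EV
  # shares (total EV per stratum is preserved), then round volumes to
  # whole delivery units.
  vol <- vol |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(stratum_ev = sum(.data$volume * .data$ev)) |>
    dplyr::group_by(.data$stratum, .data$category) |>
    dplyr::mutate(volume = .data$volume * config$category_ev_shares[
      dplyr::cur_group()$category
    ] * .data$stratum_ev[1] / sum(.data$volume * .data$ev)) |>
    dplyr::ungroup() |>
    dplyr::mutate(volume = round_half_up(.data$volume))

  # Plant the ground truth: stratum expenditure = c* x total EV (after the
  # uplift's integer rounding), split by input-category shares and spread
  # over facilities by their measured EV.
  fac_ev <- vol |>
    dplyr::group_by(.data$facility_id, .data$stratum) |>
    dplyr::summarise(fac_ev = sum(.data$volume * .data$ev),
                     .groups = "drop")
  stratum_ev <- fac_ev |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(measured_ev = sum(.data$fac_ev), .groups = "drop") |>
    dplyr::mutate(
      total_ev = uplifted_total_ev(.data$measured_ev, config$uplift_share),
      total_exp = config$planted_cost_per_ev[.data$stratum] * .data$total_ev
    )
  fac_ev <- fac_ev |>
    dplyr::left_join(stratum_ev, by = "stratum") |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(weight = .data$fac_ev / sum(.data$fac_ev)) |>
    dplyr::ungroup()
  for (ec in expenditure_categories()) {
    fac[[paste0("exp_", ec)]] <- as.numeric((fac_ev$total_exp *
      fac_ev$weight * config$expenditure_shares[[ec]])[
        match(fac$facility_id, fac_ev$facility_id)])
  }

  panel <- facility_panel(
    fac, dplyr::select(vol, "facility_id", "service_id", "volume")
  )
  validate_panel(panel, cat)
  list(catalog = cat, panel = panel, config = config)
}
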