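#' Reporting policy: how results are rounded and chained
#'
#' Two modes are supported. `"published"` reproduces the arithmetic chains
#' used in published costing tables: the cost of one EV is rounded to
#' `money_decimals` (cents) before being multiplied by the program EV, the
#' program cost is rounded to whole USD before the per-capita division,
#' per-capita costs are rounded to cents, and percent shares to two
#' decimals — all half-up. `"full_precision"` performs every step on full
#' floats and leaves rounding to the caller; in that mode the category
#' decompositions sum exactly to their totals.
#'
#' @param mode `"published"` or `"full_precision"`.
#' @param money_decimals Decimal places for money values (default 2).
#' @param propagate_rounded Should rounded intermediates feed downstream
#'   steps? Defaults to `TRUE` in published mode, `FALSE` otherwise.
#' @return An object of class `ev_reporting_policy`.
#' @export
#' @examples
#' reporting_policy("full_precision")
reporting_policy <- function(mode = c("published", "full_precision"),
                             money_decimals = 2L,
                             propagate_rounded = NULL) {
  mode <- match.arg(mode)
  if (money_decimals < 0) {
    ev_abort("`money_decimals` must be >= 0.", "evcost_error_domain")
  }
  structure(
    list(mode = mode,
         money_decimals = as.integer(money_decimals),
         propagate_rounded = propagate_rounded %||% (mode == "published")),
    class = "ev_reporting_policy"
  )
}

#' @export
print.ev_reporting_policy <- function(x, ...) {
  cat(sprintf("<ev_reporting_policy> mode = %s, money_decimals = %d%s\n",
              x$mode, x$money_decimals,
              if (x$propagate_rounded) ", rounded intermediates propagate"
              else ""))
  invisible(x)
}

pol_round <- function(x, policy, digits) {
  if (policy$propagate_rounded) round_half_up(x, digits) else x
}
pol_money <- function(x, policy) pol_round(x, policy, policy$money_decimals)
pol_whole <- function(x, policy) pol_round(x, policy, 0)
pol_pct   <- function(x, policy) pol_round(x, policy, 2)

#' Cost of one EV, total and by input category
#'
#' The cost of one EV is the total annual expenditure of a scope divided by
#' its total EV; each input category's contribution is that category's
#' expenditure over the same denominator, so in full precision the three
#' category costs sum exactly to the total.
#'
#' @param aggregates An `ev_stratum_aggregates` table.
#' @param policy A [reporting_policy()].
#' @return A tibble with one row per scope (each stratum and `"all"`):
#'   `scope`, `total_ev`, `cost_per_ev_human_resources`,
#'   `cost_per_ev_materials`, `cost_per_ev_public_funds`,
#'   `cost_per_ev_total`.
#' @export
#' @examples
#' cost_per_ev(beijing_fixture()$aggregates)
cost_per_ev <- function(aggregates, policy = reporting_policy()) {
  if (any(aggregates$total_ev <= 0)) {
    bad <- aggregates$stratum[aggregates$total_ev <= 0]
    ev_abort(sprintf("Zero total EV in scope(s): %s; cannot divide.",
                     paste(bad, collapse = ", ")),
             "evcost_error_domain")
  }
  exp_cols <- paste0("exp_", expenditure_categories())
  total_exp <- rowSums(as.data.frame(aggregates)[, exp_cols])
  out <- tibble::tibble(
    scope = aggregates$stratum,
    total_ev = aggregates$total_ev
  )
  for (cat_name in expenditure_categories()) {
    out[[paste0("cost_per_ev_", cat_name)]] <-
      pol_money(aggregates[[paste0("exp_", cat_name)]] / aggregates$total_ev,
                policy)
  }
  out$cost_per_ev_total <- pol_money(total_exp / aggregates$total_ev, policy)
  out
}

#' Program EV and its share of total workload
#'
#' Sums the measured EV over a program — either whole service categories
#' (default: the `nephsp` category, i.e. the ten national essential
#' public-health services) or an explicit set of service ids — and reports
#' it alongside its percent share of the scope's total EV.
#'
#' Service-id programs require aggregates produced by
#' [aggregate_facilities()], which retain per-service EV totals; the
#' published stratum-level reference data only resolves to categories.
#'
#' @param aggregates An `ev_stratum_aggregates` table.
#' @param program Character vector: measured category labels, or service
#'   ids.
#' @return A tibble with `scope`, `program_ev`, `program_share` (percent,
#'   full precision).
#' @export
#' @examples
#' program_ev(beijing_fixture()$aggregates)
program_ev <- function(aggregates, program = "nephsp") {
  if (length(program) == 0) {
    ev_abort("`program` must name at least one category or service.",
             "evcost_error_domain")
  }
  is_category <- program %in% ev_measured_categories()
  if (all(is_category)) {
    pe <- rowSums(as.data.frame(aggregates)[, paste0("ev_", program),
                                            drop = FALSE])
  } else if (any(is_category)) {
    ev_abort("`program` mixes category labels and service ids.",
             "evcost_error_type")
  } else {
    service_ev <- attr(aggregates, "service_ev")
    if (is.null(service_ev)) {
      ev_abort(
        "Service-id programs need aggregates from aggregate_facilities().",
        "evcost_error_type"
      )
    }
    unknown <- setdiff(program, unique(service_ev$service_id))
    if (length(unknown) > 0) {
      ev_abort(sprintf("Unknown program service id(s): %s.",
                       paste(unknown, collapse = ", ")),
               "evcost_error_schema")
    }
    pe_tbl <- service_ev |>
      dplyr::filter(.data$service_id %in% program) |>
      dplyr::group_by(.data$stratum) |>
      dplyr::summarise(program_ev = sum(.data$ev_total), .groups = "drop")
    pe <- pe_tbl$program_ev[match(aggregates$stratum, pe_tbl$stratum)]
    pe[is.na(pe)] <- 0
  }
  tibble::tibble(
    scope = aggregates$stratum,
    program_ev = pe,
    program_share = pe / aggregates$total_ev * 100
  )
}

#' Program cost from program EV and cost per EV
#'
#' Multiplies the program's EV total by the cost of one EV. Under a
#' published-mode policy the cost per EV is already rounded to cents and
#' the product is rounded to whole USD, matching how published totals
#' chain.
#'
#' @param program_ev Program EV total(s).
#' @param cost_per_ev Cost of one EV, USD.
#' @param policy A [reporting_policy()].
#' @return Program cost in USD.
#' @export
#' @examples
#' program_cost(5514777, 1.87)  # 10,312,633 USD
program_cost <- function(program_ev, cost_per_ev,
                         policy = reporting_policy()) {
  if (any(program_ev < 0) || any(cost_per_ev < 0)) {
    ev_abort("`program_ev` and `cost_per_ev` must be nonnegative.",
             "evcost_error_domain")
  }
  pol_whole(program_ev * cost_per_ev, policy)
}

#' Per-capita cost
#'
#' Divides a cost by the population served (residents of at least six
#' months). Published mode rounds to `money_decimals`.
#'
#' @param cost Cost in USD.
#' @param population Persons; must be > 0.
#' @param policy A [reporting_policy()].
#' @return USD per person.
#' @export
#' @examples
#' per_capita(10312633, 1296408)  # 7.95 USD
per_capita <- function(cost, population, policy = reporting_policy()) {
  if (any(population <= 0)) {
    ev_abort("`population` must be > 0.", "evcost_error_domain")
  }
  pol_money(cost / population, policy)
}

#' Per-capita funding gap
#'
#' Estimated per-capita program cost minus the per-capita government
#' allocation. Negative values indicate a surplus and are labelled as such
#' when printed.
#'
#' @param cost_per_capita USD/person.
#' @param allocation_per_capita USD/person.
#' @return USD/person; may be negative.
#' @export
#' @examples
#' funding_gap(7.95, 3.97)
funding_gap <- function(cost_per_capita, allocation_per_capita) {
  if (any(cost_per_capita < 0) || any(allocation_per_capita < 0)) {
    ev_abort("Funding-gap inputs must be nonnegative.",
             "evcost_error_domain")
  }
  cost_per_capita - allocation_per_capita
}

#' Full cost report: cost per EV, program cost, per-capita cost, gap
#'
#' Composes the whole costing chain for every scope (each stratum plus the
#' pooled `"all"`): cost of one EV with its input-category decomposition,
#' the program's EV and share of total workload, the program cost, the
#' per-capita cost with its category decomposition, and — when an
#' allocation is supplied — the per-capita funding gap. Deterministic given
#' its inputs and policy.
#'
#' @param x An `ev_stratum_aggregates` table, or an `ev_facility_panel`
#'   (in which case `cat` is required and aggregation runs first).
#' @param program See [program_ev()].
#' @param policy A [reporting_policy()].
#' @param allocation_per_capita Government allocation, USD/person
#'   (optional).
#' @param ... Passed between methods.
#' @return An object of class `ev_cost_report`; see [tidy()], [glance()],
#'   [autoplot()] and `as_tibble()` for accessors.
#' @export
#' @examples
#' rep <- cost_report(beijing_fixture()$aggregates,
#'                    allocation_per_capita = 3.97)
#' rep
#' glance(rep)
cost_report <- function(x, ...) UseMethod("cost_report")

#' @rdname cost_report
#' @export
cost_report.ev_stratum_aggregates <- function(x, program = "nephsp",
                                              policy = reporting_policy(),
                                              allocation_per_capita = NULL,
                                              ...) {
  cpe <- cost_per_ev(x, policy)
  pe <- program_ev(x, program)
  rep <- dplyr::left_join(cpe, pe, by = "scope")
  rep$program_share <- pol_pct(rep$program_share, policy)
  rep$population <- x$population
  rep$n_facilities <- x$n_facilities
  rep$measured_ev_total <- x$measured_ev_total
  rep$program_cost <- program_cost(rep$program_ev, rep$cost_per_ev_total,
                                   policy)
  rep$cost_per_capita_total <- per_capita(rep$program_cost, rep$population,
                                          policy)
  for (cat_name in expenditure_categories()) {
    cost_c <- program_cost(rep$program_ev,
                           rep[[paste0("cost_per_ev_", cat_name)]], policy)
    rep[[paste0("cost_per_capita_", cat_name)]] <-
      per_capita(cost_c, rep$population, policy)
  }
  if (!is.null(allocation_per_capita)) {
    ev_stopifnot_scalar_number(allocation_per_capita,
                               "allocation_per_capita", nonnegative = TRUE)
    rep$allocation_per_capita <- allocation_per_capita
    rep$funding_gap_per_capita <-
      funding_gap(rep$cost_per_capita_total, allocation_per_capita)
  } else {
    rep$allocation_per_capita <- NA_real_
    rep$funding_gap_per_capita <- NA_real_
  }
  rep <- dplyr::select(rep, dplyr::all_of(c(
    "scope", "n_facilities", "population", "measured_ev_total", "total_ev",
    "program_ev", "program_share",
    paste0("cost_per_ev_", expenditure_categories()), "cost_per_ev_total",
    "program_cost",
    paste0("cost_per_capita_", expenditure_categories()),
    "cost_per_capita_total",
    "allocation_per_capita", "funding_gap_per_capita"
  )))
  structure(
    list(report = rep, policy = policy, program = program,
         uplift_share = attr(x, "uplift_share")),
    class = "ev_cost_report"
  )
}

#' @rdname cost_report
#' @param cat An `ev_catalog` (facility-panel method only).
#' @param uplift_share See [uplifted_total_ev()] (facility-panel method
#'   only).
#' @export
cost_report.ev_facility_panel <- function(x, cat, program = "nephsp",
                                          policy = reporting_policy(),
                                          allocation_per_capita = NULL,
                                          uplift_share = 0.1, ...) {
  agg <- aggregate_facilities(x, cat, uplift_share = uplift_share)
  cost_report(agg, program = program, policy = policy,
              allocation_per_capita = allocation_per_capita)
}

# Two display tables mirroring the published layout: cost items x scopes.
report_tables <- function(x) {
  rep <- x$report
  items <- c(expenditure_categories(), "total")
  labels <- c("Human resources costs", "Materials costs", "Public funds",
              "Total")
  mk <- function(prefix) {
    df <- data.frame(`Cost items` = labels, check.names = FALSE)
    for (sc in rep$scope) {
      row <- rep[rep$scope == sc, ]
      df[[sc]] <- vapply(items, function(it) row[[paste0(prefix, it)]],
                         numeric(1))
    }
    df
  }
  list(cost_per_ev = mk("cost_per_ev_"),
       cost_per_capita = mk("cost_per_capita_"))
}

#' @export
print.ev_cost_report <- function(x, ...) {
  rep <- x$report
  dec <- x$policy$money_decimals
  cat(sprintf("<ev_cost_report> policy = %s, program = %s, uplift = %g\n\n",
              x$policy$mode, paste(x$program, collapse = "+"),
              x$uplift_share %||% NA))
  tabs <- report_tables(x)
  fmt <- function(df) {
    df[-1] <- lapply(df[-1], ev_format_money, decimals = dec)
    df
  }
  cat("Cost of one EV (USD):\n")
  print(fmt(tabs$cost_per_ev), row.names = FALSE)
  cat("\nProgram cost per capita (USD):\n")
  print(fmt(tabs$cost_per_capita), row.names = FALSE)
  all_row <- rep[rep$scope == "all", ]
  if (nrow(all_row) == 1) {
    cat(sprintf(
      "\nPooled: total EV %s; program EV %s (%.2f%% of workload); program cost %s USD\n",
      ev_format_money(all_row$total_ev, 0),
      ev_format_money(all_row$program_ev, 0), all_row$program_share,
      ev_format_money(all_row$program_cost, 0)
    ))
    if (!is.na(all_row$funding_gap_per_capita)) {
      gap <- all_row$funding_gap_per_capita
      cat(sprintf(
        "Per-capita cost %s vs allocation %s USD: %s of %s USD per person\n",
        ev_format_money(all_row$cost_per_capita_total, dec),
        ev_format_money(all_row$allocation_per_capita, dec),
        if (gap >= 0) "funding gap" else "surplus",
        ev_format_money(abs(gap), dec)
      ))
    }
  }
  invisible(x)
}

#' @export
#' @method as_tibble ev_cost_report
#' @importFrom tibble as_tibble
as_tibble.ev_cost_report <- function(x, ...) {
  x$report
}

#' Tidy a cost report into one row per scope and cost item
#'
#' @param x An `ev_cost_report`.
#' @param ... Unused.
#' @return A tibble with columns `scope`, `cost_item` (the three input
#'   categories and `total`), `cost_per_ev`, `cost_per_capita`.
#' @method tidy ev_cost_report
#' @export
tidy.ev_cost_report <- function(x, ...) {
  items <- c(expenditure_categories(), "total")
  purrr::map_dfr(items, function(it) {
    tibble::tibble(
      scope = x$report$scope,
      cost_item = it,
      cost_per_ev = x$report[[paste0("cost_per_ev_", it)]],
      cost_per_capita = x$report[[paste0("cost_per_capita_", it)]]
    )
  }) |>
    dplyr::arrange(match(.data$scope, x$report$scope))
}

#' One-row pooled summary of a cost report
#'
#' @param x An `ev_cost_report`.
#' @param ... Unused.
#' @return A one-row tibble with the pooled headline quantities.
#' @method glance ev_cost_report
#' @export
glance.ev_cost_report <- function(x, ...) {
  all_row <- x$report[x$report$scope == "all", ]
  if (nrow(all_row) == 0) all_row <- x$report[nrow(x$report), ]
  tibble::tibble(
    total_ev = all_row$total_ev,
    cost_per_ev = all_row$cost_per_ev_total,
    program_ev = all_row$program_ev,
    program_share = all_row$program_share,
    program_cost = all_row$program_cost,
    population = all_row$population,
    cost_per_capita = all_row$cost_per_capita_total,
    allocation_per_capita = all_row$allocation_per_capita,
    funding_gap_per_capita = all_row$funding_gap_per_capita
  )
}

#' Plot the cost decomposition of a report
#'
#' Stacked bars of the cost of one EV by input category for each scope,
#' with the program's per-capita cost as a companion panel.
#'
#' @param object An `ev_cost_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ev_cost_report
#' @export
autoplot.ev_cost_report <- function(object, ...) {
  td <- tidy(object) |>
    dplyr::filter(.data$cost_item != "total") |>
    tidyr::pivot_longer(cols = c("cost_per_ev", "cost_per_capita"),
                        names_to = "measure", values_to = "usd") |>
    dplyr::mutate(measure = dplyr::recode(.data$measure,
      cost_per_ev = "Cost of one EV (USD)",
      cost_per_capita = "Program cost per capita (USD)"
    ))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$scope, y = .data$usd,
                                   fill = .data$cost_item)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "USD", fill = "Input category") +
    ggplot2::theme_minimal()
}
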