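#' Bundled Beijing community-health-center reference data (2010)
#'
#' Loads the packaged reference dataset from a 2010 expenditure-and-volume
#' costing study of 17 Beijing community health centers (7 urban, 10
#' suburban): the workload catalog of the 27 main primary-care services
#' with stratum-specific indicators in person-minutes, stratum-level annual
#' expenditure by input category with populations served, and the measured
#' EV totals of the five enumerated service categories per stratum. These
#' data ship as plain CSV under `inst/extdata/` so they remain
#' independently reviewable.
#'
#' Notes on the source values:
#' * Stratum populations are the published per-center averages times the
#'   center counts (117,687 x 7 and 47,260 x 10); the pooled population is
#'   stored as the published total 1,296,408 (the source also prints
#'   1,296,403 in one place; the per-capita figures are insensitive to the
#'   difference).
#' * The published pooled expenditure rows differ from the sum of their
#'   stratum columns by fractions of a dollar (display rounding); the
#'   pooled row of the aggregates uses the published pooled values.
#' * The urban "Infectious disease reporting and treatment" entry is
#'   stored as its published workload (5,913.63 person-minutes); its EV is
#'   derived by the 15-minute rule (394.24), since the published 94.24
#'   is inconsistent with the rule and with the suburban row, and is
#'   treated as a misprint.
#'
#' @param uplift_share Residual-services share used to build the
#'   aggregates; see [uplifted_total_ev()].
#' @return A list with elements:
#'   \describe{
#'     \item{catalog}{An `ev_catalog` of 27 services in 5 measured
#'       categories over strata `urban`, `suburban`.}
#'     \item{strata}{Tibble of stratum-level facility counts, populations,
#'       and expenditures, including the published pooled (`all`) row.}
#'     \item{category_ev}{Tibble of measured category EV totals per
#'       stratum.}
#'     \item{aggregates}{`ev_stratum_aggregates` built from the above.}
#'     \item{allocations}{Named vector of government per-capita
#'       allocations: 2.38 USD (2009), 3.97 USD (2011).}
#'   }
#' @export
#' @examples
#' fx <- beijing_fixture()
#' cost_report(fx$aggregates, allocation_per_capita = fx$allocations[["2011"]])
beijing_fixture <- function(uplift_share = 0.1) {
  path <- function(f) {
    system.file("extdata", f, package = "evcost", mustWork = TRUE)
  }
  cat <- read_catalog(path("beijing_catalog.csv"))
  strata <- readr::read_csv(path("beijing_strata.csv"),
                            show_col_types = FALSE, progress = FALSE)
  category_ev <- readr::read_csv(path("beijing_category_ev.csv"),
                                 show_col_types = FALSE, progress = FALSE)
  list(
    catalog = cat,
    strata = strata,
    category_ev = category_ev,
    aggregates = stratum_aggregates(strata, category_ev,
                                    uplift_share = uplift_share),
    allocations = c("2009" = 2.38, "2011" = 3.97)
  )
}
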