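fx <- beijing_fixture()
pub <- reporting_policy("published")
fullp <- reporting_policy("full_precision")

test_that("cost per EV reproduces the published totals and decomposition", {
  cpe <- cost_per_ev(fx$aggregates, pub)
  expect_equal(cpe$cost_per_ev_total[cpe$scope == "all"], 1.87)
  expect_equal(cpe$cost_per_ev_total[cpe$scope == "urban"], 1.71)
  expect_equal(cpe$cost_per_ev_total[cpe$scope == "suburban"], 2.05)
  expect_equal(cpe$cost_per_ev_human_resources,
               c(1.12, 1.38, 1.24)[match(cpe$scope,
                                         c("urban", "suburban", "all"))])
  expect_equal(cpe$cost_per_ev_materials[cpe$scope == "all"], 0.18)
  expect_equal(cpe$cost_per_ev_public_funds[cpe$scope == "all"], 0.45)
})

test_that("degenerate costing inputs behave as specified", {
  zero_exp <- stratum_aggregates(
    tibble::tibble(stratum = "urban", n_facilities = 1, population = 1000,
                   exp_human_resources = 0, exp_materials = 0,
                   exp_public_funds = 0),
    tibble::tibble(stratum = "urban", category = "nephsp",
                   measured_ev = 900)
  )
  cpe <- cost_per_ev(zero_exp, pub)
  expect_equal(cpe$cost_per_ev_total, c(0, 0))
  no_ev <- stratum_aggregates(
    tibble::tibble(stratum = "urban", n_facilities = 1, population = 1000,
                   exp_human_resources = 10, exp_materials = 0,
                   exp_public_funds = 0),
    tibble::tibble(stratum = "urban", category = "nephsp", measured_ev = 0)
  )
  expect_error(cost_per_ev(no_ev, pub), class = "evcost_error_domain",
               regexp = "urban")
})

test_that("program EV and share match the published program workload", {
  pe <- program_ev(fx$aggregates, "nephsp")
  expect_equal(pe$program_ev[pe$scope == "all"], 5514777)
  expect_equal(round_half_up(pe$program_share[pe$scope == "all"], 2), 39.23)
  expect_equal(pe$program_ev[pe$scope == "urban"], 3520967)
  expect_equal(round_half_up(pe$program_share[pe$scope == "urban"], 2),
               47.30)
  expect_equal(round_half_up(pe$program_share[pe$scope == "suburban"], 2),
               30.15)
  expect_error(program_ev(fx$aggregates, character(0)),
               class = "evcost_error_domain")
})

test_that("a program of every category at zero uplift covers all workload", {
  agg0 <- stratum_aggregates(fx$strata, fx$category_ev, uplift_share = 0)
  pe <- program_ev(agg0, ev_measured_categories())
  expect_equal(pe$program_share, rep(100, 3), tolerance = 1e-7)
})

test_that("program cost and per-capita chains match the published figures", {
  expect_equal(program_cost(5514777, 1.87, pub), 10312633)
  expect_equal(program_cost(0, 123, pub), 0)
  expect_equal(program_cost(1993810, 2.05, pub), 4087311)
  expect_equal(per_capita(10312633, 1296408, pub), 7.95)
  expect_equal(per_capita(program_cost(3520967, 1.71, pub), 823809, pub),
               7.31)
  expect_equal(per_capita(0, 5, pub), 0)
  expect_error(per_capita(1, 0, pub), class = "evcost_error_domain")
})

test_that("funding gap is a signed difference of per-capita amounts", {
  expect_equal(funding_gap(7.95, 3.97), 3.98)
  expect_equal(funding_gap(5, 5), 0)
  expect_equal(funding_gap(7.95, 2.38), 5.57)
  expect_lt(funding_gap(2, 3), 0) # surplus is allowed
})

test_that("the full report reproduces the published per-capita costs", {
  rep <- cost_report(fx$aggregates, policy = pub,
                     allocation_per_capita = 3.97)
  r <- as_tibble(rep)
  expect_equal(r$cost_per_capita_total,
               c(7.31, 8.65, 7.95)[match(r$scope,
                                         c("urban", "suburban", "all"))])
  expect_equal(r$program_cost[r$scope == "all"], 10312633)
  expect_equal(r$funding_gap_per_capita[r$scope == "all"], 3.98)
})

test_that("category decompositions are conserved at full precision", {
  check <- function(agg) {
    rep <- as_tibble(cost_report(agg, policy = fullp))
    cats <- paste0("cost_per_ev_", expenditure_categories())
    expect_equal(rowSums(as.data.frame(rep)[, cats]), rep$cost_per_ev_total,
                 tolerance = 1e-12)
    pc_cats <- paste0("cost_per_capita_", expenditure_categories())
    expect_equal(rowSums(as.data.frame(rep)[, pc_cats]),
                 rep$cost_per_capita_total, tolerance = 1e-12)
    # shares over all six service categories account for all workload
    share_cols <- c(paste0("ev_", ev_measured_categories()), "ev_other")
    shares <- rowSums(as.data.frame(agg)[, share_cols]) / agg$total_ev * 100
    expect_equal(shares, rep(100, nrow(agg)), tolerance = 1e-4)
  }
  check(fx$aggregates)
  gen <- generate_panel(synthetic_config(seed = 5))
  check(aggregate_facilities(gen$panel, gen$catalog))
})

test_that("costs are homogeneous in expenditure and volume scaling", {
  gen <- generate_panel(synthetic_config(seed = 9))
  base <- as_tibble(cost_report(gen$panel, gen$catalog, policy = fullp))
  k <- 1.75
  fac_k <- gen$panel$facilities
  for (col in paste0("exp_", expenditure_categories())) {
    fac_k[[col]] <- fac_k[[col]] * k
  }
  scaled_exp <- as_tibble(cost_report(facility_panel(fac_k,
                                                     gen$panel$volumes),
                                      gen$catalog, policy = fullp))
  expect_equal(scaled_exp$cost_per_ev_total, k * base$cost_per_ev_total,
               tolerance = 1e-12)
  expect_equal(scaled_exp$cost_per_capita_total,
               k * base$cost_per_capita_total, tolerance = 1e-12)

  vol_k <- gen$panel$volumes
  vol_k$volume <- vol_k$volume * k
  scaled_vol <- as_tibble(cost_report(facility_panel(gen$panel$facilities,
                                                     vol_k),
                                      gen$catalog, policy = fullp))
  expect_equal(scaled_vol$program_ev, k * base$program_ev,
               tolerance = 1e-9)
  expect_equal(scaled_vol$cost_per_ev_total, base$cost_per_ev_total / k,
               tolerance = 1e-6) # integer rounding of the uplifted total
})

test_that("full reports agree with the first-principles oracle", {
  for (seed in 1:6) {
    case <- random_small_panel(seed, n_fac = 2 + seed %% 4,
                               n_svc = 2 + (seed * 2) %% 4)
    rep <- as_tibble(cost_report(case$panel, case$catalog, policy = fullp))
    orc <- oracle_report(case$panel$facilities, case$panel$volumes,
                         case$services, c("urban", "suburban"))
    for (sc in names(orc)) {
      row <- rep[rep$scope == sc, ]
      expect_equal(row$total_ev, orc[[sc]]$total_ev)
      expect_equal(row$cost_per_ev_total, orc[[sc]]$cost_per_ev,
                   tolerance = 1e-12)
      expect_equal(row$program_ev, orc[[sc]]$program_ev,
                   tolerance = 1e-12)
      expect_equal(row$cost_per_capita_total, orc[[sc]]$cost_per_capita,
                   tolerance = 1e-12)
    }
  }
})

test_that("tidy, glance, as_tibble and autoplot expose the report", {
  rep <- cost_report(fx$aggregates, allocation_per_capita = 3.97)
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3 * 4) # three scopes x four cost items
  expect_setequal(unique(td$cost_item),
                  c(expenditure_categories(), "total"))
  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$cost_per_ev, 1.87)
  expect_equal(gl$funding_gap_per_capita, 3.98)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_output(print(rep), "funding gap")
})
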