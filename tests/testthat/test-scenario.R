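fullp <- reporting_policy("full_precision")

gen <- generate_panel(synthetic_config(seed = 21))

test_that("the identity scenario is a fixed point of the pipeline", {
  out <- apply_scenario(gen$panel, gen$catalog, scenario("identity"))
  expect_equal(out$panel$facilities, gen$panel$facilities)
  expect_equal(out$panel$volumes, gen$panel$volumes)
  expect_equal(out$catalog$services, gen$catalog$services)
  base <- as_tibble(cost_report(gen$panel, gen$catalog, policy = fullp))
  again <- as_tibble(cost_report(out$panel, out$catalog, policy = fullp))
  expect_equal(again, base)
})

test_that("uniform expenditure multipliers scale the cost per EV", {
  scn <- scenario("prices +10%", expenditure_multipliers = c(
    human_resources = 1.10, materials = 1.10, public_funds = 1.10
  ))
  out <- apply_scenario(gen$panel, gen$catalog, scn)
  base <- as_tibble(cost_report(gen$panel, gen$catalog, policy = fullp))
  rep <- as_tibble(cost_report(out$panel, out$catalog, policy = fullp))
  expect_equal(rep$cost_per_ev_total, 1.10 * base$cost_per_ev_total,
               tolerance = 1e-12)
  # inputs are untouched (pure transformation)
  expect_equal(as_tibble(cost_report(gen$panel, gen$catalog,
                                     policy = fullp)), base)
})

test_that("an added 30-minute service adds exactly 2 EV per unit volume", {
  v_urban <- 5000
  v_suburban <- 3000
  scn <- scenario("new program service", added_services = list(list(
    service = list(service_id = "new_screening", name = "New screening",
                   category = "nephsp", delivery_unit = "per visit",
                   workload = list(urban = 30, suburban = 30)),
    volume = list(urban = v_urban, suburban = v_suburban)
  )))
  out <- apply_scenario(gen$panel, gen$catalog, scn)
  base <- as_tibble(cost_report(gen$panel, gen$catalog, policy = fullp))
  rep <- as_tibble(cost_report(out$panel, out$catalog, policy = fullp))
  expect_equal(rep$program_ev[rep$scope == "urban"] -
                 base$program_ev[base$scope == "urban"], 2 * v_urban)
  expect_equal(rep$program_ev[rep$scope == "all"] -
                 base$program_ev[base$scope == "all"],
               2 * (v_urban + v_suburban))
  # incremental program cost has the closed form delta_EV x new cost per EV
  delta <- incremental_cost(
    cost_report(gen$panel, gen$catalog, policy = fullp),
    cost_report(out$panel, out$catalog, policy = fullp)
  )
  d_all <- delta[delta$scope == "all", ]
  cpe_new <- rep$cost_per_ev_total[rep$scope == "all"]
  manual <- rep$program_ev[rep$scope == "all"] * cpe_new -
    base$program_ev[base$scope == "all"] *
      base$cost_per_ev_total[base$scope == "all"]
  expect_equal(d_all$delta_program_cost, manual, tolerance = 1e-9)
})

test_that("adding a zero-volume service changes no cost output", {
  scn <- scenario("ghost service", added_services = list(list(
    service = list(service_id = "ghost", name = "Ghost",
                   category = "nephsp", delivery_unit = "per visit",
                   workload = list(urban = 30, suburban = 30)),
    volume = list(urban = 0, suburban = 0)
  )))
  out <- apply_scenario(gen$panel, gen$catalog, scn)
  base <- as_tibble(cost_report(gen$panel, gen$catalog, policy = fullp))
  rep <- as_tibble(cost_report(out$panel, out$catalog, policy = fullp))
  expect_equal(rep, base)
})

test_that("multiplicative scenarios compose as their product", {
  s1 <- scenario("a", expenditure_multipliers = c(human_resources = 1.2),
                 volume_multipliers = c(nephsp = 1.5),
                 population_multiplier = 1.1)
  s2 <- scenario("b", expenditure_multipliers = c(human_resources = 1.25),
                 volume_multipliers = c(nephsp = 0.8),
                 population_multiplier = 2)
  s12 <- scenario("ab",
                  expenditure_multipliers = c(human_resources = 1.2 * 1.25),
                  volume_multipliers = c(nephsp = 1.5 * 0.8),
                  population_multiplier = 1.1 * 2)
  chained <- apply_scenario(gen$panel, gen$catalog, s1)
  chained <- apply_scenario(chained$panel, chained$catalog, s2)
  direct <- apply_scenario(gen$panel, gen$catalog, s12)
  expect_equal(chained$panel$facilities, direct$panel$facilities,
               tolerance = 1e-12)
  expect_equal(chained$panel$volumes, direct$panel$volumes,
               tolerance = 1e-12)
})

test_that("volume multipliers accept categories and service ids only", {
  one_svc <- gen$catalog$services$service_id[1]
  out <- apply_scenario(gen$panel, gen$catalog,
                        scenario("one", volume_multipliers =
                                   stats::setNames(2, one_svc)))
  expect_equal(
    sum(out$panel$volumes$volume[out$panel$volumes$service_id == one_svc]),
    2 * sum(gen$panel$volumes$volume[gen$panel$volumes$service_id ==
                                       one_svc])
  )
  expect_error(
    apply_scenario(gen$panel, gen$catalog,
                   scenario("bad", volume_multipliers = c(nonsense = 2))),
    class = "evcost_error_schema"
  )
})

test_that("workload overrides rewrite the catalog and reject unknown ids", {
  svc <- gen$catalog$services$service_id[3]
  scn <- scenario("protocol revision", workload_overrides = tibble::tibble(
    service_id = svc, stratum = "urban", workload = 45
  ))
  out <- apply_scenario(gen$panel, gen$catalog, scn)
  expect_equal(
    out$catalog$services$workload_urban[
      out$catalog$services$service_id == svc], 45
  )
  expect_error(
    apply_scenario(gen$panel, gen$catalog,
                   scenario("x", workload_overrides = tibble::tibble(
                     service_id = "nope", stratum = "urban", workload = 10
                   ))),
    class = "evcost_error_schema", regexp = "nope"
  )
})

test_that("scenario invariants are validated at construction", {
  expect_error(scenario(expenditure_multipliers = c(human_resources = 0)),
               class = "evcost_error_domain")
  expect_error(scenario(expenditure_multipliers = c(rent = 1.1)),
               class = "evcost_error_schema")
  expect_error(scenario(population_multiplier = -1),
               class = "evcost_error_domain")
  expect_error(scenario(workload_overrides = tibble::tibble(
    service_id = "a", stratum = "urban", workload = 0
  )), class = "evcost_error_domain")
})

test_that("incremental cost differences reports field by field", {
  base <- cost_report(gen$panel, gen$catalog, policy = fullp,
                      allocation_per_capita = 2.38)
  same <- incremental_cost(base, base)
  expect_true(all(vapply(same[-1], function(x) all(x == 0), logical(1))))
  higher <- cost_report(gen$panel, gen$catalog, policy = fullp,
                        allocation_per_capita = 3.97)
  delta <- incremental_cost(base, higher)
  expect_equal(delta$delta_funding_gap_per_capita,
               rep(-1.59, nrow(delta)))
  expect_equal(delta$delta_cost_per_capita_total, rep(0, nrow(delta)))
  # scope mismatch is refused
  urban_only <- facility_panel(
    gen$panel$facilities[gen$panel$facilities$stratum == "urban", ],
    dplyr::semi_join(gen$panel$volumes,
                     gen$panel$facilities[gen$panel$facilities$stratum ==
                                            "urban", ],
                     by = "facility_id")
  )
  rep_urban <- cost_report(urban_only, gen$catalog, policy = fullp)
  expect_error(incremental_cost(base, rep_urban),
               class = "evcost_error_domain")
})

test_that("scenarios load from YAML and JSON", {
  ypath <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "name: repriced",
    "expenditure_multipliers:",
    "  human_resources: 1.15",
    "volume_multipliers:",
    "  nephsp: 1.2",
    "workload_overrides:",
    "  - service_id: basic_medical_01",
    "    stratum: urban",
    "    workload: 20",
    "allocation_per_capita: 3.97",
    "population_multiplier: 1.05"
  ), ypath)
  scn <- read_scenario(ypath)
  expect_s3_class(scn, "ev_scenario")
  expect_equal(scn$expenditure_multipliers[["human_resources"]], 1.15)
  expect_equal(nrow(scn$workload_overrides), 1)
  expect_equal(scn$allocation_per_capita, 3.97)

  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    name = "from json",
    volume_multipliers = list(nephsp = 1.3)
  ), jpath, auto_unbox = TRUE)
  scn2 <- read_scenario(jpath)
  expect_equal(scn2$volume_multipliers[["nephsp"]], 1.3)
  out <- apply_scenario(gen$panel, gen$catalog, scn2)
  expect_s3_class(out$panel, "ev_facility_panel")
})
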