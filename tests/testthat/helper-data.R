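# Small in-code fixtures used across test files.

tiny_catalog <- function() {
  catalog(tibble::tibble(
    service_id = c("visit", "home_visit", "records", "jab"),
    name = c("Clinic visit", "Home visit", "Records", "Immunization"),
    category = c("basic_medical", "basic_medical", "nephsp", "nephsp"),
    delivery_unit = c("per visit", "per visit", "per person year",
                      "per visit"),
    workload_urban = c(15, 60, 90, 24),
    workload_suburban = c(15, 60, 120, 18)
  ))
}

tiny_panel <- function() {
  facility_panel(
    tibble::tibble(
      facility_id = c("u1", "u2", "s1"),
      stratum = c("urban", "urban", "suburban"),
      population_served = c(50000, 80000, 40000),
      n_employees = c(100, 150, 80),
      exp_human_resources = c(600000, 900000, 500000),
      exp_materials = c(100000, 120000, 90000),
      exp_public_funds = c(200000, 260000, 160000)
    ),
    tibble::tibble(
      facility_id = c("u1", "u1", "u1", "u2", "u2", "s1", "s1"),
      service_id = c("visit", "home_visit", "records", "visit", "jab",
                     "visit", "records"),
      volume = c(10000, 500, 2000, 15000, 3000, 8000, 1200)
    )
  )
}

# Independent of the synthetic_data module: arbitrary small panels for
# oracle-equivalence checks.
random_small_panel <- function(seed, n_fac = 4, n_svc = 4) {
  set.seed(seed)
  cats <- sample(c("basic_medical", "nursing", "nephsp"), n_svc,
                 replace = TRUE)
  cats[1] <- "nephsp" # ensure the program is non-empty
  services <- tibble::tibble(
    service_id = sprintf("svc%02d", seq_len(n_svc)),
    name = sprintf("Service %d", seq_len(n_svc)),
    category = cats,
    delivery_unit = "per unit",
    workload_urban = runif(n_svc, 5, 200),
    workload_suburban = runif(n_svc, 5, 200)
  )
  strata <- rep(c("urban", "suburban"), length.out = n_fac)
  fac <- tibble::tibble(
    facility_id = sprintf("fac%02d", seq_len(n_fac)),
    stratum = strata,
    population_served = round(runif(n_fac, 10000, 90000)),
    n_employees = round(runif(n_fac, 40, 150)),
    exp_human_resources = runif(n_fac, 1e5, 9e5),
    exp_materials = runif(n_fac, 1e4, 2e5),
    exp_public_funds = runif(n_fac, 5e4, 4e5)
  )
  vol <- tidyr::crossing(facility_id = fac$facility_id,
                         service_id = services$service_id)
  vol$volume <- round(runif(nrow(vol), 0, 20000))
  list(catalog = catalog(services), panel = facility_panel(fac, vol),
       services = services)
}
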