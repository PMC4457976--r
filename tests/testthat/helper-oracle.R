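# Straight-line, loop-based recomputation of the full costing chain from
# first principles, kept independent of the package's aggregation and
# reporting code paths. Full precision only.
oracle_report <- function(fac, vol, services, strata_labels,
                          benchmark_minutes = 15, uplift = 0.1,
                          program_category = "nephsp") {
  scopes <- c(strata_labels, "all")
  out <- list()
  for (sc in scopes) {
    fids <- if (sc == "all") fac$facility_id else {
      fac$facility_id[fac$stratum == sc]
    }
    measured <- 0
    prog <- 0
    for (i in seq_len(nrow(vol))) {
      fid <- vol$facility_id[i]
      if (!fid %in% fids) next
      st <- fac$stratum[match(fid, fac$facility_id)]
      j <- match(vol$service_id[i], services$service_id)
      ev <- services[[paste0("workload_", st)]][j] / benchmark_minutes
      amount <- vol$volume[i] * ev
      measured <- measured + amount
      if (services$category[j] == program_category) prog <- prog + amount
    }
    total_ev <- floor(measured / (1 - uplift) + 0.5)
    keep <- fac$facility_id %in% fids
    exp_total <- sum(fac$exp_human_resources[keep]) +
      sum(fac$exp_materials[keep]) + sum(fac$exp_public_funds[keep])
    pop <- sum(fac$population_served[keep])
    cpe <- exp_total / total_ev
    prog_cost <- prog * cpe
    out[[sc]] <- list(
      measured_ev = measured, total_ev = total_ev, cost_per_ev = cpe,
      program_ev = prog, program_share = prog / total_ev * 100,
      program_cost = prog_cost, cost_per_capita = prog_cost / pop
    )
  }
  out
}
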