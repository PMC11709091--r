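test_that("cohort generation honors the six-group design", {
    donors <- generateCohort(cohortSpec(), seed = 1)
    expect_equal(nrow(donors), 120L)
    expect_equal(unname(table(donors$group)[groupLabels()]),
                 rep(20L, 6L), ignore_attr = TRUE)
    # ages stay inside each group's configured range
    spec <- cohortSpec()
    for (g in groupLabels()) {
        a <- donors$age_years[donors$group == g]
        expect_true(all(a >= spec$age_ranges[[g]][1] &
                        a <= spec$age_ranges[[g]][2]))
    }
    expect_equal(nrow(generateCohort(cohortSpec(donors_per_group = 1,
                                               pools_per_group_plasma = 1,
                                               pools_per_group_proteomics = 1,
                                               donors_per_pool = 1),
                                     seed = 1)), 6L)
})

test_that("cohort generation is deterministic under a fixed seed", {
    expect_identical(generateCohort(cohortSpec(), seed = 7),
                     generateCohort(cohortSpec(), seed = 7))
    expect_false(identical(generateCohort(cohortSpec(), seed = 7),
                           generateCohort(cohortSpec(), seed = 8)))
})

test_that("pooling partitions donors into balanced disjoint pools", {
    spec <- cohortSpec()
    donors <- generateCohort(spec, seed = 2)
    pools <- makePools(donors, spec)
    expect_equal(nrow(pools), 30L)
    expect_equal(sum(pools$proteomics), 18L)
    expect_equal(unique(lengths(pools$donor_ids)), 4L)
    # disjoint: every donor appears in exactly one pool
    all_donors <- unlist(pools$donor_ids)
    expect_false(anyDuplicated(all_donors) > 0)
    # age balance: spread of pool mean ages bounded by donor age spread
    for (g in groupLabels()) {
        pg <- pools[pools$group == g, ]
        dg <- donors$age_years[donors$group == g]
        expect_lte(max(pg$mean_age) - min(pg$mean_age),
                   max(dg) - min(dg))
    }
})

test_that("singleton pools and shortfalls behave as specified", {
    spec1 <- cohortSpec(donors_per_group = 5, donors_per_pool = 1,
                        pools_per_group_plasma = 5,
                        pools_per_group_proteomics = 3)
    donors <- generateCohort(spec1, seed = 3)
    pools <- makePools(donors, spec1)
    expect_equal(unique(lengths(pools$donor_ids)), 1L)

    spec2 <- cohortSpec()
    short <- generateCohort(spec2, seed = 3)
    short <- short[-which(short$group == "M.old")[1], ]
    expect_error(makePools(short, spec2), "M.old.*1 donors")
    expect_error(cohortSpec(donors_per_group = 10), "not enough donors")
})

test_that("noise-free simulation collapses to baselines and exact ratios", {
    spec <- cohortSpec()
    pools <- makePools(generateCohort(spec, seed = 4), spec)
    eff0 <- effectSpec(n_proteins = 40, frac_ev_enriched = 0,
                       frac_prot_enriched = 0, donor_sd_log2 = 0,
                       tech_sd_log2 = 0, lod_log2 = -Inf)
    sim0 <- simulateAbundance(pools, eff0, seed = 5)
    expect_equal(abundance(sim0$ev), abundance(sim0$prot))
    # every pool equals the protein baseline
    expect_equal(log2(abundance(sim0$ev)),
                 matrix(sim0$truth$baseline_log2, nrow = 40, ncol = 18,
                        dimnames = dimnames(abundance(sim0$ev))))

    eff2 <- effectSpec(n_proteins = 40, frac_ev_enriched = 0.5,
                       frac_prot_enriched = 0, ev_enrichment_log2 = 2,
                       donor_sd_log2 = 0, tech_sd_log2 = 0,
                       lod_log2 = -Inf)
    sim2 <- simulateAbundance(pools, eff2, seed = 5)
    enriched <- sim2$truth$protein[sim2$truth$fraction_class == "EV"]
    ratio <- abundance(sim2$ev)[enriched, ] /
        abundance(sim2$prot)[enriched, ]
    expect_equal(unname(ratio),
                 matrix(4, nrow = length(enriched), ncol = 18))
})

test_that("zero noise and zero effects yield no DE calls at all", {
    spec <- cohortSpec()
    pools <- makePools(generateCohort(spec, seed = 4), spec)
    eff0 <- effectSpec(n_proteins = 30, frac_ev_enriched = 0,
                       frac_prot_enriched = 0, donor_sd_log2 = 0,
                       tech_sd_log2 = 0, lod_log2 = -Inf)
    sim0 <- simulateAbundance(pools, eff0, seed = 9)
    de <- pairedFractionDE(sim0$ev, sim0$prot)
    expect_true(all(de$verdict == "not_DE"))
    plan <- suppressWarnings(runPlan(sim0$ev, sim0$prot))
    expect_equal(sum(plan$summary$n_DE), 0L)
})

test_that("pooling attenuates donor-level variance", {
    spec <- cohortSpec()
    pools <- makePools(generateCohort(spec, seed = 6), spec)
    eff <- effectSpec(n_proteins = 400, frac_ev_enriched = 0,
                      frac_prot_enriched = 0, donor_sd_log2 = 0.8,
                      tech_sd_log2 = 0, lod_log2 = -Inf,
                      baseline_sd_log2 = 0)
    sim <- simulateAbundance(pools, eff, seed = 7)
    pool_var <- mean(apply(log2(abundance(sim$ev)), 1, var))
    # pools of 4 donors: variance well below the donor-level 0.64
    expect_lt(pool_var, 0.8^2)
    expect_gt(pool_var, 0)
})

test_that("simulation is deterministic and ground truth labels align", {
    spec <- cohortSpec()
    pools <- makePools(generateCohort(spec, seed = 8), spec)
    eff <- effectSpec(n_proteins = 50)
    s1 <- simulateAbundance(pools, eff, seed = 11)
    s2 <- simulateAbundance(pools, eff, seed = 11)
    expect_identical(abundance(s1$ev), abundance(s2$ev))
    expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))
    expect_equal(sum(s1$truth$fraction_class == "EV"),
                 round(0.35 * 50))
})

test_that("particle simulation recovers group means and offsets", {
    spec <- cohortSpec()
    pools <- makePools(generateCohort(spec, seed = 1), spec)
    m0 <- simulateParticles(pools, group_mean = 3e9, cv = 0,
                            instruments = "NTA", seed = 2)
    norm <- normalizeParticles(m0)
    expect_equal(norm$particles_per_mL_plasma, rep(3e9, nrow(pools)))

    gm <- stats::setNames(rep(2e9, 6), groupLabels())
    gm["M.mid"] <- 4e9
    m1 <- simulateParticles(pools, group_mean = gm, cv = 0.1,
                            instruments = "NFCM", seed = 3)
    norm1 <- normalizeParticles(m1)
    norm1$group <- pools$group[match(norm1$pool_id, pools$pool_id)]
    means <- tapply(norm1$particles_per_mL_plasma, norm1$group, mean)
    expect_true(all(means["M.mid"] > means[setdiff(groupLabels(), "M.mid")]))

    expect_identical(simulateParticles(pools, seed = 5),
                     simulateParticles(pools, seed = 5))
})

test_that("simulated analytes reproduce the female HDL elevation", {
    donors <- generateCohort(cohortSpec(), seed = 10)
    an <- simulateAnalytes(donors, seed = 11)
    hdl <- tapply(an[["HDL (mg/dL)"]], an$group, mean)
    for (a in c("young", "mid", "old")) {
        expect_gt(hdl[[paste0("F.", a)]], hdl[[paste0("M.", a)]])
    }
})

test_that("effect specifications are validated", {
    expect_error(effectSpec(frac_ev_enriched = 0.7,
                            frac_prot_enriched = 0.5), "<= 1")
    expect_error(effectSpec(donor_sd_log2 = -1), "non-negative")
    expect_error(effectSpec(age_affected = data.frame(protein = "PR0001",
                                                      young = 1, mid = 0,
                                                      old = 0)),
                 "sex_scope")
})
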