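#' Default pipeline configuration
#'
#' All tunables of the end-to-end run in one serializable list:
#' simulation design and effect structure, the detection-filter
#' threshold, the comparison plan options, set-analysis and clustering
#' options, and the top-level seed from which every stage's seed is
#' derived deterministically.
#'
#' @param seed Top-level integer seed.
#' @param out_dir Output directory for the report bundle.
#' @return A nested configuration list.
#' @export
defaultConfig <- function(seed = 1L, out_dir = tempfile("poolfrac_run_")) {
    list(
        seed = as.integer(seed),
        out_dir = out_dir,
        cohort = list(donors_per_group = 20L, pools_per_group_plasma = 5L,
                      pools_per_group_proteomics = 3L, donors_per_pool = 4L),
        effects = list(n_proteins = 1000L, frac_ev_enriched = 0.35,
                       frac_prot_enriched = 0.1, ev_enrichment_log2 = 2,
                       donor_sd_log2 = 0.5, tech_sd_log2 = 0.2,
                       lod_log2 = 16, baseline_mean_log2 = 20,
                       baseline_sd_log2 = 2),
        filter_threshold = 0.8,
        min_comparisons = 2L,
        clustering = list(distance = "correlation", linkage = "average",
                          cut_k = 3L)
    )
}

.mergeConfig <- function(base, override) {
    for (nm in names(override)) {
        if (is.list(base[[nm]]) && is.list(override[[nm]])) {
            base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
        } else {
            base[[nm]] <- override[[nm]]
        }
    }
    base
}

#' Run the full pipeline
#'
#' Simulate (or load) paired EV/PROT abundance tables, apply the
#' detection filter, run the full ratio-sign-consistency comparison
#' plan, derive the set-analysis protein lists, compute particle and
#' analyte group statistics, and cluster the age-dynamic proteins.
#' Every intermediate table is written to the output directory as TSV
#' together with a human-readable \code{summary.txt}, a copy of the
#' configuration, and a run log (stage, seed, row counts). Two runs
#' with the same configuration and seed produce byte-identical bundles.
#'
#' @param config A configuration list (see [defaultConfig()]) or a path
#'   to a YAML file with the same structure; partial configurations are
#'   completed with defaults.
#' @return Invisibly, a list with all stage outputs (\code{sim},
#'   \code{filtered}, \code{plan}, \code{sets}, \code{venn},
#'   \code{particle_stats}, \code{analyte_stats}, \code{clustering},
#'   \code{summary_lines}).
#' @export
runPipeline <- function(config = defaultConfig()) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    config <- .mergeConfig(defaultConfig(), config)
    out <- config$out_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    log_lines <- character()
    note <- function(stage, detail) {
        log_lines <<- c(log_lines, sprintf("%s\t%s", stage, detail))
    }
    yaml::write_yaml(config, file.path(out, "config.yaml"))

    # --- simulate -----------------------------------------------------
    cspec <- do.call(cohortSpec, config$cohort)
    espec <- do.call(effectSpec, config$effects)
    donors <- generateCohort(cspec, seed = deriveSeed(config$seed, "cohort"))
    pools <- makePools(donors, cspec)
    sim <- simulateAbundance(pools, espec,
                             seed = deriveSeed(config$seed, "abundance"))
    particles <- simulateParticles(pools,
                                   seed = deriveSeed(config$seed,
                                                     "particles"))
    analytes <- simulateAnalytes(donors,
                                 seed = deriveSeed(config$seed, "analytes"))
    utils::write.table(donors, file.path(out, "donors.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writePoolMetadata(pools, file.path(out, "pools.tsv"))
    writeAbundance(sim$ev, file.path(out, "ev.tsv"))
    writeAbundance(sim$prot, file.path(out, "prot.tsv"))
    writeResultTable(as.data.frame(sim$truth),
                     file.path(out, "ground_truth.tsv"))
    utils::write.table(particles, file.path(out, "particles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeAnalyteTable(analytes, file.path(out, "analytes.tsv"))
    note("simulate", sprintf("donors=%d pools=%d proteins=%d seed=%d",
                             nrow(donors), nrow(pools), nrow(sim$ev),
                             config$seed))

    # --- detection filter --------------------------------------------
    filt <- lapply(list(EV = sim$ev, PROT = sim$prot), detectionFilter,
                   threshold = config$filter_threshold)
    for (frac in names(filt)) {
        writeResultTable(filterReportTable(filt[[frac]]$report),
                         file.path(out, sprintf("filter_%s.tsv", frac)))
    }
    ev_f <- filt$EV$table
    prot_f <- filt$PROT$table
    note("filter", sprintf("EV=%d/%d PROT=%d/%d",
                           nrow(ev_f), nrow(sim$ev),
                           nrow(prot_f), nrow(sim$prot)))

    # --- fraction Venn -----------------------------------------------
    venn <- vennSummary(list(EV = rownames(ev_f), PROT = rownames(prot_f)))
    writeResultTable(data.frame(region = names(venn$region_counts),
                                count = unname(venn$region_counts),
                                percent = unname(venn$region_percentages)),
                     file.path(out, "venn_fractions.tsv"))

    # --- comparison plan ---------------------------------------------
    plan <- runPlan(ev_f, prot_f,
                    expected_pools = config$cohort$pools_per_group_proteomics)
    for (frac in names(plan$results)) {
        for (lab in names(plan$results[[frac]])) {
            fn <- sprintf("de_%s_%s.tsv", frac, gsub("[:]", "_", lab))
            writeResultTable(as.data.frame(plan$results[[frac]][[lab]]),
                             file.path(out, fn))
        }
    }
    writeResultTable(plan$summary, file.path(out, "de_summary.tsv"))
    note("de", sprintf("comparisons=%d", nrow(plan$summary)))

    # --- set analysis ------------------------------------------------
    age_labels <- comparisonPlan()
    age_labels <- age_labels[age_labels$type == "age", ]
    sets <- list()
    for (frac in names(plan$results)) {
        res <- plan$results[[frac]]
        by_sex <- lapply(c(M = "M", F = "F"), function(s) {
            labs <- age_labels$label[startsWith(age_labels$label,
                                                paste0(s, ":"))]
            res[labs]
        })
        dyn <- lapply(by_sex, ageDynamicProteins,
                      min_comparisons = config$min_comparisons)
        common <- sexCommonAgeProteins(by_sex$M, by_sex$F,
                                       dyn$M, dyn$F)
        sex_labels <- sprintf("%s:M_vs_F", .VALID_AGE)
        sex_consistent <- sexConsistentAcrossAges(res[sex_labels])
        sets[[frac]] <- list(dynamic = dyn, sex_common = common,
                             sex_consistent = sex_consistent)
        for (s in c("M", "F")) {
            writeGeneList(dyn[[s]],
                          file.path(out, sprintf("age_dynamic_%s_%s.txt",
                                                 frac, s)))
        }
        writeGeneList(common,
                      file.path(out, sprintf("sex_common_age_%s.txt", frac)))
        writeGeneList(sex_consistent,
                      file.path(out, sprintf("sex_consistent_%s.txt", frac)))
    }
    note("sets", sprintf("EV dynamic M/F=%d/%d",
                         length(sets$EV$dynamic$M),
                         length(sets$EV$dynamic$F)))

    # --- group statistics --------------------------------------------
    particle_stats <- particleGroupStats(particles, pools)
    for (inst in names(particle_stats)) {
        writeResultTable(particle_stats[[inst]]$pairs,
                         file.path(out, sprintf("lsd_particles_%s.tsv",
                                                inst)))
    }
    analyte_cols <- setdiff(colnames(analytes), c("sample_id", "group"))
    analyte_stats <- lapply(stats::setNames(analyte_cols, analyte_cols),
                            function(cl) fisherLSD(analytes[[cl]],
                                                   analytes$group))
    for (cl in analyte_cols) {
        safe <- gsub("[^A-Za-z0-9]+", "_", cl)
        writeResultTable(analyte_stats[[cl]]$pairs,
                         file.path(out, sprintf("lsd_analyte_%s.tsv", safe)))
    }
    note("stats", sprintf("instruments=%d analytes=%d",
                          length(particle_stats), length(analyte_cols)))

    # --- clustering of EV male age-dynamic proteins -------------------
    clus <- NULL
    dyn_ev_m <- sets$EV$dynamic$M
    male_pools <- colnames(ev_f)[colData(ev_f)$sex == "M"]
    a <- abundance(ev_f)
    complete <- dyn_ev_m[!is.na(rowSums(a[dyn_ev_m, male_pools,
                                          drop = FALSE]))]
    if (length(complete) >= 2L && length(male_pools) >= 2L) {
        clus <- clusterHeatmap(ev_f[, male_pools], complete,
                               distance = config$clustering$distance,
                               linkage = config$clustering$linkage,
                               cut_k = config$clustering$cut_k)
        writeDendrogram(clus@row_hclust,
                        file.path(out, "cluster_rows.nwk"))
        writeDendrogram(clus@col_hclust,
                        file.path(out, "cluster_cols.nwk"))
        writeResultTable(data.frame(pool_id = names(clus@col_clusters),
                                    cluster = unname(clus@col_clusters)),
                         file.path(out, "cluster_pool_labels.tsv"))
        zdf <- data.frame(protein = rownames(clus@z), clus@z,
                          check.names = FALSE)
        writeResultTable(zdf, file.path(out, "cluster_zmatrix.tsv"))
        note("cluster", sprintf("proteins=%d pools=%d", nrow(clus@z),
                                ncol(clus@z)))
    } else {
        note("cluster", "skipped: fewer than 2 clusterable proteins")
    }

    # --- summary ------------------------------------------------------
    m <- config$cohort$pools_per_group_proteomics
    null_rate <- nullConsistencyRate(m, m)
    age_rows <- plan$summary[plan$summary$type == "age", , drop = FALSE]
    obs_rate <- age_rows$n_DE / pmax(1L, age_rows$n_evaluable)
    lines <- c(
        "poolfrac pipeline summary",
        sprintf("seed: %d", config$seed),
        sprintf("protein universes after detection filter (> %g): EV %d, PROT %d",
                config$filter_threshold, nrow(ev_f), nrow(prot_f)),
        sprintf("fraction Venn: %s",
                paste(sprintf("%s %d (%.1f%%)", names(venn$region_counts),
                              venn$region_counts, venn$region_percentages),
                      collapse = ", ")),
        "",
        "DE counts per comparison (n_DE = n_up + n_down):",
        sprintf("  %-5s %-16s DE=%-5d up=%-5d down=%-5d evaluable=%d",
                plan$summary$fraction, plan$summary$label,
                plan$summary$n_DE, plan$summary$n_up,
                plan$summary$n_down, plan$summary$n_evaluable),
        "",
        sprintf("analytic null DE rate at %d vs %d pools: %.4g", m, m,
                null_rate),
        sprintf("observed DE rate across age comparisons: mean %.4f (range %.4f-%.4f)",
                mean(obs_rate), min(obs_rate), max(obs_rate)),
        sprintf("paired-rule null at %d pools: %.4g", 6L * m,
                nullPairedRate(6L * m)),
        "",
        sprintf("age-dynamic proteins (>= %d of 3 comparisons): EV M=%d F=%d; PROT M=%d F=%d",
                config$min_comparisons,
                length(sets$EV$dynamic$M), length(sets$EV$dynamic$F),
                length(sets$PROT$dynamic$M), length(sets$PROT$dynamic$F)),
        sprintf("sex-common age proteins: EV %d, PROT %d",
                length(sets$EV$sex_common), length(sets$PROT$sex_common)),
        sprintf("sex-consistent proteins across ages: EV %d, PROT %d",
                length(sets$EV$sex_consistent),
                length(sets$PROT$sex_consistent))
    )
    writeLines(lines, file.path(out, "summary.txt"))
    writeLines(log_lines, file.path(out, "run.log"))
    invisible(list(config = config, sim = sim, pools = pools,
                   donors = donors, filtered = list(EV = ev_f,
                                                    PROT = prot_f),
                   filter_reports = lapply(filt, `[[`, "report"),
                   venn = venn, plan = plan, sets = sets,
                   particle_stats = particle_stats,
                   analyte_stats = analyte_stats,
                   clustering = clus, summary_lines = lines))
}
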