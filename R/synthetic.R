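#' Cohort and pooling design specification
#'
#' Describes the donor cohort and the donor-to-pool design the simulator
#' emulates: six sex-by-age groups, equal numbers of donors per group,
#' pools formed from equal plasma volumes of several unique donors, and a
#' subset of pools per group taken forward to proteomics. Defaults match
#' the reference study design: 20 donors per group (120 total), pools of
#' 4 donors, 5 pools per group for plasma work and the first 3 of them
#' for proteomics.
#'
#' @param donors_per_group Donors in each of the six groups.
#' @param pools_per_group_plasma Pools formed per group.
#' @param pools_per_group_proteomics Pools per group flagged for
#'   proteomics (the first k pools of each group).
#' @param donors_per_pool Unique donors mixed into each pool.
#' @param plasma_per_donor_mL Plasma volume contributed by each donor.
#' @param age_ranges Named list of \code{c(min, max)} donor ages (years)
#'   per group; defaults emulate healthy adult young / middle-aged / old
#'   bands.
#'
#' @return A validated list of class \code{"cohort_spec"}.
#' @examples
#' spec <- cohortSpec()
#' spec$donors_per_group
#' @export
cohortSpec <- function(donors_per_group = 20L,
                       pools_per_group_plasma = 5L,
                       pools_per_group_proteomics = 3L,
                       donors_per_pool = 4L,
                       plasma_per_donor_mL = 0.5,
                       age_ranges = NULL) {
    if (is.null(age_ranges)) {
        age_ranges <- list(
            M.young = c(22, 34), F.young = c(22, 35),
            M.mid   = c(43, 55), F.mid   = c(41, 54),
            M.old   = c(64, 79), F.old   = c(64, 76)
        )
    }
    spec <- list(donors_per_group = as.integer(donors_per_group),
                 pools_per_group_plasma = as.integer(pools_per_group_plasma),
                 pools_per_group_proteomics =
                     as.integer(pools_per_group_proteomics),
                 donors_per_pool = as.integer(donors_per_pool),
                 plasma_per_donor_mL = plasma_per_donor_mL,
                 age_ranges = age_ranges)
    class(spec) <- "cohort_spec"
    validateCohortSpec(spec)
    spec
}

validateCohortSpec <- function(spec) {
    with(spec, {
        if (donors_per_group < 1L || pools_per_group_plasma < 1L ||
            pools_per_group_proteomics < 1L || donors_per_pool < 1L)
            stop("cohort spec counts must be positive integers")
        if (donors_per_pool * pools_per_group_plasma > donors_per_group)
            stop("not enough donors per group: need ",
                 donors_per_pool * pools_per_group_plasma, ", have ",
                 donors_per_group)
        if (pools_per_group_proteomics > pools_per_group_plasma)
            stop("proteomics pools cannot exceed plasma pools")
        miss <- setdiff(groupLabels(), names(age_ranges))
        if (length(miss) > 0L)
            stop("age_ranges lacks groups: ", paste(miss, collapse = ", "))
    })
    invisible(TRUE)
}

#' Effect-structure specification for the abundance simulator
#'
#' Encodes, on the log2 scale, the signal structure the simulator plants:
#' per-protein baselines, fraction enrichment (a fixed log2 EV/PROT
#' offset for EV-enriched proteins, sign-flipped for PROT-enriched
#' ones), optional age effects (per-age-group mean offsets, scoped to one
#' or both sexes), optional sex effects (per-age-group M minus F
#' offsets), between-donor and technical noise, and a detection-limit
#' threshold below which values drop out.
#'
#' @param n_proteins Number of simulated proteins.
#' @param frac_ev_enriched,frac_prot_enriched Proportions of proteins
#'   enriched in the EV / PROT fraction; their sum must be at most 1.
#' @param ev_enrichment_log2 Log2 EV/PROT offset applied to
#'   fraction-enriched proteins.
#' @param age_affected \code{NULL} or a data.frame with columns
#'   \code{protein}, \code{sex_scope} (\code{"M"}, \code{"F"} or
#'   \code{"both"}), \code{young}, \code{mid}, \code{old} (mean log2
#'   offsets added to donors of that age group, within scope).
#' @param sex_affected \code{NULL} or a data.frame with columns
#'   \code{protein}, \code{young}, \code{mid}, \code{old} (log2 M - F
#'   offsets per age group, applied to male donors).
#' @param donor_sd_log2,tech_sd_log2 Between-donor and technical
#'   (per pool per fraction) standard deviations, log2 scale.
#' @param lod_log2 Detection limit: pool values whose log2 abundance
#'   falls below this become missing.
#' @param baseline_mean_log2,baseline_sd_log2 Distribution of per-protein
#'   log2 baselines (label-free intensity scale).
#'
#' @return A validated list of class \code{"effect_spec"}.
#' @examples
#' eff <- effectSpec(n_proteins = 100)
#' @export
effectSpec <- function(n_proteins = 1000L,
                       frac_ev_enriched = 0.35,
                       frac_prot_enriched = 0.1,
                       ev_enrichment_log2 = 2,
                       age_affected = NULL,
                       sex_affected = NULL,
                       donor_sd_log2 = 0.5,
                       tech_sd_log2 = 0.2,
                       lod_log2 = 16,
                       baseline_mean_log2 = 20,
                       baseline_sd_log2 = 2) {
    spec <- list(n_proteins = as.integer(n_proteins),
                 frac_ev_enriched = frac_ev_enriched,
                 frac_prot_enriched = frac_prot_enriched,
                 ev_enrichment_log2 = ev_enrichment_log2,
                 age_affected = age_affected,
                 sex_affected = sex_affected,
                 donor_sd_log2 = donor_sd_log2,
                 tech_sd_log2 = tech_sd_log2,
                 lod_log2 = lod_log2,
                 baseline_mean_log2 = baseline_mean_log2,
                 baseline_sd_log2 = baseline_sd_log2)
    class(spec) <- "effect_spec"
    validateEffectSpec(spec)
    spec
}

validateEffectSpec <- function(spec) {
    with(spec, {
        if (n_proteins < 1L) stop("n_proteins must be positive")
        for (p in c(frac_ev_enriched, frac_prot_enriched))
            if (p < 0 || p > 1) stop("enrichment fractions must lie in [0,1]")
        if (frac_ev_enriched + frac_prot_enriched > 1)
            stop("frac_ev_enriched + frac_prot_enriched must be <= 1")
        if (donor_sd_log2 < 0 || tech_sd_log2 < 0)
            stop("standard deviations must be non-negative")
        for (tab in list(age_affected, sex_affected)) {
            if (!is.null(tab)) {
                need <- c("protein", "young", "mid", "old")
                if (!all(need %in% colnames(tab)))
                    stop("effect tables need columns: ",
                         paste(need, collapse = ", "))
            }
        }
        if (!is.null(age_affected) &&
            (!"sex_scope" %in% colnames(age_affected) ||
             !all(age_affected$sex_scope %in% c("M", "F", "both"))))
            stop("age_affected$sex_scope must be 'M', 'F' or 'both'")
    })
    invisible(TRUE)
}

#' Generate a synthetic donor cohort
#'
#' Draws \code{donors_per_group} donors in each of the six sex-by-age
#' groups, with ages uniform within each group's configured range.
#' Deterministic under a fixed seed.
#'
#' @param spec A [cohortSpec()].
#' @param seed Integer seed for this operation's RNG stream.
#' @return A data.frame with columns \code{donor_id}, \code{sex},
#'   \code{age_group}, \code{group}, \code{age_years}.
#' @examples
#' donors <- generateCohort(cohortSpec(), seed = 1)
#' nrow(donors)  # 120
#' @export
generateCohort <- function(spec = cohortSpec(), seed) {
    validateCohortSpec(spec)
    withSeed(seed, {
        rows <- lapply(groupLabels(), function(g) {
            rng <- spec$age_ranges[[g]]
            n <- spec$donors_per_group
            parts <- strsplit(g, ".", fixed = TRUE)[[1L]]
            data.frame(
                donor_id = sprintf("D_%s_%02d", g, seq_len(n)),
                sex = parts[1L],
                age_group = parts[2L],
                group = g,
                age_years = round(stats::runif(n, rng[1L], rng[2L]), 1L),
                stringsAsFactors = FALSE
            )
        })
        do.call(rbind, rows)
    })
}

#' Partition donors into age-balanced pools
#'
#' Within each group, donors are sorted by age and dealt round-robin into
#' \code{pools_per_group_plasma} disjoint pools of
#' \code{donors_per_pool}, which keeps the age distribution balanced
#' across pools. The first \code{pools_per_group_proteomics} pools of
#' each group are flagged for proteomics.
#'
#' @param donors A cohort data.frame from [generateCohort()].
#' @param spec The matching [cohortSpec()].
#' @return A \code{DataFrame} of pool metadata: \code{pool_id},
#'   \code{sex}, \code{age_group}, \code{group}, \code{donor_ids} (list),
#'   \code{mean_age}, \code{plasma_volume_mL}, \code{proteomics}.
#' @examples
#' donors <- generateCohort(cohortSpec(), seed = 1)
#' pools <- makePools(donors, cohortSpec())
#' table(pools$proteomics)
#' @export
makePools <- function(donors, spec = cohortSpec()) {
    validateCohortSpec(spec)
    per_pool <- spec$donors_per_pool
    k <- spec$pools_per_group_plasma
    rows <- lapply(groupLabels(), function(g) {
        d <- donors[donors$group == g, , drop = FALSE]
        if (nrow(d) < per_pool * k)
            stop("group ", g, " short by ",
                 per_pool * k - nrow(d), " donors")
        d <- d[order(d$age_years, d$donor_id), , drop = FALSE]
        d <- d[seq_len(per_pool * k), , drop = FALSE]
        pool_of <- rep(seq_len(k), length.out = nrow(d))
        parts <- strsplit(g, ".", fixed = TRUE)[[1L]]
        DataFrame(
            pool_id = sprintf("%s_p%d", g, seq_len(k)),
            sex = parts[1L],
            age_group = parts[2L],
            group = g,
            donor_ids = I(split(d$donor_id, pool_of)),
            mean_age = as.numeric(tapply(d$age_years, pool_of, mean)),
            plasma_volume_mL = per_pool * spec$plasma_per_donor_mL,
            proteomics = seq_len(k) <= spec$pools_per_group_proteomics
        )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- out$pool_id
    out
}

.effectOffsets <- function(tab, n_proteins, proteins, what) {
    # expand an effect table into per-protein x per-age-group offsets
    off <- matrix(0, nrow = n_proteins, ncol = 3L,
                  dimnames = list(proteins, .VALID_AGE))
    scope <- rep(NA_character_, n_proteins)
    names(scope) <- proteins
    if (!is.null(tab)) {
        idx <- match(as.character(tab$protein), proteins)
        if (any(is.na(idx)))
            stop(what, " table names unknown proteins: ",
                 paste(tab$protein[is.na(idx)], collapse = ", "))
        off[idx, "young"] <- tab$young
        off[idx, "mid"] <- tab$mid
        off[idx, "old"] <- tab$old
        scope[idx] <- if ("sex_scope" %in% colnames(tab))
            as.character(tab$sex_scope) else "both"
    }
    list(offsets = off, scope = scope)
}

#' Simulate paired EV / PROT abundance matrices
#'
#' For every protein, each donor gets a log2 abundance equal to the
#' protein baseline plus any age/sex offsets for the donor's group plus
#' Normal(0, \code{donor_sd_log2}) noise. A pool's biological value is
#' the linear-scale mean of its member donors (physical mixing of equal
#' plasma volumes). Each fraction then receives independent technical
#' noise Normal(0, \code{tech_sd_log2}) on the log2 scale, and
#' fraction-enriched proteins an additional \code{ev_enrichment_log2}
#' offset in their enriched fraction. Pool values whose log2 abundance
#' falls below \code{lod_log2} are censored to missing, emulating
#' detection-limit dropout.
#'
#' @param pools Pool metadata from [makePools()]; only pools flagged
#'   \code{proteomics} are simulated (all pools if no flag column).
#' @param effects An [effectSpec()].
#' @param seed Integer seed for this operation's RNG stream.
#' @return A list with elements \code{ev} and \code{prot}
#'   ([AbundanceExperiment-class]s over the same pool ids) and
#'   \code{truth}, a \code{DataFrame} of ground-truth labels per protein
#'   (fraction class, age/sex effect scopes and offsets) for recovery
#'   tests.
#' @examples
#' pools <- makePools(generateCohort(cohortSpec(), seed = 1), cohortSpec())
#' sim <- simulateAbundance(pools, effectSpec(n_proteins = 50), seed = 2)
#' sim$ev
#' @export
simulateAbundance <- function(pools, effects = effectSpec(), seed) {
    validateEffectSpec(effects)
    if ("proteomics" %in% colnames(pools))
        pools <- pools[pools$proteomics, , drop = FALSE]
    n <- effects$n_proteins
    proteins <- sprintf("PR%04d", seq_len(n))
    withSeed(seed, {
        baseline <- stats::rnorm(n, effects$baseline_mean_log2,
                                 effects$baseline_sd_log2)
        n_ev <- round(effects$frac_ev_enriched * n)
        n_pr <- round(effects$frac_prot_enriched * n)
        frac_class <- rep("none", n)
        frac_class[seq_len(n_ev)] <- "EV"
        if (n_pr > 0L) frac_class[n_ev + seq_len(n_pr)] <- "PROT"
        age <- .effectOffsets(effects$age_affected, n, proteins, "age")
        sex <- .effectOffsets(effects$sex_affected, n, proteins, "sex")

        donor_ids <- unique(unlist(pools$donor_ids))
        donor_pool <- rep(seq_len(nrow(pools)),
                          lengths(pools$donor_ids))[
                              match(donor_ids, unlist(pools$donor_ids))]
        donor_sex <- pools$sex[donor_pool]
        donor_age <- pools$age_group[donor_pool]
        nd <- length(donor_ids)

        # donor-level log2 abundance: baseline + group offsets + noise
        donor_log2 <- matrix(baseline, nrow = n, ncol = nd)
        ai <- match(donor_age, .VALID_AGE)
        for (j in seq_len(nd)) {
            a_off <- age$offsets[, ai[j]]
            in_scope <- !is.na(age$scope) &
                (age$scope == "both" | age$scope == donor_sex[j])
            donor_log2[, j] <- donor_log2[, j] + ifelse(in_scope, a_off, 0)
            if (donor_sex[j] == "M") {
                s_off <- sex$offsets[, ai[j]]
                donor_log2[, j] <- donor_log2[, j] +
                    ifelse(!is.na(sex$scope), s_off, 0)
            }
        }
        donor_log2 <- donor_log2 +
            matrix(stats::rnorm(n * nd, 0, effects$donor_sd_log2), n, nd)

        # pool biological value: linear mean of member donors
        pool_log2 <- vapply(seq_len(nrow(pools)), function(k) {
            cols <- match(pools$donor_ids[[k]], donor_ids)
            log2(rowMeans(2^donor_log2[, cols, drop = FALSE]))
        }, numeric(n))
        dimnames(pool_log2) <- list(proteins, pools$pool_id)

        makeFraction <- function(frac) {
            off <- numeric(n)
            off[frac_class == frac] <- effects$ev_enrichment_log2
            m <- pool_log2 + off +
                matrix(stats::rnorm(length(pool_log2), 0,
                                    effects$tech_sd_log2),
                       nrow = n)
            m[m < effects$lod_log2] <- NA_real_
            cd <- DataFrame(pool_id = pools$pool_id, sex = pools$sex,
                            age_group = pools$age_group,
                            group = pools$group,
                            fraction = frac,
                            plasma_volume_mL = pools$plasma_volume_mL,
                            row.names = pools$pool_id)
            AbundanceExperiment(2^m, poolData = cd, fraction = frac)
        }
        ev <- makeFraction("EV")
        prot <- makeFraction("PROT")

        truth <- DataFrame(
            protein = proteins,
            baseline_log2 = baseline,
            fraction_class = frac_class,
            age_scope = age$scope,
            age_young = age$offsets[, "young"],
            age_mid = age$offsets[, "mid"],
            age_old = age$offsets[, "old"],
            sex_affected = !is.na(sex$scope),
            sex_young = sex$offsets[, "young"],
            sex_mid = sex$offsets[, "mid"],
            sex_old = sex$offsets[, "old"],
            row.names = proteins
        )
        list(ev = ev, prot = prot, truth = truth)
    })
}

#' Simulate particle-count measurements
#'
#' Draws lognormal per-pool particle concentrations (particles per mL of
#' plasma) around configurable group means, then expresses them as
#' instrument-scale measurements of the diluted EV preparation so that
#' [normalizeParticles()] recovers the plasma-scale value.
#'
#' @param pools Pool metadata from [makePools()].
#' @param group_mean Named vector of mean particles per mL plasma per
#'   group (names from [groupLabels()]); a single unnamed value recycles.
#' @param cv Coefficient of variation of the lognormal draw (0 gives the
#'   group mean exactly).
#' @param instruments Instruments to emit rows for.
#' @param dilution_factor,prep_volume_mL,plasma_input_mL Measurement
#'   geometry used to back-compute the suspension-scale concentration.
#' @param seed Integer seed.
#' @return A particle-measurement data.frame (see [readParticleTable()]).
#' @export
simulateParticles <- function(pools, group_mean = 3e9, cv = 0.25,
                              instruments = c("NTA", "NFCM"),
                              dilution_factor = 100,
                              prep_volume_mL = 0.6,
                              plasma_input_mL = 2,
                              seed) {
    if (is.null(names(group_mean))) {
        group_mean <- stats::setNames(rep(group_mean,
                                          length.out = 6L), groupLabels())
    }
    if (any(group_mean <= 0)) stop("group means must be positive")
    withSeed(seed, {
        rows <- lapply(instruments, function(inst) {
            mu <- group_mean[pools$group]
            if (cv > 0) {
                sdlog <- sqrt(log(1 + cv^2))
                conc <- stats::rlnorm(nrow(pools),
                                      log(mu) - sdlog^2 / 2, sdlog)
            } else {
                conc <- as.numeric(mu)
            }
            data.frame(
                pool_id = pools$pool_id,
                instrument = inst,
                measured_concentration = conc * plasma_input_mL /
                    (prep_volume_mL * dilution_factor),
                dilution_factor = dilution_factor,
                prep_volume_mL = prep_volume_mL,
                plasma_input_mL = plasma_input_mL,
                stringsAsFactors = FALSE
            )
        })
        do.call(rbind, rows)
    })
}

#' Simulate donor-level plasma analytes
#'
#' Draws HDL, LDL (mg/dL) and albumin (g/L) per donor from group-wise
#' Normal distributions. Defaults emulate a healthy adult cohort,
#' including the characteristic elevation of HDL in females relative to
#' males in every age band.
#'
#' @param donors Cohort data.frame from [generateCohort()].
#' @param stats_by_group Optional list per group of
#'   \code{list(HDL = c(mean, sd), LDL = ..., ALB = ...)}.
#' @param seed Integer seed.
#' @return An analyte data.frame with unit-bearing column names
#'   (see [readAnalyteTable()]).
#' @export
simulateAnalytes <- function(donors, stats_by_group = NULL, seed) {
    if (is.null(stats_by_group)) {
        stats_by_group <- list(
            M.young = list(HDL = c(46.5, 7.3), LDL = c(110.7, 22.9),
                           ALB = c(45.1, 2.4)),
            F.young = list(HDL = c(58.7, 12.4), LDL = c(95.0, 18.6),
                           ALB = c(43.6, 4.0)),
            M.mid   = list(HDL = c(43.8, 9.0), LDL = c(130.9, 22.8),
                           ALB = c(44.7, 2.1)),
            F.mid   = list(HDL = c(63.6, 12.1), LDL = c(126.6, 33.1),
                           ALB = c(43.8, 2.0)),
            M.old   = list(HDL = c(52.55, 12.9), LDL = c(117.1, 40.0),
                           ALB = c(43.6, 2.3)),
            F.old   = list(HDL = c(60.9, 13.6), LDL = c(126.9, 29.0),
                           ALB = c(42.5, 1.7))
        )
    }
    withSeed(seed, {
        draw <- function(analyte) {
            vapply(seq_len(nrow(donors)), function(i) {
                p <- stats_by_group[[donors$group[i]]][[analyte]]
                max(0, stats::rnorm(1L, p[1L], p[2L]))
            }, numeric(1L))
        }
        out <- data.frame(sample_id = donors$donor_id,
                          group = donors$group,
                          check.names = FALSE,
                          stringsAsFactors = FALSE)
        out[["HDL (mg/dL)"]] <- draw("HDL")
        out[["LDL (mg/dL)"]] <- draw("LDL")
        out[["ALB (g/L)"]] <- draw("ALB")
        out
    })
}
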