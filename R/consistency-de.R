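#' Ratio-sign-consistency differential abundance
#'
#' The pipeline's core rule: a protein is differentially abundant between
#' two conditions when every evaluated abundance ratio falls on the same
#' side of 1. No distributional assumption is made; instead the analytic
#' false-positive rate of the rule under an exchangeable null is supplied
#' by [nullConsistencyRate()] and [nullPairedRate()].
#'
#' Two forms are provided:
#' \itemize{
#'   \item \code{pairedFractionDE}: per-pool EV/PROT ratios across all
#'     matched pools (one ratio per pool; 18 at the default design).
#'     Verdict \code{up} means EV-enriched.
#'   \item \code{crossGroupDE}: all cross ratios \eqn{a_i / b_j} between
#'     the pools of two disjoint groups (9 ratios at 3 vs 3 pools).
#'     Verdict \code{up} means higher in the first-named group.
#' }
#'
#' Ties (a ratio exactly 1) break consistency, so equal values give
#' \code{not_DE}. A protein missing a value in any required pool is
#' \code{not_evaluable}: the full ratio set is undefined and no
#' imputation is attempted. \code{log2fc} is the mean of the log2 ratios
#' (the log2 geometric-mean ratio), reported for every evaluable protein.
#'
#' @param ev,prot [AbundanceExperiment-class]s for the two fractions;
#'   pools are matched one-to-one by pool id (plasma pool of origin).
#' @return A \code{DataFrame} with one row per protein: \code{protein},
#'   \code{comparison}, \code{n_ratios}, \code{n_ratios_gt1},
#'   \code{n_ratios_lt1}, \code{verdict} (\code{up}, \code{down},
#'   \code{not_DE}, \code{not_evaluable}) and \code{log2fc}.
#' @examples
#' a <- matrix(2, 2, 3, dimnames = list(c("X", "Y"), paste0("P", 1:3)))
#' b <- matrix(1, 2, 3, dimnames = list(c("X", "Y"), paste0("P", 1:3)))
#' ev <- AbundanceExperiment(a, fraction = "EV")
#' prot <- AbundanceExperiment(b, fraction = "PROT")
#' pairedFractionDE(ev, prot)
#' @export
pairedFractionDE <- function(ev, prot) {
    pools <- intersect(colnames(ev), colnames(prot))
    if (length(pools) == 0L)
        stop("no corresponding pools between the EV and PROT tables")
    proteins <- intersect(rownames(ev), rownames(prot))
    a <- abundance(ev)[proteins, pools, drop = FALSE]
    b <- abundance(prot)[proteins, pools, drop = FALSE]
    n <- length(pools)
    res <- lapply(seq_along(proteins), function(i) {
        .consistencyVerdict(a[i, ], b[i, ], paired = TRUE)
    })
    .deFrame(proteins, "EV_vs_PROT", n, res)
}

#' @rdname pairedFractionDE
#' @param x An [AbundanceExperiment-class].
#' @param group_a,group_b Disjoint character vectors of pool ids (the
#'   comparison is \code{group_a} versus \code{group_b}; \code{up} =
#'   higher in \code{group_a}).
#' @param comparison Label recorded on each result row.
#' @export
crossGroupDE <- function(x, group_a, group_b, comparison = "A_vs_B") {
    if (length(group_a) == 0L || length(group_b) == 0L)
        stop("both comparison groups must be non-empty")
    if (length(intersect(group_a, group_b)) > 0L)
        stop("comparison groups overlap: ",
             paste(intersect(group_a, group_b), collapse = ", "))
    missing_pools <- setdiff(c(group_a, group_b), colnames(x))
    if (length(missing_pools) > 0L)
        stop("pools not in table: ", paste(missing_pools, collapse = ", "))
    m <- abundance(x)
    proteins <- rownames(x)
    n_ratios <- length(group_a) * length(group_b)
    res <- lapply(seq_along(proteins), function(i) {
        .consistencyVerdict(m[i, group_a], m[i, group_b], paired = FALSE)
    })
    .deFrame(proteins, comparison, n_ratios, res)
}

.consistencyVerdict <- function(a, b, paired) {
    if (anyNA(a) || anyNA(b)) {
        return(list(gt = NA_integer_, lt = NA_integer_,
                    verdict = "not_evaluable", log2fc = NA_real_))
    }
    ratios <- if (paired) a / b else as.vector(outer(a, b, "/"))
    gt <- sum(ratios > 1)
    lt <- sum(ratios < 1)
    n <- length(ratios)
    verdict <- if (gt == n) "up" else if (lt == n) "down" else "not_DE"
    list(gt = gt, lt = lt, verdict = verdict,
         log2fc = mean(log2(ratios)))
}

.deFrame <- function(proteins, comparison, n_ratios, res) {
    DataFrame(
        protein = proteins,
        comparison = comparison,
        n_ratios = ifelse(vapply(res, function(r) r$verdict,
                                 character(1L)) == "not_evaluable",
                          NA_integer_, n_ratios),
        n_ratios_gt1 = vapply(res, function(r) as.integer(r$gt),
                              integer(1L)),
        n_ratios_lt1 = vapply(res, function(r) as.integer(r$lt),
                              integer(1L)),
        verdict = vapply(res, function(r) r$verdict, character(1L)),
        log2fc = vapply(res, function(r) r$log2fc, numeric(1L)),
        row.names = proteins
    )
}

#' The default comparison plan
#'
#' Six age comparisons (young vs mid, young vs old, mid vs old, within
#' males and within females) and three sex comparisons (M vs F within
#' each age band). \code{up} refers to the first-named group.
#'
#' @return A data.frame with columns \code{label}, \code{type}
#'   (\code{"age"} or \code{"sex"}), \code{group_a}, \code{group_b}.
#' @examples
#' comparisonPlan()
#' @export
comparisonPlan <- function() {
    age_pairs <- list(c("young", "mid"), c("young", "old"),
                      c("mid", "old"))
    age <- do.call(rbind, lapply(.VALID_SEX, function(s) {
        do.call(rbind, lapply(age_pairs, function(p) {
            data.frame(label = sprintf("%s:%s_vs_%s", s, p[1L], p[2L]),
                       type = "age",
                       group_a = paste(s, p[1L], sep = "."),
                       group_b = paste(s, p[2L], sep = "."),
                       stringsAsFactors = FALSE)
        }))
    }))
    sex <- do.call(rbind, lapply(.VALID_AGE, function(a) {
        data.frame(label = sprintf("%s:M_vs_F", a),
                   type = "sex",
                   group_a = paste("M", a, sep = "."),
                   group_b = paste("F", a, sep = "."),
                   stringsAsFactors = FALSE)
    }))
    rbind(age, sex)
}

#' Run the full comparison plan over both fractions
#'
#' Applies [crossGroupDE()] for every plan comparison within each
#' fraction and summarizes differentially-abundant protein counts per
#' comparison (every summary row satisfies
#' \code{n_DE = n_up + n_down}).
#'
#' @param ev,prot [AbundanceExperiment-class]s (typically
#'   detection-filtered); either may be \code{NULL} to skip a fraction.
#' @param plan A comparison plan data.frame, see [comparisonPlan()].
#' @param expected_pools Expected pools per group; a mismatch draws a
#'   warning, not an error (group sizes are configurable).
#' @return A list with \code{results} (nested list,
#'   \code{results[[fraction]][[label]]} a \code{DataFrame}) and
#'   \code{summary} (data.frame: fraction, label, type, n_universe,
#'   n_evaluable, n_DE, n_up, n_down).
#' @export
runPlan <- function(ev, prot, plan = comparisonPlan(),
                    expected_pools = 3L) {
    tables <- Filter(Negate(is.null), list(EV = ev, PROT = prot))
    results <- list()
    summary_rows <- list()
    for (frac in names(tables)) {
        x <- tables[[frac]]
        grp <- colData(x)$group
        if (is.null(grp))
            grp <- paste(colData(x)$sex, colData(x)$age_group, sep = ".")
        results[[frac]] <- list()
        for (i in seq_len(nrow(plan))) {
            pa <- colnames(x)[grp == plan$group_a[i]]
            pb <- colnames(x)[grp == plan$group_b[i]]
            if (length(pa) != expected_pools ||
                length(pb) != expected_pools)
                warning(sprintf("comparison %s (%s): %d vs %d pools, expected %d",
                                plan$label[i], frac, length(pa),
                                length(pb), expected_pools))
            de <- crossGroupDE(x, pa, pb, comparison = plan$label[i])
            results[[frac]][[plan$label[i]]] <- de
            summary_rows[[length(summary_rows) + 1L]] <- data.frame(
                fraction = frac,
                label = plan$label[i],
                type = plan$type[i],
                n_universe = nrow(de),
                n_evaluable = sum(de$verdict != "not_evaluable"),
                n_DE = sum(de$verdict %in% c("up", "down")),
                n_up = sum(de$verdict == "up"),
                n_down = sum(de$verdict == "down"),
                stringsAsFactors = FALSE
            )
        }
    }
    list(results = results, summary = do.call(rbind, summary_rows))
}

#' Extract the DE protein set from a result table
#'
#' @param de A \code{DataFrame} from [crossGroupDE()] or
#'   [pairedFractionDE()].
#' @param direction \code{"any"}, \code{"up"} or \code{"down"}.
#' @return Character vector of protein identifiers.
#' @export
deProteins <- function(de, direction = c("any", "up", "down")) {
    direction <- match.arg(direction)
    keep <- if (direction == "any") de$verdict %in% c("up", "down")
            else de$verdict == direction
    de$protein[keep]
}

#' Analytic null rates of the consistency rule
#'
#' Under an exchangeable null (all \eqn{m + n} pool values i.i.d. from a
#' continuous distribution), all \eqn{m \times n} cross ratios exceed 1
#' exactly when the minimum of the first group beats the maximum of the
#' second, which happens with probability \eqn{1 / \binom{m+n}{m}} per
#' direction: \code{nullConsistencyRate(m, n)} returns
#' \eqn{2 / \binom{m+n}{m}} (0.1 at 3 vs 3). For the paired rule with
#' independent, direction-symmetric per-pool ratios,
#' \code{nullPairedRate(n)} returns \eqn{2 (1/2)^n} (\eqn{2^{-17}} at 18
#' pools).
#'
#' @param m,n Pool counts of the two groups (paired form: \code{n}
#'   pools).
#' @return The false-positive probability of the rule per protein.
#' @examples
#' nullConsistencyRate(3, 3)  # 0.1
#' nullPairedRate(2)          # 0.5
#' @export
nullConsistencyRate <- function(m, n) {
    if (m < 1 || n < 1) stop("group sizes must be at least 1")
    2 / choose(m + n, m)
}

#' @rdname nullConsistencyRate
#' @export
nullPairedRate <- function(n) {
    if (n < 1) stop("pool count must be at least 1")
    2 * (1 / 2)^n
}
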