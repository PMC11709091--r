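# Fixture builders shared by the test files. All data are generated in
# code; nothing is read from disk except files the tests write first.

# bare abundance container around a matrix
makeAE <- function(m, fraction = "EV", groups = NULL) {
    pd <- NULL
    if (!is.null(groups)) {
        parts <- strsplit(groups, ".", fixed = TRUE)
        pd <- S4Vectors::DataFrame(
            pool_id = colnames(m),
            sex = vapply(parts, `[`, character(1), 1),
            age_group = vapply(parts, `[`, character(1), 2),
            group = groups,
            fraction = fraction,
            row.names = colnames(m))
    }
    AbundanceExperiment(m, poolData = pd, fraction = fraction)
}

# paired EV/PROT tables at the full 18-pool proteomics design
studyPools <- function() {
    grp <- rep(groupLabels(), each = 3)
    paste0(grp, "_p", rep(1:3, times = 6))
}

studyGroups <- function() rep(groupLabels(), each = 3)

# matrix with a prescribed number of detected pools per protein
detectionMatrix <- function(n_detected, n_pools, value = 100) {
    m <- matrix(NA_real_, nrow = length(n_detected), ncol = n_pools,
                dimnames = list(sprintf("PX%04d", seq_along(n_detected)),
                                sprintf("P%02d", seq_len(n_pools))))
    for (i in seq_along(n_detected)) {
        if (n_detected[i] > 0) m[i, seq_len(n_detected[i])] <- value
    }
    m
}

# cross-group fixture with prescribed verdict counts: n_up proteins with
# min(A) > max(B), n_down with max(A) < min(B), n_null straddling 1
verdictFixture <- function(n_up, n_down, n_null,
                           group_a = paste0("A", 1:3),
                           group_b = paste0("B", 1:3)) {
    n <- n_up + n_down + n_null
    m <- matrix(NA_real_, nrow = n, ncol = length(group_a) + length(group_b),
                dimnames = list(sprintf("FX%04d", seq_len(n)),
                                c(group_a, group_b)))
    ia <- seq_along(group_a)
    ib <- length(group_a) + seq_along(group_b)
    r <- 0
    for (i in seq_len(n_up))   { r <- r + 1; m[r, ia] <- 10 + ia; m[r, ib] <- 1 + 0.1 * ib }
    for (i in seq_len(n_down)) { r <- r + 1; m[r, ia] <- 1 + 0.1 * ia; m[r, ib] <- 10 + ib }
    for (i in seq_len(n_null)) { r <- r + 1; m[r, ia] <- c(1, 5, 9)[seq_along(ia)]; m[r, ib] <- 5 + 0.1 * ib }
    m
}

# tiny DE result table for set-analysis tests
deTable <- function(up = character(), down = character(),
                    not_de = character(), comparison = "cmp") {
    proteins <- c(up, down, not_de)
    S4Vectors::DataFrame(
        protein = proteins,
        comparison = rep(comparison, length(proteins)),
        n_ratios = rep(9L, length(proteins)),
        n_ratios_gt1 = c(rep(9L, length(up)), rep(0L, length(down)),
                         rep(4L, length(not_de))),
        n_ratios_lt1 = c(rep(0L, length(up)), rep(9L, length(down)),
                         rep(5L, length(not_de))),
        verdict = c(rep("up", length(up)), rep("down", length(down)),
                    rep("not_DE", length(not_de))),
        log2fc = c(rep(1, length(up)), rep(-1, length(down)),
                   rep(0, length(not_de))),
        row.names = proteins)
}
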