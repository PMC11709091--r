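# independent oracle for the cross-group rule: all m x n ratios share a
# direction iff one group's minimum beats the other group's maximum
minMaxVerdict <- function(a, b) {
    if (anyNA(a) || anyNA(b)) return("not_evaluable")
    if (min(a) > max(b)) "up" else if (max(a) < min(b)) "down" else "not_DE"
}

# exhaustive-enumeration oracle for the exchangeable null: every
# assignment of ranks 1..(m+n) to group A is equally likely
enumNullRate <- function(m, n) {
    ranks <- seq_len(m + n)
    subsets <- utils::combn(ranks, m)
    hits <- sum(apply(subsets, 2, function(s) {
        min(s) > max(setdiff(ranks, s)) || max(s) < min(setdiff(ranks, s))
    }))
    hits / ncol(subsets)
}

test_that("paired fraction rule: constant ratios, ties and missingness", {
    pools <- studyPools()
    ev <- matrix(2, 3, 18, dimnames = list(c("A", "B", "C"), pools))
    pr <- matrix(1, 3, 18, dimnames = list(c("A", "B", "C"), pools))
    pr["B", ] <- 2          # ties: ratio exactly 1 everywhere
    pr["C", 5] <- NA        # one missing value
    de <- pairedFractionDE(makeAE(ev), makeAE(pr, "PROT"))
    expect_equal(de["A", "verdict"], "up")
    expect_equal(de["A", "log2fc"], 1)
    expect_equal(de["A", "n_ratios"], 18L)
    expect_equal(de["B", "verdict"], "not_DE")
    expect_equal(de["C", "verdict"], "not_evaluable")
    expect_true(is.na(de["C", "log2fc"]))
    expect_error(pairedFractionDE(makeAE(ev),
                                  makeAE(`colnames<-`(pr, paste0("Q", 1:18)),
                                         "PROT")),
                 "no corresponding pools")
})

test_that("cross-group rule: worked examples and the 9-ratio contract", {
    m <- rbind(X = c(2, 3, 4, 1, 1, 1),
               Y = c(1, 2, 3, 2, 2, 2))
    colnames(m) <- c(paste0("A", 1:3), paste0("B", 1:3))
    de <- crossGroupDE(makeAE(m), paste0("A", 1:3), paste0("B", 1:3))
    expect_equal(de["X", "verdict"], "up")
    expect_equal(de["X", "n_ratios"], 9L)
    expect_equal(de["X", "n_ratios_gt1"], 9L)
    expect_equal(de["Y", "verdict"], "not_DE")
    expect_error(crossGroupDE(makeAE(m), c("A1", "A2"), c("A2", "B1")),
                 "overlap")
    expect_error(crossGroupDE(makeAE(m), character(), "B1"), "non-empty")
})

test_that("verdicts agree with the min/max oracle on random instances", {
    set.seed(2024)
    n_instances <- 1200L
    for (sizes in list(c(3L, 3L), c(2L, 4L), c(1L, 3L))) {
        na <- sizes[1]; nb <- sizes[2]
        vals <- matrix(sample(c(1:6, NA), n_instances * (na + nb),
                              replace = TRUE,
                              prob = c(rep(0.138, 6), 0.17)),
                       nrow = n_instances)
        vals <- vals + 0.01 * matrix(stats::runif(length(vals)),
                                     nrow = n_instances)
        colnames(vals) <- c(paste0("A", seq_len(na)),
                            paste0("B", seq_len(nb)))
        rownames(vals) <- sprintf("R%05d", seq_len(n_instances))
        de <- crossGroupDE(makeAE(vals), paste0("A", seq_len(na)),
                           paste0("B", seq_len(nb)))
        oracle <- vapply(seq_len(n_instances), function(i) {
            minMaxVerdict(vals[i, seq_len(na)], vals[i, na + seq_len(nb)])
        }, character(1))
        expect_identical(unname(de$verdict), oracle)
    }
})

test_that("adding pools can only remove DE calls (subset monotonicity)", {
    set.seed(77)
    vals <- matrix(stats::runif(300 * 6), nrow = 300)
    colnames(vals) <- c(paste0("A", 1:3), paste0("B", 1:3))
    rownames(vals) <- sprintf("R%03d", 1:300)
    ae <- makeAE(vals)
    full <- crossGroupDE(ae, paste0("A", 1:3), paste0("B", 1:3))
    for (sub in list(list(a = 1:2, b = 1:3), list(a = 1:3, b = 2:3),
                     list(a = 1L, b = 1L))) {
        reduced <- crossGroupDE(ae, paste0("A", sub$a), paste0("B", sub$b))
        expect_true(all(deProteins(full) %in% deProteins(reduced)))
    }
})

test_that("swapping groups mirrors verdicts and negates log2fc", {
    set.seed(88)
    vals <- matrix(stats::runif(200 * 6), nrow = 200)
    colnames(vals) <- c(paste0("A", 1:3), paste0("B", 1:3))
    rownames(vals) <- sprintf("R%03d", 1:200)
    ae <- makeAE(vals)
    ab <- crossGroupDE(ae, paste0("A", 1:3), paste0("B", 1:3))
    ba <- crossGroupDE(ae, paste0("B", 1:3), paste0("A", 1:3))
    expect_identical(unname(ab$verdict == "up"), unname(ba$verdict == "down"))
    expect_identical(unname(ab$verdict == "not_DE"),
                     unname(ba$verdict == "not_DE"))
    expect_equal(ab$log2fc, -ba$log2fc)
})

test_that("rescaling one group shifts log2fc by exactly log2(c)", {
    set.seed(99)
    vals <- matrix(stats::runif(100 * 6, 1, 10), nrow = 100)
    colnames(vals) <- c(paste0("A", 1:3), paste0("B", 1:3))
    rownames(vals) <- sprintf("R%03d", 1:100)
    for (cc in c(0.25, 3)) {
        scaled <- vals
        scaled[, 1:3] <- scaled[, 1:3] * cc
        d0 <- crossGroupDE(makeAE(vals), paste0("A", 1:3), paste0("B", 1:3))
        d1 <- crossGroupDE(makeAE(scaled), paste0("A", 1:3),
                           paste0("B", 1:3))
        expect_equal(d1$log2fc, d0$log2fc + log2(cc))
        # verdicts follow the min/max oracle on the rescaled values
        oracle <- vapply(seq_len(nrow(scaled)), function(i)
            minMaxVerdict(scaled[i, 1:3], scaled[i, 4:6]), character(1))
        expect_identical(unname(d1$verdict), oracle)
    }
})

test_that("analytic null rates match exhaustive enumeration", {
    expect_equal(nullConsistencyRate(3, 3), 0.1)
    expect_equal(nullConsistencyRate(3, 3), enumNullRate(3, 3))
    expect_equal(nullConsistencyRate(1, 1), 1)
    expect_equal(nullConsistencyRate(2, 1), 2 / 3)
    expect_equal(nullConsistencyRate(2, 1), enumNullRate(2, 1))
    expect_equal(nullConsistencyRate(4, 2), enumNullRate(4, 2))
    expect_error(nullConsistencyRate(0, 3), "at least 1")

    expect_equal(nullPairedRate(1), 1)
    # n = 2: enumeration of the 4 sign patterns gives 2/4
    signs <- expand.grid(c(-1, 1), c(-1, 1))
    expect_equal(mean(abs(rowSums(signs)) == 2), nullPairedRate(2))
    expect_equal(nullPairedRate(18), 2^-17)
    expect_error(nullPairedRate(0), "at least 1")
})

test_that("the comparison plan enumerates 6 age and 3 sex contrasts", {
    plan <- comparisonPlan()
    expect_equal(nrow(plan), 9L)
    expect_equal(sum(plan$type == "age"), 6L)
    expect_equal(sum(plan$type == "sex"), 3L)
    expect_false(anyDuplicated(plan$label) > 0)
    # every contrast pairs two distinct of the six groups
    expect_true(all(plan$group_a %in% groupLabels()))
    expect_true(all(plan$group_a != plan$group_b))
})

test_that("running the plan summarizes counts consistently", {
    spec <- cohortSpec()
    pools <- makePools(generateCohort(spec, seed = 21), spec)
    eff <- effectSpec(n_proteins = 150)
    sim <- simulateAbundance(pools, eff, seed = 22)
    plan <- runPlan(sim$ev, sim$prot)
    s <- plan$summary
    expect_equal(nrow(s), 18L)  # 9 comparisons x 2 fractions
    expect_equal(s$n_DE, s$n_up + s$n_down)
    expect_true(all(s$n_evaluable <= s$n_universe))
    # per-comparison results expose 9 ratios for evaluable proteins
    one <- plan$results$EV[["M:young_vs_old"]]
    expect_true(all(one$n_ratios[one$verdict != "not_evaluable"] == 9L))
})

test_that("unexpected group sizes warn rather than fail", {
    m <- matrix(stats::runif(20), 2, 10)
    rownames(m) <- c("A", "B")
    groups <- c(rep("M.young", 2), rep("M.mid", 2), rep("M.old", 2),
                rep("F.young", 2), rep("F.mid", 1), rep("F.old", 1))
    colnames(m) <- paste0(groups, "_p", sequence(rle(groups)$lengths))
    ae <- makeAE(m, groups = groups)
    w <- capture_warnings(plan <- runPlan(ae, NULL))
    expect_true(all(grepl("expected 3", w)))
    expect_equal(nrow(plan$summary), 9L)
})
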