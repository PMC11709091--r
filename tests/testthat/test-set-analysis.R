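test_that("venn regions partition the union and percentages recompute", {
    v <- vennSummary(list(EV = c("A", "B", "C"), PROT = c("B", "D")))
    expect_equal(v$union_size, 4L)
    expect_equal(sum(v$region_counts), v$union_size)
    expect_equal(unname(v$region_counts[c("EV", "PROT", "EV&PROT")]),
                 c(2L, 1L, 1L))
    expect_equal(unname(v$region_percentages),
                 unname(sapply(v$region_counts,
                               function(k) round(100 * k / 4, 1))))

    same <- vennSummary(list(a = letters[1:5], b = letters[1:5]))
    expect_equal(unname(same$region_counts["a&b"]), 5L)
    expect_equal(unname(same$region_percentages["a&b"]), 100)

    disj <- vennSummary(list(a = letters[1:3], b = letters[10:16]))
    expect_equal(unname(disj$region_counts[c("a", "b", "a&b")]),
                 c(3L, 7L, 0L))
    expect_equal(disj$union_size, 10L)
})

test_that("venn handles three sets and rejects more than four", {
    v <- vennSummary(list(x = c("1", "2", "3"), y = c("2", "3", "4"),
                          z = c("3", "4", "5")))
    expect_equal(sum(v$region_counts), 5L)
    expect_equal(unname(v$region_counts["x&y&z"]), 1L)
    expect_equal(sum(v$region_percentages), 100, tolerance = 0.11)
    expect_error(vennSummary(list(a = "1", b = "1", c = "1", d = "1",
                                  e = "1")), "4 sets")
    expect_error(vennSummary(list("1", "2")), "named")
})

test_that("age-dynamic selection counts comparisons correctly", {
    de <- list(young_vs_mid = deTable(up = c("P1", "P2")),
               young_vs_old = deTable(up = "P1", down = "P3"),
               mid_vs_old   = deTable(down = c("P1", "P4")))
    expect_identical(ageDynamicProteins(de, 2), "P1")
    expect_identical(ageDynamicProteins(de, 3), "P1")
    expect_identical(ageDynamicProteins(de, 1),
                     sort(c("P1", "P2", "P3", "P4")))
    # monotone decreasing in min_comparisons
    for (k in 1:2) {
        expect_true(all(ageDynamicProteins(de, k + 1) %in%
                        ageDynamicProteins(de, k)))
    }
    expect_error(ageDynamicProteins(de[1:2]), "three age comparisons")
})

test_that("a protein DE in exactly two comparisons flips at min = 3", {
    de <- list(a = deTable(up = "PX"), b = deTable(up = "PX"),
               c = deTable(not_de = "PX"))
    expect_identical(ageDynamicProteins(de, 2), "PX")
    expect_identical(ageDynamicProteins(de, 3), character(0))
})

test_that("a fixture with nine triple-DE proteins returns all nine", {
    triple <- sprintf("T%02d", 1:9)
    de <- list(young_vs_mid = deTable(up = c(triple, "X1")),
               young_vs_old = deTable(up = triple, down = "X2"),
               mid_vs_old   = deTable(down = triple))
    expect_identical(ageDynamicProteins(de, 3), sort(triple))
})

test_that("sex-common selection requires same comparison and direction", {
    de_M <- list(yo = deTable(up = c("P1", "P2"), down = "P3"),
                 ym = deTable(up = "P1"),
                 mo = deTable())
    de_F <- list(yo = deTable(up = "P1", down = c("P2", "P3")),
                 ym = deTable(),
                 mo = deTable(up = "P4"))
    dyn_M <- c("P1", "P2", "P3")
    dyn_F <- character(0)
    out <- sexCommonAgeProteins(de_M, de_F, dyn_M, dyn_F)
    # P1 up/up in yo and dynamic -> in; P2 up/down -> out; P3 down/down -> in
    expect_identical(as.character(out), c("P1", "P3"))
    prov <- attr(out, "provenance")
    expect_true(all(prov$comparison == "yo"))
    # any-comparison reading admits proteins DE in different contrasts
    out2 <- sexCommonAgeProteins(de_M, de_F, dyn_M, c("P4"),
                                 same_comparison = FALSE)
    expect_true("P1" %in% out2)
})

test_that("sex-consistent selection needs all three ages, same sign", {
    de <- list(young = deTable(up = c("OXSR1", "B"), down = "ADIPOQ"),
               mid   = deTable(up = "OXSR1", down = c("ADIPOQ", "B")),
               old   = deTable(up = "OXSR1", down = "ADIPOQ"))
    out <- sexConsistentAcrossAges(de)
    expect_identical(as.character(out), c("ADIPOQ", "OXSR1"))
    expect_equal(unname(attr(out, "direction")["ADIPOQ"]), "down")
    # B flips direction -> excluded; DE in only 2 of 3 -> excluded
    de2 <- list(young = deTable(up = "C"), mid = deTable(up = "C"),
                old = deTable(not_de = "C"))
    expect_length(sexConsistentAcrossAges(de2), 0L)
    expect_error(sexConsistentAcrossAges(de[1:2]), "three")
})

test_that("set operations are order-independent and idempotent", {
    s1 <- c("B", "A", "C"); s2 <- c("C", "D")
    v1 <- vennSummary(list(x = s1, y = s2))
    v2 <- vennSummary(list(x = rev(s1), y = rev(s2)))
    expect_identical(v1, v2)
    expect_identical(vennSummary(list(x = c(s1, s1), y = s2)), v1)
})

test_that("set summaries report half-up percentages of the universe", {
    s <- proteinSetSummary(sprintf("P%03d", 1:122), 1193)
    expect_equal(s$percent, 10.23)
    expect_equal(proteinSetSummary(sprintf("P%02d", 1:36), 516)$percent,
                 6.98)
})
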