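#' Venn-region counts and percentages
#'
#' Partitions the union of 2 to 4 named protein sets into exclusive
#' regions, reporting each region's count and its percentage of the
#' union (rounded half-up to one decimal). Region labels name the sets a
#' region belongs to, joined by \code{"&"}; e.g. for sets EV and PROT
#' the regions are \code{"EV"}, \code{"PROT"} and \code{"EV&PROT"}.
#'
#' @param sets Named list of character vectors (2 to 4 sets).
#' @return A list with \code{region_counts}, \code{region_percentages}
#'   and \code{union_size}. Counts sum to the union size and percentages
#'   to 100 within rounding.
#' @examples
#' vennSummary(list(EV = c("A", "B", "C"), PROT = c("B", "D")))
#' @export
vennSummary <- function(sets) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        stop("sets must be named")
    if (length(sets) < 2L || length(sets) > 4L)
        stop("between 2 and 4 sets are supported")
    sets <- lapply(sets, function(s) unique(as.character(s)))
    universe <- unique(unlist(sets))
    membership <- vapply(sets, function(s) universe %in% s,
                         logical(length(universe)))
    if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
    key <- apply(membership, 1L, function(m)
        paste(names(sets)[m], collapse = "&"))
    # enumerate all non-empty combinations for stable, complete output
    combos <- unlist(lapply(seq_along(sets), function(k) {
        apply(utils::combn(names(sets), k), 2L, paste, collapse = "&")
    }))
    counts <- vapply(combos, function(cb) sum(key == cb), integer(1L))
    union_size <- length(universe)
    pct <- if (union_size > 0L)
        roundHalfUp(100 * counts / union_size, 1L) else counts * 0
    list(region_counts = counts,
         region_percentages = pct,
         union_size = union_size)
}

#' Count and percentage of a protein set within a universe
#'
#' @param set Character vector of proteins.
#' @param universe_size Size of the reference universe.
#' @param digits Decimals for the percentage (half-up rounding).
#' @return A data.frame with \code{n}, \code{universe}, \code{percent}.
#' @examples
#' proteinSetSummary(letters[1:5], 40)
#' @export
proteinSetSummary <- function(set, universe_size, digits = 2L) {
    n <- length(unique(set))
    data.frame(n = n, universe = universe_size,
               percent = roundHalfUp(100 * n / universe_size, digits))
}

.asProteinSets <- function(de_list) {
    lapply(de_list, function(d) {
        if (is.character(d)) unique(d) else deProteins(d)
    })
}

#' Proteins dynamic across age comparisons
#'
#' Given the three age-comparison DE results for one sex and fraction,
#' returns the proteins called DE (any direction) in at least
#' \code{min_comparisons} of the three.
#'
#' @param de_list Named list of exactly three age-comparison results
#'   (\code{DataFrame}s from [crossGroupDE()] or plain protein sets).
#' @param min_comparisons Minimum number of comparisons a protein must
#'   be DE in (default 2; the result is monotone decreasing in this).
#' @return Character vector of protein identifiers.
#' @export
ageDynamicProteins <- function(de_list, min_comparisons = 2L) {
    if (length(de_list) != 3L)
        stop("exactly the three age comparisons are required, got ",
             length(de_list))
    sets <- .asProteinSets(de_list)
    tab <- table(unlist(sets))
    sort(names(tab)[tab >= min_comparisons])
}

.deDirections <- function(de) {
    # named verdict vector restricted to DE proteins
    keep <- de$verdict %in% c("up", "down")
    stats::setNames(de$verdict[keep], de$protein[keep])
}

#' Sex-common age-associated proteins
#'
#' Selects proteins whose age-related change is consistent across sexes
#' — DE in both males and females for at least one common age comparison
#' with the same direction — and intersects them with the proteins
#' dynamic across age comparisons in either sex. Membership provenance
#' (which comparison and direction qualified each protein) is attached
#' as the \code{"provenance"} attribute.
#'
#' @param de_M,de_F Named lists of the three age-comparison results per
#'   sex (names must agree between the lists).
#' @param dynamic_M,dynamic_F Protein sets from [ageDynamicProteins()]
#'   for each sex.
#' @param same_comparison If \code{TRUE} (default), both sexes must be
#'   DE in the same comparison with the same direction; if \code{FALSE},
#'   DE in any comparison per sex qualifies.
#' @return Character vector of proteins, with a \code{"provenance"}
#'   data.frame attribute.
#' @export
sexCommonAgeProteins <- function(de_M, de_F, dynamic_M, dynamic_F,
                                 same_comparison = TRUE) {
    prov <- list()
    if (same_comparison) {
        shared <- intersect(names(de_M), names(de_F))
        for (cmp in shared) {
            dm <- .deDirections(de_M[[cmp]])
            df <- .deDirections(de_F[[cmp]])
            common <- intersect(names(dm), names(df))
            agree <- common[dm[common] == df[common]]
            if (length(agree) > 0L)
                prov[[length(prov) + 1L]] <- data.frame(
                    protein = agree, comparison = cmp,
                    direction = unname(dm[agree]),
                    stringsAsFactors = FALSE)
        }
    } else {
        in_m <- unique(unlist(lapply(de_M, deProteins)))
        in_f <- unique(unlist(lapply(de_F, deProteins)))
        both <- intersect(in_m, in_f)
        if (length(both) > 0L)
            prov[[1L]] <- data.frame(protein = both,
                                     comparison = "any",
                                     direction = NA_character_,
                                     stringsAsFactors = FALSE)
    }
    prov <- if (length(prov) > 0L) do.call(rbind, prov) else
        data.frame(protein = character(), comparison = character(),
                   direction = character(), stringsAsFactors = FALSE)
    dynamic <- union(dynamic_M, dynamic_F)
    out <- sort(intersect(unique(prov$protein), dynamic))
    attr(out, "provenance") <- prov[prov$protein %in% out, ,
                                    drop = FALSE]
    out
}

#' Proteins sex-different across all age groups
#'
#' Returns the proteins called DE between males and females in all three
#' age groups with the same direction throughout — the stable
#' sex-associated markers.
#'
#' @param de_by_age Named list of the three M-vs-F results (young, mid,
#'   old).
#' @return Character vector of proteins, with a \code{"direction"}
#'   attribute giving each protein's common direction.
#' @export
sexConsistentAcrossAges <- function(de_by_age) {
    if (length(de_by_age) != 3L)
        stop("exactly the three per-age-group sex comparisons are required")
    dirs <- lapply(de_by_age, .deDirections)
    common <- Reduce(intersect, lapply(dirs, names))
    keep <- common[vapply(common, function(p) {
        length(unique(vapply(dirs, `[[`, character(1L), p))) == 1L
    }, logical(1L))]
    keep <- sort(keep)
    direction <- vapply(keep, function(p) dirs[[1L]][[p]], character(1L))
    attr(keep, "direction") <- direction
    keep
}
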