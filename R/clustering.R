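#' Hierarchical clustering of protein abundance
#'
#' Result container for [clusterHeatmap()]: row (protein) and column
#' (pool) dendrograms over the z-scored log2 abundance matrix, leaf
#' orders, and column cluster labels at the requested cut.
#'
#' @slot row_hclust,col_hclust \code{hclust} objects.
#' @slot row_order,col_order Leaf orders (identifiers).
#' @slot col_clusters Named integer cluster labels from cutting the
#'   column tree at \code{cut_k}.
#' @slot z The z-scored matrix that was clustered.
#' @slot distance,linkage The settings used.
#' @export
setClass("ClusteringResult",
    representation(row_hclust = "ANY", col_hclust = "ANY",
                   row_order = "character", col_order = "character",
                   col_clusters = "integer", z = "matrix",
                   distance = "character", linkage = "character"))

#' @describeIn ClusteringResult-class display a short summary
#' @param object A \code{ClusteringResult}.
#' @export
setMethod("show", "ClusteringResult", function(object) {
    cat("ClusteringResult: ", nrow(object@z), " proteins x ",
        ncol(object@z), " pools (", object@distance, " distance, ",
        object@linkage, " linkage)\n", sep = "")
    cat("  column clusters: ",
        paste(table(object@col_clusters), collapse = " / "), "\n",
        sep = "")
})

.zscoreRows <- function(m) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1L, stats::sd)
    z <- (m - mu) / ifelse(sdv == 0, 1, sdv)
    z[sdv == 0, ] <- 0
    z
}

.rowDistance <- function(z, distance) {
    if (distance == "euclidean") return(stats::dist(z))
    # correlation distance; zero-variance rows (all-zero after z-scoring)
    # have undefined correlation -> maximal distance, with a warning
    zero_var <- apply(z, 1L, function(v) stats::sd(v) == 0)
    cm <- suppressWarnings(stats::cor(t(z)))
    d <- 1 - cm
    if (any(zero_var)) {
        warning("zero-variance rows given maximal correlation distance: ",
                paste(rownames(z)[zero_var], collapse = ", "))
        d[zero_var, ] <- 2
        d[, zero_var] <- 2
    }
    diag(d) <- 0
    stats::as.dist(d)
}

#' Cluster proteins and pools on z-scored log2 abundance
#'
#' Rows are restricted to \code{proteins}, log2-transformed and
#' z-scored per protein (zero-variance proteins become all-zero rows);
#' rows and columns are then clustered agglomeratively with the chosen
#' distance and linkage. Input rows are ordered by identifier before
#' clustering so the result does not depend on input row order.
#' Undetected values are not allowed: proteins must be detected in every
#' selected pool (filter or subset first).
#'
#' @param x An [AbundanceExperiment-class].
#' @param proteins Protein identifiers to cluster (default all rows).
#' @param distance \code{"correlation"} (default; on the z-scored rows)
#'   or \code{"euclidean"}.
#' @param linkage \code{"average"} (default), \code{"complete"} or
#'   \code{"ward.D2"}.
#' @param cut_k Number of column clusters to label.
#' @return A [ClusteringResult-class].
#' @examples
#' m <- matrix(2^(1:12), 3, 4,
#'             dimnames = list(c("A", "B", "C"), paste0("P", 1:4)))
#' clusterHeatmap(AbundanceExperiment(m, fraction = "EV"), cut_k = 2)
#' @export
clusterHeatmap <- function(x, proteins = rownames(x),
                           distance = c("correlation", "euclidean"),
                           linkage = c("average", "complete", "ward.D2"),
                           cut_k = 3L) {
    distance <- match.arg(distance)
    linkage <- match.arg(linkage)
    absent <- setdiff(proteins, rownames(x))
    if (length(absent) > 0L)
        stop("proteins not in table: ", paste(absent, collapse = ", "))
    proteins <- sort(unique(proteins))
    if (length(proteins) < 2L || ncol(x) < 2L)
        stop("at least 2 proteins and 2 pools are required")
    a <- abundance(x)[proteins, , drop = FALSE]
    if (anyNA(a))
        stop("undetected values present; filter or subset before clustering")
    z <- .zscoreRows(log2(a))
    row_hc <- stats::hclust(.rowDistance(z, distance), method = linkage)
    col_hc <- stats::hclust(.rowDistance(t(z), distance), method = linkage)
    cut_k <- min(cut_k, ncol(z))
    new("ClusteringResult",
        row_hclust = row_hc, col_hclust = col_hc,
        row_order = rownames(z)[row_hc$order],
        col_order = colnames(z)[col_hc$order],
        col_clusters = stats::cutree(col_hc, k = cut_k),
        z = z, distance = distance, linkage = linkage)
}

#' Purity of column clusters against known group labels
#'
#' Fraction of pools whose cluster's majority label matches their own
#' label; 1 means every cluster is label-pure.
#'
#' @param result A [ClusteringResult-class].
#' @param labels Named vector of true labels (names = pool ids).
#' @return Purity in [0, 1].
#' @export
clusterPurity <- function(result, labels) {
    cl <- result@col_clusters
    labels <- labels[names(cl)]
    sum(vapply(split(labels, cl), function(l) max(table(l)),
               numeric(1L))) / length(cl)
}

#' Export a dendrogram in Newick format
#'
#' @param hc An \code{hclust} object (e.g. the \code{row_hclust} slot of
#'   a [ClusteringResult-class]).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeDendrogram <- function(hc, path) {
    ape::write.tree(ape::as.phylo(hc), file = path)
    invisible(path)
}
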