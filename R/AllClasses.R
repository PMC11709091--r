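#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData assay<- colData<-
NULL

.VALID_SEX <- c("M", "F")
.VALID_AGE <- c("young", "mid", "old")
.VALID_FRACTION <- c("EV", "PROT")

#' Six sex-by-age group labels
#'
#' The study design crosses biological sex (M, F) with three age bands
#' (young, mid, old), giving six donor groups. Labels follow the
#' \code{<sex>.<age>} convention, e.g. \code{"M.young"}.
#'
#' @return Character vector of the six group labels.
#' @examples
#' groupLabels()
#' @export
groupLabels <- function() {
    as.vector(outer(.VALID_SEX, .VALID_AGE, paste, sep = "."))
}

#' Container for one fraction's protein abundance matrix
#'
#' An \code{AbundanceExperiment} extends
#' \linkS4class{SummarizedExperiment}: rows are proteins (gene symbols),
#' columns are pools, and the single \code{"abundance"} assay holds
#' linear-scale normalized quantification values. \code{NA} means not
#' detected; all present values are non-negative, and a value of exactly 0
#' read from disk is treated as not detected (label-free quantification
#' outputs use 0 for absent). Pool metadata (sex, age group, fraction,
#' member donors, plasma volume) lives in \code{colData}.
#'
#' @slot fraction Which fraction the matrix quantifies, \code{"EV"} or
#'   \code{"PROT"}.
#'
#' @seealso [AbundanceExperiment()] for construction,
#'   [detectionRate()], [detectionFilter()].
#' @export
setClass("AbundanceExperiment",
    contains = "SummarizedExperiment",
    representation(fraction = "character")
)

.validAbundanceExperiment <- function(object) {
    msg <- NULL
    if (length(object@fraction) != 1L ||
        !object@fraction %in% .VALID_FRACTION) {
        msg <- c(msg, "fraction must be one of 'EV', 'PROT'")
    }
    if (!"abundance" %in% names(assays(object))) {
        msg <- c(msg, "assay 'abundance' is required")
    } else {
        a <- assay(object, "abundance")
        if (!is.numeric(a)) {
            msg <- c(msg, "'abundance' assay must be numeric")
        } else if (any(a < 0, na.rm = TRUE)) {
            msg <- c(msg, "abundance values must be >= 0 (NA = not detected)")
        }
    }
    if (anyDuplicated(rownames(object))) {
        dups <- unique(rownames(object)[duplicated(rownames(object))])
        msg <- c(msg, paste0("duplicate protein identifiers: ",
                             paste(dups, collapse = ", ")))
    }
    if (anyDuplicated(colnames(object))) {
        dups <- unique(colnames(object)[duplicated(colnames(object))])
        msg <- c(msg, paste0("duplicate pool ids: ",
                             paste(dups, collapse = ", ")))
    }
    cd <- colData(object)
    if ("fraction" %in% colnames(cd) &&
        !all(cd$fraction == object@fraction)) {
        msg <- c(msg, "colData fraction labels disagree with object fraction")
    }
    if ("sex" %in% colnames(cd) && !all(cd$sex %in% .VALID_SEX)) {
        msg <- c(msg, "sex must be 'M' or 'F'")
    }
    if ("age_group" %in% colnames(cd) && !all(cd$age_group %in% .VALID_AGE)) {
        msg <- c(msg, "age_group must be 'young', 'mid' or 'old'")
    }
    if (is.null(msg)) TRUE else msg
}

setValidity("AbundanceExperiment", .validAbundanceExperiment)

#' Construct an AbundanceExperiment
#'
#' @param abundance Numeric matrix, proteins x pools, linear scale.
#'   \code{NA} or 0 marks a protein not detected in a pool; zeros are
#'   converted to \code{NA} on construction.
#' @param poolData \code{DataFrame} or data.frame of per-pool metadata with
#'   one row per column of \code{abundance}; typically carries
#'   \code{pool_id}, \code{sex}, \code{age_group}, \code{fraction},
#'   \code{donor_ids}, \code{plasma_volume_mL}. May be omitted for
#'   bare matrices.
#' @param fraction \code{"EV"} or \code{"PROT"}.
#'
#' @return An [AbundanceExperiment-class] object.
#' @examples
#' m <- matrix(c(4, 2, 1, 8, 0, 2), nrow = 3,
#'             dimnames = list(c("CD9", "ALB", "APOA1"), c("P1", "P2")))
#' ae <- AbundanceExperiment(m, fraction = "EV")
#' detectionRate(ae)
#' @export
AbundanceExperiment <- function(abundance, poolData = NULL, fraction) {
    abundance <- as.matrix(abundance)
    storage.mode(abundance) <- "double"
    abundance[!is.na(abundance) & abundance == 0] <- NA_real_
    if (is.null(poolData)) {
        poolData <- DataFrame(pool_id = colnames(abundance),
                              row.names = colnames(abundance))
    } else {
        poolData <- DataFrame(poolData)
        if (is.null(rownames(poolData)) && "pool_id" %in% colnames(poolData))
            rownames(poolData) <- poolData$pool_id
    }
    se <- SummarizedExperiment(
        assays = SimpleList(abundance = abundance),
        colData = poolData
    )
    new("AbundanceExperiment", se, fraction = fraction)
}

#' @describeIn AbundanceExperiment-class display a short summary
#' @param object An \code{AbundanceExperiment}.
#' @export
setMethod("show", "AbundanceExperiment", function(object) {
    a <- assay(object, "abundance")
    cat("AbundanceExperiment (", object@fraction, " fraction)\n", sep = "")
    cat("  ", nrow(object), " proteins x ", ncol(object), " pools\n", sep = "")
    cat("  missing (not detected): ",
        sum(is.na(a)), " / ", length(a),
        sprintf(" (%.1f%%)", 100 * mean(is.na(a))), "\n", sep = "")
    callNextMethod()
})

#' Report of a detection-rate filter run
#'
#' Produced by [detectionFilter()]. Records the fraction, the input and
#' retained protein counts, the threshold applied and every protein's
#' detection rate (share of pools in which it was detected).
#'
#' @slot fraction Fraction label.
#' @slot n_input Number of proteins before filtering.
#' @slot n_retained Number of proteins retained.
#' @slot threshold Detection-rate threshold; retention requires a rate
#'   strictly greater than this.
#' @slot detection_rate Named numeric vector, one rate per input protein.
#' @export
setClass("FilterReport",
    representation(
        fraction = "character",
        n_input = "integer",
        n_retained = "integer",
        threshold = "numeric",
        detection_rate = "numeric"
    )
)

setValidity("FilterReport", function(object) {
    msg <- NULL
    if (object@n_retained > object@n_input)
        msg <- c(msg, "n_retained must be <= n_input")
    if (object@threshold < 0 || object@threshold > 1)
        msg <- c(msg, "threshold must lie in [0, 1]")
    if (length(object@detection_rate) != object@n_input)
        msg <- c(msg, "one detection rate per input protein required")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn FilterReport-class display a short summary
#' @param object A \code{FilterReport}.
#' @export
setMethod("show", "FilterReport", function(object) {
    cat("FilterReport (", object@fraction, " fraction)\n", sep = "")
    cat(sprintf("  %d / %d proteins retained at detection rate > %g\n",
                object@n_retained, object@n_input, object@threshold))
})
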