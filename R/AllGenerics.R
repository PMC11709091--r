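#' Fraction label of an object
#'
#' @param x An object carrying a fraction label.
#' @return \code{"EV"} or \code{"PROT"}.
#' @export
setGeneric("fraction", function(x) standardGeneric("fraction"))

#' @rdname fraction
#' @export
setMethod("fraction", "AbundanceExperiment", function(x) x@fraction)

#' Protein abundance matrix
#'
#' @param x An [AbundanceExperiment-class].
#' @return Numeric matrix (proteins x pools), linear scale, \code{NA} =
#'   not detected.
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @rdname abundance
#' @export
setMethod("abundance", "AbundanceExperiment",
          function(x) assay(x, "abundance"))

#' Pool metadata
#'
#' @param x An [AbundanceExperiment-class].
#' @return The \code{colData} \code{DataFrame} of per-pool metadata.
#' @export
setGeneric("poolData", function(x) standardGeneric("poolData"))

#' @rdname poolData
#' @export
setMethod("poolData", "AbundanceExperiment", function(x) colData(x))

#' Detection indicator and rate
#'
#' A protein is detected in a pool when its value is present (not
#' \code{NA}) and strictly positive.
#'
#' @param x An [AbundanceExperiment-class].
#' @return \code{detected}: logical matrix; \code{detectionRate}: named
#'   numeric vector of per-protein detection rates over the object's pools.
#' @export
setGeneric("detected", function(x) standardGeneric("detected"))

#' @rdname detected
#' @export
setMethod("detected", "AbundanceExperiment", function(x) {
    a <- abundance(x)
    !is.na(a) & a > 0
})

#' @rdname detected
#' @export
setGeneric("detectionRate", function(x) standardGeneric("detectionRate"))

#' @rdname detected
#' @export
setMethod("detectionRate", "AbundanceExperiment",
          function(x) rowMeans(detected(x)))
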