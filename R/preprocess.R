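#' Detection-rate filter
#'
#' Keeps a protein only when it is detected (present and positive) in
#' strictly more than \code{threshold} of the object's pools. With the
#' default 0.8 over 18 pools this requires detection in at least 15
#' pools. The detection rate is computed per fraction over all of that
#' fraction's pools jointly, not per group. Row order is preserved, and
#' the filter is idempotent.
#'
#' @param x An [AbundanceExperiment-class].
#' @param threshold Detection-rate threshold in [0, 1]; retention is
#'   strict (\code{rate > threshold}).
#' @return A list with elements \code{table} (the filtered
#'   [AbundanceExperiment-class]) and \code{report} (a
#'   [FilterReport-class]).
#' @examples
#' m <- matrix(c(1, NA, 2, 3, NA, NA), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), c("P1", "P2")))
#' detectionFilter(AbundanceExperiment(m, fraction = "EV"), 0.5)$report
#' @export
detectionFilter <- function(x, threshold = 0.8) {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        is.na(threshold) || threshold < 0 || threshold > 1)
        stop("threshold must be a single number in [0, 1]")
    if (nrow(x) == 0L) stop("abundance table has no proteins")
    rate <- detectionRate(x)
    keep <- rate > threshold
    report <- new("FilterReport",
                  fraction = fraction(x),
                  n_input = nrow(x),
                  n_retained = sum(keep),
                  threshold = threshold,
                  detection_rate = rate)
    list(table = x[keep, ], report = report)
}

#' Tabulate a FilterReport
#'
#' @param report A [FilterReport-class].
#' @return A data.frame with one row per input protein: identifier,
#'   detection rate, retained flag.
#' @export
filterReportTable <- function(report) {
    data.frame(protein = names(report@detection_rate),
               detection_rate = unname(report@detection_rate),
               retained = unname(report@detection_rate > report@threshold),
               stringsAsFactors = FALSE)
}
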