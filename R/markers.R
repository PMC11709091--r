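#' Marker panels
#'
#' A \code{MarkerPanel} is a named, ordered, duplicate-free list of gene
#' symbols used to characterize fractions: canonical EV markers
#' (tetraspanins and cytosolic MISEV-style markers), the consensus
#' top-100 EV proteins shared by the Exocarta and Vesiclepedia
#' databases, blood-component proteins (albumin, hemoglobin, red-cell
#' and platelet proteins), apolipoproteins, and complement components.
#' Panels ship as editable plain-text data files (one symbol per line,
#' \code{#} comments) because marker nomenclature varies across
#' resources; alias notes live in the file comments and no automatic
#' alias resolution is performed.
#'
#' @slot name Panel name.
#' @slot members Gene symbols, unique and non-empty.
#' @slot note Free-text source note.
#' @export
setClass("MarkerPanel",
    representation(name = "character", members = "character",
                   note = "character"))

setValidity("MarkerPanel", function(object) {
    msg <- NULL
    if (length(object@members) == 0L)
        msg <- c(msg, "panel must have at least one member")
    if (anyDuplicated(object@members))
        msg <- c(msg, paste0("duplicate members: ",
                             paste(unique(object@members[
                                 duplicated(object@members)]),
                                 collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' @describeIn MarkerPanel-class display a short summary
#' @param object A \code{MarkerPanel}.
#' @export
setMethod("show", "MarkerPanel", function(object) {
    cat("MarkerPanel '", object@name, "': ", length(object@members),
        " proteins\n", sep = "")
    if (nzchar(object@note)) cat("  ", object@note, "\n", sep = "")
})

#' Read a marker-panel file
#'
#' @param path Text file, one gene symbol per line; \code{#} starts a
#'   comment (full-line or trailing).
#' @param name Panel name (defaults to the file stem).
#' @param note Source note.
#' @return A [MarkerPanel-class].
#' @export
readPanel <- function(path, name = NULL, note = "") {
    if (is.null(name))
        name <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    members <- trimws(lines)
    members <- members[nzchar(members)]
    new("MarkerPanel", name = name, members = members, note = note)
}

#' @rdname readPanel
#' @param x A [MarkerPanel-class].
#' @return \code{panelMembers}: the member gene symbols.
#' @export
panelMembers <- function(x) x@members

#' Built-in marker panels
#'
#' Loads the panels shipped with the package: \code{ev_core} (canonical
#' EV markers), \code{exocarta_vesiclepedia_top100} (the 72 consensus
#' top-100 EV proteins), \code{blood_components},
#' \code{apolipoproteins} and \code{complement}.
#'
#' @return Named list of [MarkerPanel-class] objects.
#' @examples
#' names(builtinPanels())
#' @export
builtinPanels <- function() {
    dir <- system.file("extdata", "panels", package = "poolfrac",
                       mustWork = TRUE)
    files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
    panels <- lapply(files, readPanel)
    stats::setNames(panels, vapply(panels, function(p) p@name,
                                   character(1L)))
}

#' Rank marker proteins within a fraction
#'
#' Ranks every panel member by its mean abundance among all proteins in
#' the table (rank 1 = highest mean; ties broken by identifier). Markers
#' absent from the table, or never detected, are reported with an
#' undefined rank and detection rate 0. Ranks are invariant to monotone
#' rescaling of all abundances.
#'
#' @param x An [AbundanceExperiment-class].
#' @param panel A [MarkerPanel-class].
#' @param log_base Base for the reported log mean abundance (10 or 2).
#' @return A data.frame per marker: \code{protein},
#'   \code{mean_abundance}, \code{log_mean}, \code{rank} (over detected
#'   proteins), \code{detection_rate}.
#' @export
rankMarkers <- function(x, panel, log_base = 10) {
    if (length(panelMembers(panel)) == 0L) stop("empty panel")
    a <- abundance(x)
    means <- rowMeans(a, na.rm = TRUE)
    means[is.nan(means)] <- NA_real_
    det <- !is.na(means)
    ord <- order(-means[det], rownames(a)[det])
    ranks <- stats::setNames(rep(NA_integer_, nrow(a)), rownames(a))
    ranks[rownames(a)[det][ord]] <- seq_len(sum(det))
    rate <- detectionRate(x)
    members <- panelMembers(panel)
    idx <- match(members, rownames(a))
    data.frame(
        protein = members,
        mean_abundance = ifelse(is.na(idx), NA_real_, means[idx]),
        log_mean = ifelse(is.na(idx), NA_real_,
                          log(means[idx], base = log_base)),
        rank = ifelse(is.na(idx), NA_integer_, ranks[idx]),
        detection_rate = ifelse(is.na(idx), 0, rate[idx]),
        stringsAsFactors = FALSE
    )
}

#' Contrast a marker panel between fractions
#'
#' Per marker and fraction, the mean and SD of log2 abundance over
#' pools (undetected pools excluded), plus the enrichment direction
#' taken from the paired ratio-sign-consistency verdict where the
#' marker is evaluable (\code{"EV"} if consistently higher in EVs,
#' \code{"PROT"} if in PROT, \code{"none"} otherwise).
#'
#' @param ev,prot [AbundanceExperiment-class]s with matched pools.
#' @param panel A [MarkerPanel-class].
#' @return A data.frame per marker: log2 mean and SD per fraction,
#'   detection rates, and \code{direction}.
#' @export
panelContrast <- function(ev, prot, panel) {
    members <- panelMembers(panel)
    de <- pairedFractionDE(ev, prot)
    stat <- function(x, p) {
        a <- abundance(x)
        if (!p %in% rownames(a)) return(c(NA_real_, NA_real_, 0))
        v <- log2(a[p, ])
        v <- v[!is.na(v)]
        c(if (length(v)) mean(v) else NA_real_,
          if (length(v) > 1L) stats::sd(v) else NA_real_,
          detectionRate(x)[p])
    }
    rows <- lapply(members, function(p) {
        sev <- stat(ev, p)
        spr <- stat(prot, p)
        verdict <- if (p %in% rownames(de)) de[p, "verdict"] else
            "not_evaluable"
        direction <- switch(verdict, up = "EV", down = "PROT", "none")
        data.frame(protein = p,
                   ev_log2_mean = sev[1L], ev_log2_sd = sev[2L],
                   ev_detection_rate = sev[3L],
                   prot_log2_mean = spr[1L], prot_log2_sd = spr[2L],
                   prot_detection_rate = spr[3L],
                   direction = direction,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
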