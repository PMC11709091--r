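#' Read a protein abundance matrix from tab-delimited text
#'
#' Expects a header row of pool ids and a first column of protein
#' identifiers (gene symbols). An empty cell, \code{"NA"}, or \code{0}
#' all mean "not detected" and are stored as \code{NA}; the original cell
#' token of every missing entry is recorded so [writeAbundance()] can
#' reproduce the file losslessly.
#'
#' @param path Path to a TSV file.
#' @param fraction \code{"EV"} or \code{"PROT"}.
#' @param poolData Optional pool metadata \code{DataFrame} (e.g. from
#'   [readPoolMetadata()]); matched to columns by pool id, and the file's
#'   pools must all be present with the matching fraction.
#'
#' @return An [AbundanceExperiment-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("protein\tP1\tP2", "CD9\t4\t2", "ALB\t\t8"), tf)
#' ae <- readAbundance(tf, "EV")
#' abundance(ae)
#' @export
readAbundance <- function(path, fraction, poolData = NULL) {
    lines <- readLines(path)
    if (length(lines) < 1L) stop("empty abundance file: ", path)
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    pools <- header[-1L]
    if (anyDuplicated(pools)) {
        dups <- unique(pools[duplicated(pools)])
        stop("duplicate pool ids in header: ", paste(dups, collapse = ", "))
    }
    body <- lines[-1L]
    cells <- strsplit(body, "\t", fixed = TRUE)
    proteins <- vapply(cells, `[`, character(1L), 1L)
    if (anyDuplicated(proteins)) {
        dups <- unique(proteins[duplicated(proteins)])
        stop("duplicate protein identifiers: ", paste(dups, collapse = ", "))
    }
    tokens <- matrix("", nrow = length(proteins), ncol = length(pools),
                     dimnames = list(proteins, pools))
    for (i in seq_along(cells)) {
        row <- cells[[i]][-1L]
        # trailing blank fields are dropped by strsplit; restore them
        length(row) <- length(pools)
        row[is.na(row)] <- ""
        tokens[i, ] <- row
    }
    missing <- tokens == "" | tokens == "NA"
    values <- suppressWarnings(array(as.numeric(tokens), dim = dim(tokens),
                                     dimnames = dimnames(tokens)))
    bad <- which(!missing & is.na(values), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
        stop(sprintf("non-numeric cell '%s' at protein '%s', pool '%s'",
                     tokens[bad[1L, 1L], bad[1L, 2L]],
                     proteins[bad[1L, 1L]], pools[bad[1L, 2L]]))
    }
    if (any(values < 0, na.rm = TRUE))
        stop("negative abundance values are not allowed")
    values[missing] <- NA_real_
    if (!is.null(poolData)) {
        absent <- setdiff(pools, rownames(poolData))
        if (length(absent) > 0L)
            stop("pools without metadata: ", paste(absent, collapse = ", "))
        poolData <- poolData[pools, , drop = FALSE]
        if ("fraction" %in% colnames(poolData) &&
            !all(poolData$fraction == fraction))
            stop("pool metadata fraction does not match '", fraction, "'")
    }
    ae <- AbundanceExperiment(values, poolData = poolData,
                              fraction = fraction)
    metadata(ae)$io_tokens <- tokens
    ae
}

#' Write a protein abundance matrix as tab-delimited text
#'
#' If the object was created by [readAbundance()], the recorded cell
#' tokens are written back verbatim (token-for-token round trip).
#' Otherwise values are formatted at \code{digits} significant digits and
#' missing entries are written as the empty string.
#'
#' @param x An [AbundanceExperiment-class].
#' @param path Output path.
#' @param digits Significant digits for freshly formatted values.
#' @return Invisibly, \code{path}.
#' @export
writeAbundance <- function(x, path, digits = 10L) {
    a <- abundance(x)
    tokens <- metadata(x)$io_tokens
    if (is.null(tokens) || !identical(dim(tokens), dim(a)) ||
        !identical(dimnames(tokens), dimnames(a))) {
        tokens <- array("", dim = dim(a), dimnames = dimnames(a))
        present <- !is.na(a)
        tokens[present] <- format(a[present], digits = digits,
                                  trim = TRUE, scientific = FALSE)
    }
    lines <- c(paste(c("protein", colnames(a)), collapse = "\t"),
               vapply(seq_len(nrow(a)), function(i) {
                   paste(c(rownames(a)[i], tokens[i, ]), collapse = "\t")
               }, character(1L)))
    writeLines(lines, path)
    invisible(path)
}

#' Read and write pool metadata tables
#'
#' The metadata TSV has columns \code{pool_id}, \code{sex},
#' \code{age_group}, \code{fraction}, \code{donor_ids} (semicolon-joined)
#' and \code{plasma_volume_mL}. Validation enforces unique pool ids and
#' non-empty, duplicate-free donor lists.
#'
#' @param path Path to a TSV file.
#' @return \code{readPoolMetadata}: a \code{DataFrame} with pool ids as
#'   row names and \code{donor_ids} split into a list column.
#' @export
readPoolMetadata <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    validatePoolMetadata(df)
    donors <- strsplit(df$donor_ids, ";", fixed = TRUE)
    out <- DataFrame(pool_id = df$pool_id, sex = df$sex,
                     age_group = df$age_group, fraction = df$fraction,
                     donor_ids = I(donors),
                     plasma_volume_mL = df$plasma_volume_mL,
                     row.names = df$pool_id)
    if ("proteomics" %in% colnames(df)) out$proteomics <- df$proteomics
    out
}

#' @rdname readPoolMetadata
#' @param meta A pool-metadata \code{DataFrame} (list or semicolon-joined
#'   \code{donor_ids}).
#' @return \code{writePoolMetadata}: invisibly, \code{path}.
#' @export
writePoolMetadata <- function(meta, path) {
    df <- as.data.frame(meta)
    if (is.list(df$donor_ids)) {
        df$donor_ids <- vapply(meta$donor_ids, paste, character(1L),
                               collapse = ";")
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

validatePoolMetadata <- function(df) {
    need <- c("pool_id", "sex", "age_group", "fraction", "donor_ids",
              "plasma_volume_mL")
    miss <- setdiff(need, colnames(df))
    if (length(miss) > 0L)
        stop("pool metadata lacks columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$pool_id))
        stop("duplicate pool ids: ",
             paste(unique(df$pool_id[duplicated(df$pool_id)]),
                   collapse = ", "))
    if (!all(df$sex %in% .VALID_SEX)) stop("sex must be 'M' or 'F'")
    if (!all(df$age_group %in% .VALID_AGE))
        stop("age_group must be 'young', 'mid' or 'old'")
    if (!all(df$fraction %in% .VALID_FRACTION))
        stop("fraction must be 'EV' or 'PROT'")
    donors <- if (is.list(df$donor_ids)) df$donor_ids else
        strsplit(as.character(df$donor_ids), ";", fixed = TRUE)
    for (i in seq_along(donors)) {
        d <- donors[[i]]
        if (length(d) == 0L || any(!nzchar(d)))
            stop("pool '", df$pool_id[i], "' has an empty donor list")
        if (anyDuplicated(d))
            stop("pool '", df$pool_id[i], "' repeats a donor")
    }
    if (any(df$plasma_volume_mL <= 0))
        stop("plasma_volume_mL must be strictly positive")
    invisible(TRUE)
}

#' Write a result table deterministically
#'
#' Columns keep their given order; rows are sorted by a \code{rank}
#' column if one exists, otherwise by \code{protein} identifier
#' (ascending, C locale), so repeated writes of the same result are
#' byte-identical. Floating values are written at a fixed precision
#' stated in the file's header comment.
#'
#' @param result A data.frame (or \code{DataFrame}) result table.
#' @param path Output path.
#' @param digits Significant digits for numeric columns.
#' @return Invisibly, \code{path}.
#' @export
writeResultTable <- function(result, path, digits = 6L) {
    df <- as.data.frame(result)
    if (nrow(df) > 0L) {
        if ("rank" %in% colnames(df)) {
            df <- df[order(df$rank), , drop = FALSE]
        } else if ("protein" %in% colnames(df)) {
            old <- Sys.getlocale("LC_COLLATE")
            on.exit(Sys.setlocale("LC_COLLATE", old))
            Sys.setlocale("LC_COLLATE", "C")
            df <- df[order(df$protein), , drop = FALSE]
        }
    }
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(v) {
        ifelse(is.na(v), "NA", format(v, digits = digits, trim = TRUE))
    })
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(sprintf("# numeric values at %d significant digits", digits),
               con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Export a plain gene list
#'
#' One gene symbol per line, suitable for pasting into external
#' enrichment services.
#'
#' @param proteins Character vector of gene symbols.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGeneList <- function(proteins, path) {
    writeLines(sort(unique(as.character(proteins))), path)
    invisible(path)
}

#' Read a particle-count table
#'
#' Columns: \code{pool_id}, \code{instrument} (NTA or NFCM),
#' \code{measured_concentration} (particles per mL of measured
#' suspension), \code{dilution_factor}, \code{prep_volume_mL},
#' \code{plasma_input_mL}. All numeric fields must be strictly positive.
#'
#' @param path Path to a TSV file.
#' @return A validated data.frame.
#' @export
readParticleTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    validateParticleTable(df)
    df
}

validateParticleTable <- function(df) {
    need <- c("pool_id", "instrument", "measured_concentration",
              "dilution_factor", "prep_volume_mL", "plasma_input_mL")
    miss <- setdiff(need, colnames(df))
    if (length(miss) > 0L)
        stop("particle table lacks columns: ", paste(miss, collapse = ", "))
    if (!all(df$instrument %in% c("NTA", "NFCM")))
        stop("instrument must be 'NTA' or 'NFCM'")
    for (col in need[3:6]) {
        if (!is.numeric(df[[col]]) || any(is.na(df[[col]])) ||
            any(df[[col]] <= 0))
            stop("'", col, "' must be strictly positive")
    }
    invisible(TRUE)
}

#' Read or write a plasma-analyte table
#'
#' Analyte columns keep their unit-bearing names (e.g. \code{"ALB (g/L)"},
#' \code{"HDL (mg/dL)"}) verbatim, so unit labels survive a round trip.
#'
#' @param path Path to a TSV file with columns \code{sample_id},
#'   \code{group}, then one column per analyte.
#' @return \code{readAnalyteTable}: a data.frame with original column
#'   names preserved.
#' @export
readAnalyteTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    need <- c("sample_id", "group")
    miss <- setdiff(need, colnames(df))
    if (length(miss) > 0L)
        stop("analyte table lacks columns: ", paste(miss, collapse = ", "))
    if (!all(df$group %in% groupLabels()))
        stop("unknown group labels: ",
             paste(setdiff(df$group, groupLabels()), collapse = ", "))
    vals <- df[, setdiff(colnames(df), need), drop = FALSE]
    if (any(vapply(vals, function(v) any(v < 0, na.rm = TRUE), logical(1L))))
        stop("analyte values must be non-negative")
    df
}

#' @rdname readAnalyteTable
#' @param analytes An analyte data.frame as returned by
#'   [readAnalyteTable()] or [simulateAnalytes()].
#' @return \code{writeAnalyteTable}: invisibly, \code{path}.
#' @export
writeAnalyteTable <- function(analytes, path) {
    utils::write.table(analytes, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
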