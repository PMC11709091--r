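#' Fisher's least significant difference test
#'
#' One-way ANOVA followed by all pairwise comparisons using the pooled
#' mean-square error: for groups i and j,
#' \deqn{t = (\bar y_i - \bar y_j) / \sqrt{MSE (1/n_i + 1/n_j)}}
#' with \eqn{df = N - k}, two-sided p. The unprotected form is used
#' (pairwise results are reported regardless of the omnibus F, which is
#' shown alongside for transparency), and no multiple-testing correction
#' is applied by default; a Bonferroni switch is available. At k = 2 the
#' LSD p-value equals the pooled-variance two-sample t-test.
#'
#' Significance bands follow the conventional star legend:
#' \code{ns} p >= 0.05, \code{*} p < 0.05, \code{**} p <= 0.01,
#' \code{***} p <= 0.001, \code{****} p <= 0.0001.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor or character vector of group labels, same
#'   length.
#' @param bonferroni Apply Bonferroni correction to pairwise p-values.
#' @return A list with \code{pairs} (data.frame: group_i, group_j,
#'   mean_diff, standard_error, t_stat, df, p_value, significance) and
#'   \code{omnibus} (data.frame: F, df1, df2, p_value, mse).
#' @examples
#' fisherLSD(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))$pairs
#' @export
fisherLSD <- function(values, groups, bonferroni = FALSE) {
    groups <- as.character(groups)
    if (length(values) != length(groups))
        stop("values and groups must have equal length")
    ok <- !is.na(values)
    values <- values[ok]; groups <- groups[ok]
    labs <- unique(groups)
    if (length(labs) < 2L) stop("at least two groups are required")
    ns <- table(groups)[labs]
    if (any(ns < 2L))
        stop("every group needs at least 2 values; offending: ",
             paste(labs[ns < 2L], collapse = ", "))
    k <- length(labs)
    N <- length(values)
    means <- tapply(values, groups, mean)[labs]
    grand <- mean(values)
    ss_within <- sum((values - means[groups])^2)
    ss_between <- sum(ns * (means - grand)^2)
    df_w <- N - k
    mse <- ss_within / df_w
    f <- (ss_between / (k - 1L)) / mse
    omnibus <- data.frame(F = f, df1 = k - 1L, df2 = df_w,
                          p_value = stats::pf(f, k - 1L, df_w,
                                              lower.tail = FALSE),
                          mse = mse)
    combos <- utils::combn(labs, 2L)
    n_pairs <- ncol(combos)
    pairs <- do.call(rbind, lapply(seq_len(n_pairs), function(c) {
        gi <- combos[1L, c]; gj <- combos[2L, c]
        se <- sqrt(mse * (1 / ns[[gi]] + 1 / ns[[gj]]))
        diff <- means[[gi]] - means[[gj]]
        tval <- if (se == 0) 0 else diff / se
        p <- 2 * stats::pt(-abs(tval), df_w)
        if (se == 0 && diff == 0) p <- 1
        data.frame(group_i = gi, group_j = gj, mean_diff = diff,
                   standard_error = se, t_stat = tval, df = df_w,
                   p_value = p, stringsAsFactors = FALSE)
    }))
    if (bonferroni)
        pairs$p_value <- pmin(1, pairs$p_value * n_pairs)
    pairs$significance <- significanceBand(pairs$p_value)
    rownames(pairs) <- NULL
    list(pairs = pairs, omnibus = omnibus)
}

#' @rdname fisherLSD
#' @param p Numeric vector of p-values.
#' @return \code{significanceBand}: character vector of star labels.
#' @export
significanceBand <- function(p) {
    ifelse(p <= 1e-4, "****",
    ifelse(p <= 1e-3, "***",
    ifelse(p <= 1e-2, "**",
    ifelse(p < 0.05, "*", "ns"))))
}

#' Normalize a particle measurement to particles per mL of plasma
#'
#' Instruments measure the diluted EV preparation; the plasma-scale
#' concentration is
#' \code{measured_concentration * dilution_factor * prep_volume_mL /
#' plasma_input_mL}, i.e. undo the measurement dilution, convert to
#' particles in the whole preparation, and divide by the plasma volume
#' it came from.
#'
#' @param measurements A particle-measurement data.frame (see
#'   [readParticleTable()]) or a one-row equivalent.
#' @return The input data.frame with a \code{particles_per_mL_plasma}
#'   column appended.
#' @examples
#' m <- data.frame(pool_id = "P1", instrument = "NTA",
#'                 measured_concentration = 1e10, dilution_factor = 1,
#'                 prep_volume_mL = 0.6, plasma_input_mL = 2)
#' normalizeParticles(m)$particles_per_mL_plasma  # 3e9
#' @export
normalizeParticles <- function(measurements) {
    validateParticleTable(measurements)
    measurements$particles_per_mL_plasma <-
        measurements$measured_concentration *
        measurements$dilution_factor *
        measurements$prep_volume_mL /
        measurements$plasma_input_mL
    measurements
}

#' Group statistics for normalized particle concentrations
#'
#' Joins particle measurements to pool metadata, normalizes to particles
#' per mL plasma, and runs [fisherLSD()] across the six groups for each
#' instrument.
#'
#' @param measurements Particle-measurement data.frame.
#' @param pools Pool metadata with \code{pool_id} and \code{group}.
#' @return Named list per instrument of [fisherLSD()] results, with the
#'   normalized table attached as \code{"normalized"}.
#' @export
particleGroupStats <- function(measurements, pools) {
    norm <- normalizeParticles(measurements)
    grp <- pools$group[match(norm$pool_id, pools$pool_id)]
    if (anyNA(grp))
        stop("pools without metadata: ",
             paste(unique(norm$pool_id[is.na(grp)]), collapse = ", "))
    norm$group <- grp
    out <- lapply(split(norm, norm$instrument), function(d)
        fisherLSD(d$particles_per_mL_plasma, d$group))
    attr(out, "normalized") <- norm
    out
}
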