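# Internal helpers shared across modules.

# round() uses round-half-even; report percentages with conventional
# half-up rounding instead so 0.05 at the last kept digit rounds away
# from zero.
roundHalfUp <- function(x, digits = 1L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a per-stage seed from a top-level seed so stages can be re-run
# in isolation with the stream they saw inside the full pipeline.
# Kept below 2^31 - 1 to stay a valid R integer.
deriveSeed <- function(seed, stage) {
    offset <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.double(seed) * 7919 + offset) %% 2147483647)
}

# Run expr with a local RNG state: the caller's stream is untouched.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
        stop("'", name, "' must be a single number", call. = FALSE)
    if (positive && x <= 0)
        stop("'", name, "' must be strictly positive", call. = FALSE)
    invisible(x)
}
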