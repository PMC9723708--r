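# Internal helpers shared across modules.

# stop() with a condition class so callers/tests can match on failure mode
# without parsing messages.
micasm_stop <- function(class, fmt, ...) {
    msg <- sprintf(fmt, ...)
    stop(structure(class = c(class, "micasm_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}

# Seed discipline: every exported stochastic function takes `seed`. When
# seed is NULL the current RNG stream is used (so orchestrators set one
# seed and all stages consume a single reproducible stream); when given,
# the seed is applied locally and the caller's RNG state restored.
with_seed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
        if (has_old) assign(".Random.seed", old, envir = globalenv())
        else rm(".Random.seed", envir = globalenv())
    })
    expr
}

is_count <- function(x, min = 0L) {
    is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
        x == round(x)
}

is_prob <- function(x) {
    is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# Relative abundances of one sample (named numeric).
rel_abund <- function(counts) {
    tot <- sum(counts)
    if (tot <= 0) micasm_stop("micasm_empty_community",
                              "community has zero total abundance")
    counts / tot
}
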