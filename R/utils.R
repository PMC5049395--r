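#' Evaluate an expression with a private RNG state
#'
#' Seeds the Mersenne-Twister generator with `seed`, evaluates `expr`, and
#' restores the caller's RNG state on exit, so simulation functions are
#' reproducible without clobbering the session RNG.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer", call. = FALSE)
    has.seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has.seed)
        old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
        if (has.seed)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of a run draws its own seed deterministically from
#' the experiment's master seed, so stages can be re-run in isolation.
#' Result is always in [1, 2^31 - 2].
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return single integer.
#' @export
#' @examples
#' deriveSeed(1L, "ems")
deriveSeed <- function(seed, stage) {
    stopifnot(is.character(stage), length(stage) == 1L)
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    val <- (as.double(seed) %% 2147483647) * 48271 + h * 69621
    as.integer(val %% 2147483646) + 1L
}

## internal: stop with a classed condition so callers can test error classes
bsaStop <- function(class, msg, ...) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = sprintf(msg, ...), call = sys.call(-1))))
}
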