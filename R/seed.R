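## Hierarchical seed splitting: each generator stage derives its own RNG
## stream from (master seed, stage key) so partial re-runs reproduce exactly.

.MOD31 <- 2147483647  # 2^31 - 1, keeps derived seeds valid R integers

#' Derive a child seed from a master seed and a stage key
#'
#' Deterministic hash of the key string folded into the master seed modulo
#' 2^31 - 1. All generators in the package draw their randomness from child
#' seeds, so re-running a single stage reproduces its output exactly.
#'
#' @param seed integer master seed.
#' @param key character stage label.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
childSeed <- function(seed, key) {
    h <- 0
    for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% .MOD31
    s <- (as.numeric(seed) %% .MOD31) + 1
    as.integer((s * 48271 + h) %% (.MOD31 - 1) + 1)
}

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}
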