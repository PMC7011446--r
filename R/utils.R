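## internal helpers

.rngState <- new.env(parent = emptyenv())
.rngState$stack <- list()

.rngSave <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  .rngState$stack <- c(.rngState$stack,
                       list(get(".Random.seed", envir = globalenv())))
  invisible(NULL)
}

.rngRestore <- function() {
  n <- length(.rngState$stack)
  if (!n) return(invisible(NULL))
  assign(".Random.seed", .rngState$stack[[n]], envir = globalenv())
  .rngState$stack <- .rngState$stack[-n]
  invisible(NULL)
}

# evaluate expr under a temporary seed, leaving the caller's RNG untouched
.withSeed <- function(seed, expr) {
  .rngSave()
  on.exit(.rngRestore())
  set.seed(seed)
  expr
}

# derive a stream of child seeds from one master seed (kept below 2^31)
#' Derive reproducible child seeds from a master seed
#'
#' All randomness in a multi-step analysis flows from one master seed;
#' each step gets its own deterministic child seed so that steps can be
#' re-run independently.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
deriveSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}
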