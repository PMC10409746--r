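# Internal helpers: validation and reproducible seed substreams.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a named seed substream from a master seed
#'
#' Each source of randomness in the package (inoculum jitter, observation
#' noise, permutation streams, ...) draws from its own substream so that
#' freezing one source does not perturb the others and results do not depend
#' on evaluation order. The substream seed is a deterministic 31-bit hash of
#' the master seed and a label.
#'
#' @param master integer master seed.
#' @param label character label naming the randomness source.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, keeps the result a valid 32-bit R integer
  h <- (abs(master) %% m)
  for (b in utf8ToInt(label)) h <- (h * 33 + b) %% m
  as.integer(h)
}

# Evaluate expr with a local RNG state seeded from (master, label).
with_substream <- function(master, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(master, label))
  expr
}

# Full-precision numeric formatting for text serialization (repr round-trip).
format_full <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}
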