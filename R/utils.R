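# Internal helpers shared across modules.

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Pad symbol used when a sequence window runs past a protein terminus.
PAD <- "X"

# Monoisotopic-ish element masses (amu); only relative values matter for
# centre-of-mass computations.
ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.  seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Zero-truncated Poisson draws via inverse-CDF conditioning on X >= 1.
rztpois <- function(n, lambda) {
  stopifnot(lambda > 0)
  stats::qpois(stats::runif(n, stats::ppois(0, lambda), 1), lambda)
}

is_probability <- function(p) is.numeric(p) && length(p) == 1L &&
  is.finite(p) && p >= 0 && p <= 1

is_count <- function(x, positive = FALSE) is.numeric(x) && length(x) == 1L &&
  is.finite(x) && x == round(x) && (if (positive) x >= 1 else x >= 0)

# Coerce a proteome given as AAStringSet or named character to a named
# character vector of sequences.
as_proteome <- function(proteome) {
  if (methods::is(proteome, "AAStringSet")) {
    out <- as.character(proteome)
    names(out) <- names(proteome)
    proteome <- out
  }
  if (!is.character(proteome) || is.null(names(proteome)) ||
      anyNA(names(proteome)) || any(names(proteome) == ""))
    stop("`proteome` must be a named character vector or AAStringSet", call. = FALSE)
  proteome
}

`%||%` <- function(a, b) if (is.null(a)) b else a
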