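# Shared internal helpers.

# The 20 canonical one-letter residue codes, in the column order used by the
# packaged composition table (aliphatics first, as in the printed table).
.RESIDUES <- c("A", "I", "L", "V", "M", "G", "P", "K", "R", "D",
               "E", "Q", "N", "S", "T", "H", "W", "F", "Y", "C")

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter residue codes accepted throughout the package.
#' Ambiguity and non-standard codes (B, J, O, U, X, Z) are rejected by
#' default everywhere, because every downstream statistic (composition,
#' mass, pI) assumes a defined residue.
#'
#' @return Character vector of 20 single-letter codes.
#' @export
canonical_residues <- function() .RESIDUES

# Round half away from zero, the convention used by the printed tables
# (11.27 -> 11.3). R's round() is round-half-even. A tiny epsilon absorbs
# binary representation error just below .5 boundaries.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched. seed = NULL means: use the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# stop() without the call, for cleaner user-facing errors
fail <- function(...) stop(..., call. = FALSE)
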