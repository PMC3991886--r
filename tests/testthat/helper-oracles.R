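# Independent oracles used by the tests. These deliberately re-derive
# results by enumeration / direct tallying, not by calling the code paths
# they check.

# Maximal global alignment score by exhaustive enumeration of all gapped
# alignments, with affine gap cost `open + len * extend` (charged open+ext
# when a gap starts, ext when it continues). Feasible for sequences of up
# to ~7 residues.
brute_force_align_score <- function(a, b, mat, open = 10, ext = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, sc, state) {
    if (i > na && j > nb) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= na && j <= nb) {
      rec(i + 1, j + 1, sc + mat[ca[i], cb[j]], 0L)
    }
    if (i <= na) {  # gap in b
      rec(i + 1, j, sc - ext - if (state == 1L) 0 else open, 1L)
    }
    if (j <= nb) {  # gap in a
      rec(i, j + 1, sc - ext - if (state == 2L) 0 else open, 2L)
    }
  }
  rec(1L, 1L, 0, 0L)
  best
}

# Direct per-character tally of group content, as percent of length.
brute_force_group_pct <- function(seq, members) {
  chars <- strsplit(seq, "")[[1]]
  100 * sum(chars %in% members) / length(chars)
}

# A random canonical-alphabet sequence.
random_sequence <- function(n, alphabet = canonical_residues()) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
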