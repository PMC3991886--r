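# Pairwise global alignment, identity/similarity percentages under a
# residue similarity-group scheme, and MSA conservation shading.

#' Six-group residue similarity scheme
#'
#' The similarity groups used for scoring alignments of the SSB family:
#' group 1 V, L, I, M; group 2 W, F, Y; group 3 E, D; group 4 K, R;
#' group 5 Q, D; group 6 S, T. Two residues are "similar" iff they are
#' identical or co-members of at least one group (D deliberately belongs to
#' two groups, so the relation is not a partition).
#'
#' @param groups List of character vectors; override to experiment with
#'   coarser or finer schemes.
#' @return List of class `ssb_sim_scheme`.
#' @export
similarity_scheme <- function(groups = list(g1 = c("V", "L", "I", "M"),
                                            g2 = c("W", "F", "Y"),
                                            g3 = c("E", "D"),
                                            g4 = c("K", "R"),
                                            g5 = c("Q", "D"),
                                            g6 = c("S", "T"))) {
  stopifnot(all(unlist(groups) %in% .RESIDUES))
  structure(groups, class = "ssb_sim_scheme")
}

#' Are two residues similar under a scheme?
#'
#' @param a,b Single residue characters (vectorized).
#' @param scheme A [similarity_scheme()].
#' @return Logical vector: identical or co-members of at least one group.
#' @export
residues_similar <- function(a, b, scheme = similarity_scheme()) {
  mapply(function(x, y) {
    if (x == y) return(TRUE)
    any(vapply(scheme, function(g) x %in% g && y %in% g, logical(1)))
  }, a, b, USE.NAMES = FALSE)
}

.seq_of <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) fail("expected a single sequence record")
    return(x$residues)
  }
  as.character(x)
}

.substitution_matrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' Optimal global pairwise alignment
#'
#' End-to-end (Needleman-Wunsch) alignment with affine gap costs: a gap of
#' length L costs `gap_open + L * gap_extend`. The dynamic programming is
#' delegated to Biostrings' `pairwiseAlignment`, whose traceback is
#' deterministic; identity and similarity percentages are computed from the
#' aligned strings under `scheme` (see [identity_similarity()]).
#'
#' Defaults are BLOSUM62 with gap open 10 / extend 0.5; PAM-series matrices
#' (`"PAM30"` ... `"PAM250"`) may be selected instead.
#'
#' @param a,b Sequence strings or one-row `ssb_records`.
#' @param matrix Substitution matrix name (any matrix shipped with
#'   Biostrings) or a numeric matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param scheme A [similarity_scheme()].
#' @param denominator See [identity_similarity()].
#' @return List of class `ssb_alignment`: `aligned_a`, `aligned_b`, `score`,
#'   `identity_pct`, `similarity_pct`, and the parameters used.
#' @examples
#' global_align("KDE", "RDE")  # identity 67, similarity 100 (K~R)
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5, scheme = similarity_scheme(),
                         denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  sa <- .seq_of(a); sb <- .seq_of(b)
  if (!nzchar(sa) || !nzchar(sb)) fail("cannot align an empty sequence")
  mat <- .substitution_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  is <- identity_similarity(ga, gb, scheme = scheme, denominator = denominator)
  structure(list(aligned_a = unname(ga), aligned_b = unname(gb),
                 score = Biostrings::score(pa),
                 identity_pct = is[["identity_pct"]],
                 similarity_pct = is[["similarity_pct"]],
                 matrix = if (is.matrix(matrix)) "custom" else matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 denominator = denominator),
            class = "ssb_alignment")
}

#' @export
print.ssb_alignment <- function(x, ...) {
  cat("Global alignment (", x$matrix, ", gap ", x$gap_open, "/",
      x$gap_extend, ")\n", sep = "")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n", sep = "")
  cat(sprintf(" score %.1f | identity %d%% | similarity %d%%\n",
              x$score, x$identity_pct, x$similarity_pct))
  invisible(x)
}

#' Percent identity and similarity of an aligned pair
#'
#' Identity: aligned columns with identical residues; similarity: columns
#' identical or similar under the scheme (gap columns are never similar).
#' Both are divided by the chosen denominator and rounded to whole percent,
#' the precision of published identity/similarity tables. The default
#' denominator is the full alignment length (symmetric in the two
#' sequences); `"shorter"` divides by the shorter de-gapped length instead.
#'
#' @param a,b Gapped aligned strings of equal length (gap = `-`), or `a` may
#'   be an `ssb_alignment` (then `b` is ignored).
#' @param scheme A [similarity_scheme()].
#' @param denominator `"alignment"` or `"shorter"`.
#' @return Named numeric vector `identity_pct`, `similarity_pct` (integers).
#' @export
identity_similarity <- function(a, b = NULL, scheme = similarity_scheme(),
                                denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  if (inherits(a, "ssb_alignment")) { b <- a$aligned_b; a <- a$aligned_a }
  if (nchar(a) != nchar(b)) fail("aligned strings differ in length")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  nongap <- ca != "-" & cb != "-"
  ident <- sum(nongap & ca == cb)
  mism <- which(nongap & ca != cb)
  simil <- ident + if (length(mism)) {
    sum(residues_similar(ca[mism], cb[mism], scheme))
  } else 0L
  denom <- switch(denominator,
                  alignment = length(ca),
                  shorter = min(sum(ca != "-"), sum(cb != "-")))
  if (denom == 0L) fail("zero-length alignment")
  c(identity_pct = round_half_up(100 * ident / denom),
    similarity_pct = round_half_up(100 * simil / denom))
}

#' Per-column conservation class of a multiple alignment
#'
#' For each column of a pre-aligned (gapped) set of sequences, finds the
#' largest cluster of mutually similar residues: for every residue present,
#' the sequences carrying a residue identical-or-similar to it are counted,
#' and the column's conservation is the largest such count divided by the
#' number of sequences (gaps never count as similar). Columns are classed
#' at the conventional alignment-editor thresholds: `"100%"`, `">=80%"`,
#' `">=60%"`, or `"none"`.
#'
#' @param msa Character vector of gapped sequences, all the same length.
#' @param scheme A [similarity_scheme()].
#' @param thresholds Decreasing fractions defining the three shading bands.
#' @return Data frame with columns `column`, `max_fraction`, `class`.
#' @export
shade_msa <- function(msa, scheme = similarity_scheme(),
                      thresholds = c(1.0, 0.8, 0.6)) {
  if (length(msa) < 2L) fail("an MSA needs at least two sequences")
  w <- unique(nchar(msa))
  if (length(w) != 1L) fail("ragged MSA: sequences differ in length")
  mat <- do.call(rbind, strsplit(msa, ""))
  n <- nrow(mat)
  labels <- c("100%", ">=80%", ">=60%")
  frac <- apply(mat, 2, function(col) {
    resid <- unique(col[col != "-"])
    if (!length(resid)) return(0)
    max(vapply(resid, function(r) {
      nong <- col != "-"
      sum(nong & residues_similar(col, rep(r, n), scheme))
    }, numeric(1))) / n
  })
  cls <- vapply(frac, function(f) {
    i <- which(f >= thresholds - 1e-9)[1]
    if (is.na(i)) "none" else labels[i]
  }, character(1))
  data.frame(column = seq_along(frac), max_fraction = frac, class = cls,
             stringsAsFactors = FALSE)
}
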