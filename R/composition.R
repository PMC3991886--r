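# Residue counting, reconstruction of integer counts from rounded
# percentages, and composition-based cold-adaptation indices.

.as_residue_string <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) fail("expected a single sequence record")
    x <- x$residues
  }
  if (!is.character(x) || length(x) != 1L) fail("expected a single sequence")
  x
}

.as_counts <- function(x) {
  if (inherits(x, "ssb_counts")) return(x)
  if (is.character(x) || is.data.frame(x)) return(count_residues(x))
  fail("expected residue counts or a sequence record")
}

# Accept counts, a sequence, or a percentage row; return per-residue
# percentages at printed precision (1 dp).
.as_percent_row <- function(x) {
  if (inherits(x, "ssb_counts")) return(residue_percentages(x))
  if (is.character(x) && length(x) == 1L) return(residue_percentages(count_residues(x)))
  if (is.numeric(x) && !is.null(names(x))) {
    missing_res <- setdiff(.RESIDUES, names(x))
    if (length(missing_res)) {
      fail("percentage row lacks residue(s): ", paste(missing_res, collapse = ", "))
    }
    return(x[.RESIDUES])
  }
  fail("expected counts, a sequence, or a named percentage row")
}

#' Count residues in a protein sequence
#'
#' @param record A sequence string, or a one-row `ssb_records` data frame.
#' @return An object of class `ssb_counts`: a named integer vector over the
#'   20 canonical residues whose sum equals the chain length.
#' @examples
#' count_residues("MAGKK")
#' @export
count_residues <- function(record) {
  seq <- .as_residue_string(record)
  if (!nzchar(seq)) fail("empty sequence")
  .validate_residues(seq, if (is.data.frame(record)) record$id else "<sequence>")
  chars <- strsplit(seq, "")[[1]]
  counts <- vapply(.RESIDUES, function(r) sum(chars == r), integer(1))
  structure(counts, class = "ssb_counts")
}

#' @export
print.ssb_counts <- function(x, ...) {
  cat("Residue counts (length ", sum(x), "):\n", sep = "")
  print(unclass(x)[x > 0])
  invisible(x)
}

#' Per-residue percentages
#'
#' `100 * count / length`, rounded half-away-from-zero to one decimal place,
#' the precision used by published composition tables.
#'
#' @param counts An `ssb_counts` object (or sequence/record, which is
#'   counted first).
#' @return Named numeric vector of 20 percentages.
#' @export
residue_percentages <- function(counts) {
  counts <- .as_counts(counts)
  n <- sum(counts)
  if (n == 0L) fail("zero-length composition")
  round_half_up(100 * unclass(counts) / n, 1)
}

#' Reconstruct integer residue counts from a rounded percentage row
#'
#' Published composition tables print percentages at one decimal place; the
#' underlying integer counts are recovered by rounding `pct * length / 100`
#' to the nearest integer and repairing any deficit or surplus in the total
#' by largest-remainder apportionment (each residue adjusted by at most one,
#' ties broken by descending fractional part and then alphabetically, so the
#' result is deterministic). The reconstruction is then verified: re-rounded
#' percentages must reproduce the input row. Printed tables occasionally
#' contain entries no integer count can produce (a transcription slip), so
#' the verification reports rather than refuses by default.
#'
#' @param row Named numeric vector of 20 percentages (names = residues).
#' @param length Chain length (positive integer).
#' @param check What to do when re-rounded percentages fail to reproduce the
#'   input row: `"warn"` (default), `"error"`, or `"none"`.
#' @return An `ssb_counts` vector summing exactly to `length`.
#' @examples
#' tab <- ssb_composition()
#' reconstruct_counts(tab$percent["DpsSSB", ], tab$lengths["DpsSSB"])
#' @export
reconstruct_counts <- function(row, length, check = c("warn", "error", "none")) {
  check <- match.arg(check)
  row <- .as_percent_row(row)
  length <- as.integer(length)
  if (is.na(length) || length <= 0L) fail("chain length must be a positive integer")
  target <- row * length / 100
  base <- floor(target + 0.5 + 1e-9)
  deficit <- length - sum(base)
  if (abs(deficit) > 20) fail("percentage row is inconsistent with length ", length)
  rem <- target - base
  if (deficit != 0) {
    s <- sign(deficit)
    ord <- order(-s * rem, names(row))
    idx <- ord[seq_len(abs(deficit))]
    base[idx] <- base[idx] + s
  }
  counts <- structure(as.integer(base), names = names(row), class = "ssb_counts")
  if (check != "none") {
    back <- residue_percentages(counts)
    off <- abs(back - row) > 1e-9
    if (any(off)) {
      msg <- paste0("reconstructed counts cannot reproduce the printed ",
                    "percentage for: ",
                    paste(sprintf("%s (%.1f -> %.1f)", names(row)[off],
                                  row[off], back[off]), collapse = ", "))
      if (check == "error") fail(msg) else warning(msg, call. = FALSE)
    }
  }
  counts
}

#' Residue group scheme for cold-adaptation statistics
#'
#' The residue groupings used for composition comparisons of psychrophilic
#' versus mesophilic/thermophilic proteins: charged (D, E, K, H, R), polar
#' (N, Q, S, T, Y), hydrophobic (A, I, L, V, M, G, P, F, W), aromatic
#' (F, W, Y), glycine, proline, amide (Q + N), and a configurable
#' tiny-plus-small set. The hydrophobic set reproduces the published
#' hydrophobic-content figures exactly; the tiny-plus-small default (Taylor's
#' small set) is known *not* to reproduce the published tiny+small figures,
#' whose exact definition was not stated, and is reported as indicative only.
#'
#' @param tiny_small Residue set used for the tiny+small index.
#' @return Named list of residue sets, class `ssb_group_scheme`.
#' @export
group_scheme <- function(tiny_small = c("A", "C", "G", "S", "T", "D", "N", "P", "V")) {
  stopifnot(all(tiny_small %in% .RESIDUES))
  structure(list(
    charged     = c("D", "E", "K", "H", "R"),
    polar       = c("N", "Q", "S", "T", "Y"),
    hydrophobic = c("A", "I", "L", "V", "M", "G", "P", "F", "W"),
    aromatic    = c("F", "W", "Y"),
    glycine     = "G",
    proline     = "P",
    amide       = c("Q", "N"),
    tiny_small  = tiny_small
  ), class = "ssb_group_scheme")
}

#' Residue-group percentage content
#'
#' Sums the member-residue percentages of each requested group, reported at
#' one decimal place. Operating on printed percentages (rather than raw
#' counts) reproduces the published group-content figures digit for digit.
#'
#' @param x Counts, a sequence, or a named percentage row.
#' @param scheme An [group_scheme()] object.
#' @param groups Which groups to report (default: all in the scheme).
#' @return Named numeric vector of group percentages (1 dp).
#' @examples
#' tab <- ssb_composition()
#' group_fractions(tab$percent["DpsSSB", ], groups = "charged")  # 24.5
#' @export
group_fractions <- function(x, scheme = group_scheme(), groups = names(scheme)) {
  row <- .as_percent_row(x)
  unknown <- setdiff(groups, names(scheme))
  if (length(unknown)) fail("unknown group(s): ", paste(unknown, collapse = ", "))
  out <- vapply(groups, function(g) {
    members <- scheme[[g]]
    if (!length(members)) return(0)
    round_half_up(sum(row[members]), 1)
  }, numeric(1))
  names(out) <- groups
  out
}

#' Arginine share of the basic residues, Arg/(Arg + Lys)
#'
#' A classic cold-adaptation indicator: psychrophilic proteins tend to favor
#' Lys over Arg, lowering the ratio. Computed from percentages or counts
#' (the two give identical results) and rounded to two decimals.
#'
#' @param x Counts, a sequence, or a named percentage row.
#' @return Ratio in `[0, 1]` (2 dp); `NA` with a warning when Arg + Lys = 0.
#' @examples
#' tab <- ssb_composition()
#' arg_lys_ratio(tab$percent["DpsSSB", ])  # 0.63
#' @export
arg_lys_ratio <- function(x) {
  row <- .as_percent_row(x)
  denom <- row["R"] + row["K"]
  if (denom == 0) {
    warning("Arg + Lys is zero; ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  unname(round_half_up(row["R"] / denom, 2))
}

#' Full composition profile of a protein
#'
#' Bundles counts, per-residue percentages, group percentages and the
#' Arg/(Arg+Lys) ratio.
#'
#' @param x A sequence record/string, or a named percentage row (then
#'   `length` must be supplied so counts can be reconstructed).
#' @param length Chain length, required when `x` is a percentage row.
#' @param scheme An [group_scheme()].
#' @param ... Passed to [reconstruct_counts()] when reconstructing.
#' @return A list of class `ssb_composition_profile` with elements `counts`,
#'   `percent`, `group_percent`, `arg_ratio`.
#' @export
composition_profile <- function(x, length = NULL, scheme = group_scheme(), ...) {
  if (is.numeric(x)) {
    if (is.null(length)) fail("`length` is required for a percentage row")
    counts <- reconstruct_counts(x, length, ...)
    pct <- .as_percent_row(x)
  } else {
    counts <- count_residues(x)
    pct <- residue_percentages(counts)
  }
  structure(list(counts = counts,
                 percent = pct,
                 group_percent = group_fractions(pct, scheme),
                 arg_ratio = arg_lys_ratio(pct)),
            class = "ssb_composition_profile")
}
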