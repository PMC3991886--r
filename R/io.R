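# Sequence and table I/O: FASTA records, composition tables, packaged
# reference tables.

.validate_residues <- function(seq, id) {
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), .RESIDUES)
  if (length(bad)) {
    fail(sprintf("record '%s' contains non-canonical residue(s): %s",
                 id, paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file into a data frame
#' of validated sequence records. Sequences are upper-cased and internal
#' whitespace removed. Residues outside the 20-letter canonical alphabet are
#' an error by default; with `on_invalid = "skip"` the offending record is
#' dropped with a warning instead.
#'
#' @param path Path to a FASTA file.
#' @param on_invalid `"error"` (default) or `"skip"`.
#' @return A data frame of class `ssb_records` with columns `id`,
#'   `description` and `residues`, one row per record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x toy", "MAG", "K"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, on_invalid = c("error", "skip")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) fail("no such file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) fail("FASTA file contains no records: ", path)
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  keep <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) fail(sprintf("record '%s' has an empty sequence", id[i]))
    ok <- tryCatch({ .validate_residues(seqs[i], id[i]); TRUE },
                   error = function(e) {
                     if (on_invalid == "error") stop(e)
                     warning(conditionMessage(e), ", record skipped", call. = FALSE)
                     FALSE
                   })
    keep[i] <- ok
  }
  out <- data.frame(id = id[keep], description = desc[keep],
                    residues = unname(seqs[keep]), stringsAsFactors = FALSE)
  class(out) <- c("ssb_records", "data.frame")
  out
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: writing then re-reading is the identity on
#' `(id, residues)`.
#'
#' @param records An `ssb_records` data frame (or anything with `id`,
#'   `description`, `residues` columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(records$residues)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a residue-composition table
#'
#' Reads a CSV/TSV table of per-protein residue percentages (one row per
#' protein, 20 residue columns at printed one-decimal precision, plus
#' `protein` and `length` columns). Percentages are kept exactly as printed
#' and never renormalized. Row sums are checked against 100 within
#' `sum_tol`: published tables carry rounding error and occasional
#' transcription slips, so the default slack is deliberately generous while
#' still catching fraction-scale or truncated rows.
#'
#' @param path Path to a CSV (or TSV) file.
#' @param sum_tol Permitted deviation of each row sum from 100 (percentage
#'   points).
#' @return A list of class `ssb_composition_table` with elements `percent`
#'   (numeric matrix, proteins x 20 residues) and `lengths` (named vector,
#'   `NA` where the chain length is not known).
#' @seealso [ssb_composition()] for the packaged reference table.
#' @export
read_composition_table <- function(path, sum_tol = 3) {
  if (!file.exists(path)) fail("no such file: ", path)
  first <- readLines(path, n = 1L)
  df <- if (grepl("\t", first)) read.delim(path, check.names = FALSE)
        else read.csv(path, check.names = FALSE)
  need <- c("protein", "length", .RESIDUES)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    fail("composition table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  pct <- as.matrix(df[, .RESIDUES])
  rownames(pct) <- df$protein
  storage.mode(pct) <- "double"
  sums <- rowSums(pct)
  off <- abs(sums - 100) > sum_tol
  if (any(off)) {
    fail("composition row sum outside 100 +/- ", sum_tol, " for: ",
         paste(sprintf("%s (%.1f)", df$protein[off], sums[off]), collapse = ", "))
  }
  lengths <- df$length
  names(lengths) <- df$protein
  structure(list(percent = pct, lengths = lengths),
            class = "ssb_composition_table")
}

#' Packaged SSB composition reference table
#'
#' Per-residue percentage composition (one decimal place) of the seven
#' psychrophilic SSBs, EcoSSB, and the thermophilic TteSSB3 and TmaSSB used
#' as comparators, as published. Chain lengths are included where published;
#' they are `NA` for the two thermophilic proteins, whose lengths were not
#' reported alongside the table.
#'
#' @return An `ssb_composition_table`; see [read_composition_table()].
#' @export
ssb_composition <- function() {
  read_composition_table(
    system.file("extdata", "ssb_composition.csv", package = "psychrossb",
                mustWork = TRUE))
}

#' Packaged SSB sequence-level reference values
#'
#' Published sequence-derived characteristics of the eight SSBs under
#' comparison: monomer mass (kDa), chain and C-terminal domain lengths,
#' C-terminal signature residues, isoelectric point, aliphatic index,
#' cysteine count, and (where measured) the native mass from analytical gel
#' filtration.
#'
#' @return A data frame with one row per protein.
#' @export
ssb_reference <- function() {
  read.csv(system.file("extdata", "ssb_reference.csv", package = "psychrossb",
                       mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Packaged SSB thermal reference values
#'
#' Published thermal characteristics: melting temperature of the 44-bp test
#' duplex alone (`duplex_tm_free_c`) and in the presence of each SSB
#' (`duplex_tm_complex_c`), and the DSC unfolding peak temperature of the
#' protein itself (`dsc_tm_c`).
#'
#' @return A data frame with one row per protein.
#' @export
ssb_thermal_reference <- function() {
  read.csv(system.file("extdata", "ssb_thermal_reference.csv",
                       package = "psychrossb", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Packaged SSB thermal-inactivation half-life table
#'
#' Published half-lives of ssDNA-binding activity (minutes) after incubation
#' at 60-100 degrees C, read from inactivation time courses on the grid
#' 0, 1, 2.5, 5, 10, 15, 30, 45, 60 min.
#'
#' @return A data frame with columns `protein`, `temperature_c`,
#'   `half_life_min`.
#' @export
ssb_halflife_reference <- function() {
  read.csv(system.file("extdata", "ssb_halflife_reference.csv",
                       package = "psychrossb", mustWork = TRUE),
           stringsAsFactors = FALSE)
}
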