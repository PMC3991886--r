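# Orchestration: one call running every applicable analysis stage over a
# set of inputs and writing a reproducible report bundle.

#' Read a flat key = value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment; values that parse
#' as numbers become numeric. Unknown keys are kept (and echoed in the
#' provenance record).
#'
#' @param path Path to the configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) fail("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  vals <- lapply(kv, function(p) {
    v <- p[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[`, character(1), 1)
  vals
}

.stage <- function(results, name, expr) {
  r <- tryCatch(list(ok = TRUE, value = expr),
                error = function(e) {
                  message("stage '", name, "' failed: ", conditionMessage(e))
                  list(ok = FALSE, error = conditionMessage(e))
                })
  results[[name]] <- r
  results
}

#' Run the full characterization workflow
#'
#' Runs every stage for which the configuration provides input and writes a
#' report bundle to `out_dir`:
#'
#' * `profile.csv` — per-protein residue percentages, group percentages,
#'   Arg/(Arg+Lys) ratio, monomer mass, pI, aliphatic index, Cys count
#'   (from `fasta` and/or `composition` input);
#' * `similarity.csv` — pairwise identity/similarity percentages for all
#'   sequence pairs (from `fasta`, when it holds 2+ records);
#' * `titration_fit.json`, `melting_tm.json`, `half_life.json`,
#'   `gel_filtration.json` — fit reports for any instrument-style CSV
#'   inputs provided;
#' * `provenance.json` — config echo, package version and seed.
#'
#' A failing stage is reported (with its input) and the remaining stages
#' still run; outputs are byte-identical across runs with identical config
#' and inputs.
#'
#' @param config Named list (or path to a flat key = value file, see
#'   [read_run_config()]). Recognized keys: `fasta`, `composition`
#'   (composition CSV), `titration` (CSV: added_oligo, fluorescence),
#'   `melting` (CSV: temperature, signal), `timecourse` (CSV: time,
#'   fraction_bound), `calibration` (CSV: mass_kda, retention_min),
#'   `sample_retention`, `monomer_mass_kda`, `protein_nmol`, `oligo_length`,
#'   `titration_mode`, `out_dir`, `seed`.
#' @return Invisibly, a list with per-stage results (`ok`/`value`/`error`).
#' @export
run_characterization <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  results <- list()

  records <- NULL
  if (!is.null(config$fasta)) {
    results <- .stage(results, "read_fasta", read_fasta(config$fasta))
    if (results$read_fasta$ok) records <- results$read_fasta$value
  }

  results <- .stage(results, "profile", {
    rows <- list()
    if (!is.null(records)) {
      for (i in seq_len(nrow(records))) {
        prof <- composition_profile(records$residues[i])
        phys <- physchem_report(prof$counts)
        rows[[records$id[i]]] <- data.frame(
          protein = records$id[i], t(prof$percent), t(prof$group_percent),
          arg_ratio = prof$arg_ratio, phys, check.names = FALSE)
      }
    }
    if (!is.null(config$composition)) {
      tab <- read_composition_table(config$composition)
      for (p in rownames(tab$percent)) {
        row <- tab$percent[p, ]
        grp <- group_fractions(row)
        base <- data.frame(protein = p, t(row), t(grp),
                           arg_ratio = arg_lys_ratio(row), check.names = FALSE)
        if (!is.na(tab$lengths[p])) {
          counts <- suppressWarnings(reconstruct_counts(row, tab$lengths[p]))
          base <- cbind(base, physchem_report(counts))
        }
        rows[[p]] <- base
      }
    }
    if (!length(rows)) NULL else {
      all_cols <- Reduce(union, lapply(rows, names))
      rows <- lapply(rows, function(r) { r[setdiff(all_cols, names(r))] <- NA; r[all_cols] })
      profiles <- do.call(rbind, rows)
      write.csv(profiles, file.path(out_dir, "profile.csv"), row.names = FALSE)
      file.path(out_dir, "profile.csv")
    }
  })

  if (!is.null(records) && nrow(records) >= 2L) {
    results <- .stage(results, "similarity", {
      prs <- utils::combn(nrow(records), 2)
      tab <- apply(prs, 2, function(ij) {
        al <- global_align(records$residues[ij[1]], records$residues[ij[2]])
        data.frame(a = records$id[ij[1]], b = records$id[ij[2]],
                   identity_pct = al$identity_pct,
                   similarity_pct = al$similarity_pct)
      })
      tab <- do.call(rbind, tab)
      write.csv(tab, file.path(out_dir, "similarity.csv"), row.names = FALSE)
      file.path(out_dir, "similarity.csv")
    })
  }

  if (!is.null(config$titration)) {
    results <- .stage(results, "titration", {
      df <- read.csv(config$titration)
      curve <- structure(list(
        protein_nmol = config$protein_nmol %||% 1.5,
        oligo_length = config$oligo_length %||% 76,
        added_oligo = df[[1]], relative_fluorescence = df[[2]],
        salt_mM = config$salt_mM %||% NA), class = "ssb_titration")
      fit <- fit_site_size(curve, mode = config$titration_mode %||% "breakpoint")
      jsonlite::write_json(unclass(fit), file.path(out_dir, "titration_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      file.path(out_dir, "titration_fit.json")
    })
  }

  if (!is.null(config$melting)) {
    results <- .stage(results, "melting", {
      df <- read.csv(config$melting)
      tm <- extract_tm(df[[1]], df[[2]], method = config$tm_method %||% "midpoint")
      jsonlite::write_json(unclass(tm), file.path(out_dir, "melting_tm.json"),
                           auto_unbox = TRUE, digits = NA)
      file.path(out_dir, "melting_tm.json")
    })
  }

  if (!is.null(config$timecourse)) {
    results <- .stage(results, "half_life", {
      df <- read.csv(config$timecourse)
      hl <- half_life(df[[1]], df[[2]])
      jsonlite::write_json(unclass(hl), file.path(out_dir, "half_life.json"),
                           auto_unbox = TRUE, digits = NA)
      file.path(out_dir, "half_life.json")
    })
  }

  if (!is.null(config$calibration)) {
    results <- .stage(results, "gel_filtration", {
      std <- read.csv(config$calibration)
      cal <- fit_calibration(std)
      rep <- list(slope = cal$slope, intercept = cal$intercept,
                  r_squared = cal$r_squared)
      if (!is.null(config$sample_retention)) {
        m <- estimate_native_mass(cal, config$sample_retention)
        rep$native_mass_kda <- as.numeric(m)
        rep$extrapolated <- attr(m, "extrapolated")
        if (!is.null(config$monomer_mass_kda)) {
          call <- oligomer_state(as.numeric(m), config$monomer_mass_kda)
          rep$ratio <- call$ratio
          rep$state_label <- call$state_label
        }
      }
      jsonlite::write_json(rep, file.path(out_dir, "gel_filtration.json"),
                           auto_unbox = TRUE, digits = NA)
      file.path(out_dir, "gel_filtration.json")
    })
  }

  prov <- list(package = "psychrossb",
               version = as.character(utils::packageVersion("psychrossb")),
               seed = seed,
               config = config,
               stages = lapply(results, function(r) r$ok))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  failed <- names(results)[!vapply(results, `[[`, logical(1), "ok")]
  if (length(failed)) {
    message("completed with failed stage(s): ", paste(failed, collapse = ", "))
  }
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
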