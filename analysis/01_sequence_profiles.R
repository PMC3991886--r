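#!/usr/bin/env Rscript
# Sequence-derived characterization of the SSB panel.
#
# From the packaged composition table (percentages at printed precision plus
# chain lengths), reconstructs integer residue counts and derives the
# monomer mass, isoelectric point, aliphatic index and cysteine count, then
# the cold-adaptation composition statistics (charged / polar / hydrophobic /
# aromatic content, Gly and Pro content, amide content, Arg/(Arg+Lys)).
# Results are compared side by side with the published reference values.

suppressMessages(library(psychrossb))
dir.create("results", showWarnings = FALSE)

tab3 <- ssb_composition()
ref <- ssb_reference()

rows <- lapply(rownames(tab3$percent), function(p) {
  grp <- group_fractions(tab3$percent[p, ])
  base <- data.frame(protein = p, t(grp),
                     arg_ratio = arg_lys_ratio(tab3$percent[p, ]))
  if (!is.na(tab3$lengths[p])) {
    counts <- suppressWarnings(reconstruct_counts(tab3$percent[p, ], tab3$lengths[p]))
    base <- cbind(base, physchem_report(counts))
  }
  base
})
cols <- Reduce(union, lapply(rows, names))
rows <- lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] })
profile <- do.call(rbind, rows)
write.csv(profile, "results/sequence_profiles.csv", row.names = FALSE)

cmp <- merge(profile, ref, by = "protein")
cat("Physicochemical values vs published reference:\n")
print(cmp[, c("protein", "monomer_mass_kda.x", "monomer_mass_kda.y",
              "pi.x", "pi.y", "aliphatic_index.x", "aliphatic_index.y",
              "cys_count.x", "cys_count.y")], row.names = FALSE)

exact_ai <- all(cmp$aliphatic_index.x == cmp$aliphatic_index.y)
cat(sprintf("\nAliphatic index reproduced exactly for %d/%d proteins.\n",
            sum(cmp$aliphatic_index.x == cmp$aliphatic_index.y), nrow(cmp)))
cat(sprintf("Monomer mass within 0.1 kDa for %d/%d; pI within 0.05 for %d/%d\n",
            sum(abs(cmp$monomer_mass_kda.x - cmp$monomer_mass_kda.y) <= 0.1 + 1e-9),
            nrow(cmp),
            sum(abs(cmp$pi.x - cmp$pi.y) <= 0.05), nrow(cmp)))
cat("(the pI outliers FpsSSB/PinSSB trace to printing inconsistencies in the\n",
    "composition table; see the methods vignette)\n")
cat("\nCold-adaptation statistics written to results/sequence_profiles.csv\n")
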