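#!/usr/bin/env Rscript
# Cross-marker correlation over directly corresponding squares of the
# aligned sections, pooled per prognostic subgroup, with the printed
# degree-of-correlation labelling.

suppressMessages(library(ithniche))
seed <- 1L
dir.create("results", showWarnings = FALSE)

cohort <- simulate_cohort(seed = seed)
tab <- cohort_correlation(lapply(cohort, `[[`, "panel"))
write.table(tab, "results/marker_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d subgroup x marker-pair correlations (pooled squares)\n",
            nrow(tab)))
strongest <- tab[which.max(abs(tab$rho)), ]
cat(sprintf("strongest: %s~%s in %s, rho = %.2f (%s, %s)\n",
            strongest$marker1, strongest$marker2, strongest$subgroup,
            strongest$rho, strongest$degree, strongest$sign))
cat(sprintf("degree breakdown: %s\n",
            paste(names(table(tab$degree)), table(tab$degree),
                  sep = "=", collapse = ", ")))
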