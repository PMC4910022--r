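#!/usr/bin/env Rscript
# Simulate the study-condition inputs: a 30-tumour cohort (9 pT1M0, 10
# pT1M1, 11 pT3/4) of five aligned marker grids per tumour, and an
# 8-patient set of matched central/peripheral variant calls with planted
# artifacts. Writes example grids, heat maps and the full variant fixture
# under results/simulated/.

suppressMessages(library(ithniche))
seed <- 1L
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- simulate_cohort(seed = seed)
saveRDS_path <- NULL  # grids are regenerated from the seed, not stored

# one worked tumour: grid TSVs and heat maps for all five markers
t1 <- cohort[[1]]$panel
for (m in names(t1$grids)) {
  heatmap_export(t1$grids[[m]],
                 png_path = file.path(out, sprintf("T01_%s_heatmap.png", m)),
                 tsv_path = file.path(out, sprintf("T01_%s_grid.tsv", m)))
}
n_sq <- vapply(cohort, function(x) sum(x$truth$mask), integer(1))
cat(sprintf("simulated %d tumours; %.1f tumour squares per section (mean)\n",
            length(cohort), mean(n_sq)))
cat(sprintf("subgroups: %s\n",
            paste(names(table(vapply(cohort, function(x) x$panel$subgroup,
                                     character(1)))), collapse = ", ")))

vsim <- simulate_variant_tables(variant_sim_config(seed = seed + 1L),
                                out_dir = file.path(out, "variants"))
cat(sprintf("simulated %d variant records for %d patients (%d planted artifacts)\n",
            nrow(vsim$records), vsim$cfg$n_patients,
            sum(vsim$truth$artifact != "none")))
cat("wrote", out, "\n")
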