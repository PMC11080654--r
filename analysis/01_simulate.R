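#!/usr/bin/env Rscript
# Simulate the default breeding-program scenario: 62 inbred parents in two
# heterotic pools, 506 inter-group hybrids genotyped at 2000 markers, and a
# 3-site x 2-year trial series (unbalanced hybrid sets, augmented and RCBD
# designs) with 20 traits in three correlated groups.
suppressMessages(library(hybridgp))

dir.create("results", showWarnings = FALSE)
seed <- 2024

scn <- simulate_scenario(n_parents = 62, n_markers = 2000, n_hybrids = 506,
                         n_sites = 3, seed = seed)

write_dosage_matrix(scn$panel, "results/parents_dosage.tsv")
write.table(scn$plan, "results/cross_plan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(scn$pheno, "results/phenotypes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
saveRDS(scn, "results/scenario.rds")   # working cache for the later steps

env_sizes <- vapply(scn$design$hybrids_per_env, length, 0L)
cat("Simulated", nrow(scn$plan), "hybrids from",
    length(scn$panel$parent_ids), "parents;",
    nrow(scn$pheno), "phenotype records over",
    nrow(scn$design$envs), "environments\n")
cat("Hybrids per environment:\n")
print(env_sizes)
cat("Year-to-year overlap at site 1:",
    length(intersect(scn$design$hybrids_per_env$S120,
                     scn$design$hybrids_per_env$S121)), "hybrids\n")
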