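#!/usr/bin/env Rscript
# Stage 1: per-environment, per-trait REML. Variance components, entry-mean
# heritabilities, genotype LRTs and BLUP correlations between traits; BLUEs
# (genotype fixed) are carried to the genomic models in stage 2.
suppressMessages(library(hybridgp))

scn <- readRDS("results/scenario.rds")
traits <- unique(scn$pheno$trait)[1:8]   # a representative trait subset

s1 <- stage1_all(scn$pheno, traits = traits)
write.table(s1$summary, "results/stage1_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(s1$blues, "results/stage1_blues.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(s1, "results/stage1.rds")

cat("Heritability (entry-mean) by environment and trait:\n")
print(round(with(s1$summary, tapply(h2, list(env, trait), mean)), 2))

## genotype LRT per env x trait
lrt_rows <- list()
for (e in names(s1$fits)) for (tr in names(s1$fits[[e]])) {
  full <- s1$fits[[e]][[tr]]$random
  red <- fit_env_model(subset(scn$pheno, env == e & trait == tr),
                       "random", drop_random = "genotype")
  l <- lrt_random_effect(full, red)
  lrt_rows[[paste(e, tr)]] <- data.frame(
    env = e, trait = tr, statistic = l$statistic, p_value = l$p_value,
    significant = l$significant)
}
lrt <- do.call(rbind, lrt_rows)
write.table(lrt, "results/stage1_lrt.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\nGenotype effect significant (LRT, 5%%) in %d of %d env x trait cells\n",
            sum(lrt$significant), nrow(lrt)))

## BLUP correlations between traits within the largest environment
env_big <- names(which.max(table(s1$blues$env)))
fits_env <- lapply(s1$fits[[env_big]], `[[`, "random")
bc <- blup_correlations(fits_env, alpha = 0.10)
write.table(bc, "results/stage1_blup_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nBLUP correlations in %s: %d of %d pairs significant at 10%%\n",
            env_big, sum(bc$significant), nrow(bc)))
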