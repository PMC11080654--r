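#!/usr/bin/env Rscript
# CV1 (untested hybrids in tested environments): five-fold cross-validation
# over the model grid in the year-1 environment of site 1, three traits.
# Chains are kept short here (2000 iterations); the published settings
# (30000 / 3000 / 10) are available through chain_config() defaults.
suppressMessages(library(hybridgp))

s1 <- readRDS("results/stage1.rds")
kern <- readRDS("results/kernels.rds")
seed <- 2024

b20 <- s1$blues[s1$blues$env == "S120", ]
traits <- intersect(c("DTP", "EL", "STC"), unique(b20$trait))
specs <- enumerate_model_grid()[c(1, 2, 5, 6)]     # AG, ADG, AR, ADR
folds <- make_cv1_folds(unique(b20$hybrid_id), k = 5, n_repeats = 3,
                        seed = seed)
acc <- run_scheme(b20, kern, specs, folds,
                  chain_config(2000, 500, 5, seed = seed), traits = traits)
write.table(acc, "results/cv1_accuracy.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

agg <- aggregate_accuracy(acc)
write.table(agg, "results/cv1_accuracy_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("CV1 mean accuracy (trait x model):\n")
print(round(with(agg, tapply(mean_accuracy, list(trait, model), mean)), 3))
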