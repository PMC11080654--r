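#!/usr/bin/env Rscript
# CV0 (tested hybrids, untested environment) and CV00 (untested hybrids,
# untested environment): within-site across-year prediction for each site,
# plus one across-site run with the G x E models (environment fixed effects
# and Hadamard-product interaction kernels).
suppressMessages(library(hybridgp))

s1 <- readRDS("results/stage1.rds")
kern <- readRDS("results/kernels.rds")
seed <- 2024
spec_ag <- model_spec("GBLUP", "A", "single")
spec_adg <- model_spec("GBLUP", "AD", "single")
ch <- chain_config(2000, 500, 5, seed = seed)
traits <- intersect(c("DTP", "EL"), unique(s1$blues$trait))

rows <- list()
for (site in c("S1", "S2", "S3")) {
  tr_env <- paste0(site, "20"); te_env <- paste0(site, "21")
  p0 <- make_cv0_split(s1$blues, tr_env, te_env)
  p00 <- make_cv00_split(s1$blues, tr_env, te_env)
  for (p in list(p0, p00))
    rows[[paste(site, p$scheme)]] <-
      run_scheme(s1$blues, kern, list(spec_ag, spec_adg), p, ch,
                 traits = traits)
}
acc <- do.call(rbind, rows)
write.table(acc, "results/cv0_cv00_accuracy.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Within-site across-year accuracy (scheme x model, mean over sites/traits):\n")
print(round(with(acc, tapply(accuracy, list(scheme, model), mean)), 3))

## across-site: train on all year-1 environments, predict site 1 year 2
spec_gxe <- model_spec("GBLUP", "A", "single", gxe = TRUE)
p0x <- make_cv0_split(s1$blues, c("S120", "S220", "S320"), "S121")
p00x <- make_cv00_split(s1$blues, c("S120", "S220", "S320"), "S121")
acc_x <- rbind(run_scheme(s1$blues, kern, spec_gxe, p0x, ch, traits = traits),
               run_scheme(s1$blues, kern, spec_gxe, p00x, ch, traits = traits))
write.table(acc_x, "results/across_site_gxe_accuracy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nAcross-site prediction of S121 with the G x E model:\n")
print(acc_x[, c("scheme", "model", "trait", "accuracy", "n_test")])
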