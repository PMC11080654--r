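# File formats, scenario configuration and the end-to-end pipeline driver.

#' Read parent genotypes
#'
#' `dosage_matrix` files are tab-delimited with a header row of marker ids
#' and sample ids in the first column; missing calls are `NA`. VCF input
#' (requires the vcfR package) keeps biallelic records only; multi-allelic
#' sites are skipped with a warning. Unphased/phased GT fields are both
#' accepted and converted to alternate-allele dosage 0/1/2.
#'
#' @param path input file
#' @param format `"dosage_matrix"` or `"vcf"`
#' @param group optional group label per sample (recycled); defaults to a
#'   single group
#' @return a `parent_panel` (without simulation provenance)
#' @export
read_genotypes <- function(path, format = c("dosage_matrix", "vcf"),
                           group = NULL) {
  format <- match.arg(format)
  if (format == "dosage_matrix") {
    d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(d[[1]])
    if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
    G <- as.matrix(d[, -1, drop = FALSE])
    storage.mode(G) <- "double"
    rownames(G) <- ids
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    alt <- vcfR::getALT(v)
    multi <- grepl(",", alt)
    if (any(multi)) {
      warning(sum(multi), " multi-allelic site(s) skipped")
      v <- v[!multi, ]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    ids <- colnames(gt)
    if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
    dose <- function(x) {
      x <- gsub("\\|", "/", x)
      ifelse(is.na(x) | x == "./.", NA_real_,
             ifelse(x == "0/0", 0, ifelse(x %in% c("0/1", "1/0"), 1,
                                          ifelse(x == "1/1", 2, NA_real_))))
    }
    G <- t(apply(gt, 1, dose))
    colnames(G) <- ids
    rownames(G) <- rownames(gt)
    G <- t(G)
  }
  if (nrow(G) < 2) stop("need at least two samples")
  group <- rep(group %||% "G1", length.out = nrow(G))
  structure(list(
    parent_ids = rownames(G),
    group = stats::setNames(group, rownames(G)),
    genotypes = G,
    marker_ids = colnames(G),
    allele_freq = colMeans(G, na.rm = TRUE) / 2
  ), class = "parent_panel")
}

#' Write a dosage matrix
#'
#' Tab-delimited, header row of marker ids, sample id in the first column,
#' missing encoded as `NA`. Round-trips through [read_genotypes()].
#'
#' @param panel a `parent_panel`
#' @param path output file
#' @export
write_dosage_matrix <- function(panel, path) {
  d <- data.frame(sample_id = panel$parent_ids, panel$genotypes,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a parent panel as a minimal biallelic VCF
#'
#' Emits VCFv4.2 text with GT-only unphased genotypes (alleles A/T as
#' placeholders) on synthetic marker positions.
#'
#' @param panel a `parent_panel`
#' @param path output file
#' @export
write_vcf <- function(panel, path) {
  G <- panel$genotypes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$parent_ids), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1])
    writeLines(paste(c("1", j, panel$marker_ids[j], "A", "T", ".", "PASS",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write / read a square kernel matrix
#'
#' Tab-delimited square matrix with the ids as header row and first column.
#'
#' @param K square matrix with dimnames
#' @param path file path
#' @export
write_kernel <- function(K, path) {
  d <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(d[, -1, drop = FALSE])
  rownames(K) <- as.character(d[[1]])
  storage.mode(K) <- "double"
  K
}

#' Read a YAML scenario file
#'
#' A scenario file fully specifies a simulation: any argument of
#' [simulate_scenario()] may appear as a key (trait tables as lists of
#' records).
#'
#' @param path YAML file
#' @return argument list for [simulate_scenario()]
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$trait_config))
    cfg$trait_config <- do.call(rbind, lapply(cfg$trait_config, as.data.frame))
  cfg
}

#' Run the full two-stage pipeline on a synthetic scenario
#'
#' simulate -> marker QC -> hybrid coding -> kernels -> stage-1 REML ->
#' CV1 model runs, writing every intermediate artifact plus a manifest under
#' `out_dir`. Intended as the scripted end-to-end entry point; the numbered
#' scripts under `analysis/` drive the same functions step by step.
#'
#' @param config list (or path to a YAML file) with optional elements
#'   `scenario` (arguments of [simulate_scenario()]), `qc` (maf_min,
#'   miss_max), `models` (labels, default `"AG"`), `chain` (n_iter, burn_in,
#'   thin), `cv` (k, n_repeats, env, traits) and `seed`
#' @param out_dir output directory (created)
#' @return invisibly, a list with the scenario, stage-1 results, the
#'   accuracy table and the manifest
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("hybridgp_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sc_args <- config$scenario %||% list(n_parents = 40, n_markers = 500,
                                       n_hybrids = 150, n_sites = 1,
                                       trait_config = default_trait_config(3))
  sc_args$seed <- seed
  scn <- do.call(simulate_scenario, sc_args)
  write_dosage_matrix(scn$panel, file.path(out_dir, "parents_dosage.tsv"))
  utils::write.table(scn$plan, file.path(out_dir, "cross_plan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scn$pheno, file.path(out_dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  qc <- config$qc %||% list()
  fa <- filter_markers(scn$hybrids$additive,
                       maf_min = qc$maf_min %||% 0.01,
                       miss_max = qc$miss_max %||% 0.30)
  keep <- colnames(fa$genotypes)
  hybrids <- structure(list(
    hybrid_ids = scn$hybrids$hybrid_ids,
    additive = fa$genotypes,
    dominance = scn$hybrids$dominance[, keep, drop = FALSE],
    marker_ids = keep), class = "hybrid_genotypes")
  utils::write.table(
    data.frame(marker = names(fa$report$flags), flag = fa$report$flags),
    file.path(out_dir, "marker_qc.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  kern <- build_kernel_set(hybrids)
  for (nm in names(kern))
    write_kernel(kern[[nm]], file.path(out_dir, paste0("kernel_", nm, ".tsv")))

  s1 <- stage1_all(scn$pheno)
  utils::write.table(s1$summary, file.path(out_dir, "stage1_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(s1$blues, file.path(out_dir, "stage1_blues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cv <- config$cv %||% list()
  env <- cv$env %||% s1$blues$env[1]
  chain_cfg <- config$chain %||% list()
  chain <- chain_config(chain_cfg$n_iter %||% 2000,
                        chain_cfg$burn_in %||% 500,
                        chain_cfg$thin %||% 5, seed = seed)
  specs <- lapply(config$models %||% "AG", parse_model_label)
  benv <- s1$blues[s1$blues$env == env, , drop = FALSE]
  folds <- make_cv1_folds(unique(benv$hybrid_id), k = cv$k %||% 5,
                          n_repeats = cv$n_repeats %||% 1, seed = seed)
  acc <- run_scheme(benv, kern, specs, folds, chain,
                    traits = cv$traits %||% unique(benv$trait)[1])
  utils::write.table(acc, file.path(out_dir, "accuracy_cv1.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("hybridgp")),
    seed = seed,
    scenario = sc_args[setdiff(names(sc_args), "trait_config")],
    qc = fa$report[c("n_input", "n_removed_maf", "n_removed_missing",
                     "n_retained")],
    kernels = names(kern),
    models = vapply(specs, `[[`, "", "label"),
    chain = unclass(chain)[c("n_iter", "burn_in", "thin", "seed", "n_stored")],
    cv_env = env)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(scenario = scn, stage1 = s1, accuracy = acc,
                 manifest = manifest, out_dir = out_dir))
}
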