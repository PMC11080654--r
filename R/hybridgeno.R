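# Hybrid marker coding from inbred parents, marker QC and mean imputation.

match_parents <- function(panel, plan) {
  bad <- setdiff(unique(c(plan$parent1, plan$parent2)), panel$parent_ids)
  if (length(bad))
    stop("unknown parent id(s): ", paste(bad, collapse = ", "))
  if (any(plan$parent1 == plan$parent2))
    stop("crossing plan contains selfs (parent1 == parent2)")
  list(g1 = panel$genotypes[plan$parent1, , drop = FALSE],
       g2 = panel$genotypes[plan$parent2, , drop = FALSE])
}

#' Hybrid additive marker dosages
#'
#' The additive dosage of a hybrid at a locus is the mean of its two parents'
#' dosages on the 0-2 scale (the gamete-expectation coding for inbred
#' parents), so fully inbred parents give hybrid values in \{0, 1, 2\} and a
#' heterozygous parent contributes the intermediate values 0.5/1.5. Missing
#' wherever either parent is missing.
#'
#' @param panel a [simulate_parents()] panel (or compatible list)
#' @param plan a [make_cross_plan()] crossing plan
#' @return hybrids x markers matrix of additive dosages
#' @export
build_hybrid_additive <- function(panel, plan) {
  p <- match_parents(panel, plan)
  add <- (p$g1 + p$g2) / 2
  rownames(add) <- plan$hybrid_id
  add
}

#' Hybrid dominance indicators
#'
#' Codes the hybrid genotype as 0 for both homozygous classes, 1 for the
#' heterozygous class (opposite homozygous parents), and missing for the
#' intermediate additive values 0.5 and 1.5 that arise when exactly one
#' parent is heterozygous; missing parents propagate.
#'
#' @inheritParams build_hybrid_additive
#' @return hybrids x markers matrix with values in \{0, 1, NA\}
#' @export
build_hybrid_dominance <- function(panel, plan) {
  add <- build_hybrid_additive(panel, plan)
  dom <- matrix(NA_real_, nrow(add), ncol(add), dimnames = dimnames(add))
  dom[add == 0 | add == 2] <- 0
  dom[add == 1] <- 1
  dom
}

#' Paired hybrid additive and dominance genotype matrices
#'
#' @inheritParams build_hybrid_additive
#' @return object of class `hybrid_genotypes`: list with `hybrid_ids`,
#'   `additive`, `dominance`, `marker_ids`
#' @export
hybrid_genotypes <- function(panel, plan) {
  structure(list(
    hybrid_ids = plan$hybrid_id,
    additive = build_hybrid_additive(panel, plan),
    dominance = build_hybrid_dominance(panel, plan),
    marker_ids = panel$marker_ids
  ), class = "hybrid_genotypes")
}

#' @export
print.hybrid_genotypes <- function(x, ...) {
  cat(sprintf("hybrid_genotypes: %d hybrids x %d markers\n",
              length(x$hybrid_ids), length(x$marker_ids)))
  invisible(x)
}

#' Marker quality control
#'
#' Removes markers with minor allele frequency below `maf_min` or missing
#' fraction above `miss_max`. A marker failing both rules is counted once,
#' under the MAF rule (applied first). Retained markers keep their order.
#'
#' @param genotypes individuals x markers dosage matrix on the 0-2 scale,
#'   `NA` allowed
#' @param maf_min minimum minor allele frequency (markers with MAF strictly
#'   below are removed)
#' @param miss_max maximum missing fraction (markers strictly above are
#'   removed)
#' @return list with `genotypes` (filtered matrix) and `report`, a
#'   `marker_qc_report` with counts `n_input`, `n_removed_maf`,
#'   `n_removed_missing`, `n_retained` and per-marker `flags`
#' @export
filter_markers <- function(genotypes, maf_min = 0.01, miss_max = 0.30) {
  if (is.null(dim(genotypes)) || ncol(genotypes) == 0 || nrow(genotypes) == 0)
    stop("empty genotype matrix")
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0                     # all-missing marker: treated as MAF 0
  miss <- colMeans(is.na(genotypes))
  fail_maf <- maf < maf_min
  fail_miss <- !fail_maf & miss > miss_max  # attributed to the first rule once
  flags <- ifelse(fail_maf, "maf", ifelse(fail_miss, "missing", "ok"))
  names(flags) <- colnames(genotypes)
  keep <- flags == "ok"
  report <- structure(list(
    n_input = ncol(genotypes),
    n_removed_maf = sum(fail_maf),
    n_removed_missing = sum(fail_miss),
    n_retained = sum(keep),
    flags = flags,
    maf = maf,
    missing_fraction = miss
  ), class = "marker_qc_report")
  list(genotypes = genotypes[, keep, drop = FALSE], report = report)
}

#' @export
print.marker_qc_report <- function(x, ...) {
  cat(sprintf(
    "marker QC: %d input, %d removed (MAF), %d removed (missingness), %d retained\n",
    x$n_input, x$n_removed_maf, x$n_removed_missing, x$n_retained))
  invisible(x)
}

#' Marker-mean imputation
#'
#' Replaces each missing entry by the mean of that marker's non-missing
#' values; observed entries are unchanged.
#'
#' @param genotypes individuals x markers matrix with `NA` allowed
#' @return matrix without missing values
#' @export
impute_mean <- function(genotypes) {
  miss <- is.na(genotypes)
  if (!any(miss)) return(genotypes)
  mu <- colMeans(genotypes, na.rm = TRUE)
  if (any(is.nan(mu)))
    stop("marker(s) with all values missing cannot be mean-imputed")
  idx <- which(miss, arr.ind = TRUE)
  genotypes[idx] <- mu[idx[, 2]]
  genotypes
}
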