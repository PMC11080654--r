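# Relationship matrices and kernels: VanRaden additive, Vitezica dominance,
# averaged Gaussian (RKHS) kernels and Hadamard-product G x E kernels.

# "5" -> "5", "0.2" -> "02": compact bandwidth-multiplier labels (Ka5, Ka02, ...)
mult_label <- function(m)
  vapply(m, function(x) gsub("\\.", "",
                             format(x, trim = TRUE, drop0trailing = TRUE)), "")

#' VanRaden additive genomic relationship matrix
#'
#' `G_a = Z Z' / (2 * sum_j p_j (1 - p_j))` where `Z` centers each marker
#' column by twice its allele frequency. Frequencies default to those of the
#' matrix being kernelized; pass `p` to use e.g. parental frequencies.
#'
#' @param M complete individuals x markers additive dosage matrix (0-2 scale;
#'   impute first)
#' @param p optional allele frequencies per marker
#' @return n x n relationship matrix
#' @export
vanraden_additive <- function(M, p = NULL) {
  if (anyNA(M)) stop("M contains missing values; impute first")
  if (is.null(p)) p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: zero VanRaden denominator")
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  (G + t(G)) / 2
}

#' Vitezica dominance genomic relationship matrix
#'
#' `G_d = W W' / sum_j (2 p_j q_j)^2` with `W_ij = d_ij - 2 p_j q_j`, where
#' `d` is the 0/1 heterozygosity indicator matrix (mean-imputed) and `p` the
#' allele frequencies of the corresponding additive matrix.
#'
#' @param D complete hybrids x markers dominance indicator matrix
#' @param p allele frequencies per marker (from the paired additive matrix;
#'   defaults to frequencies implied by `D`'s column means via `d = 2pq`
#'   inversion being unavailable, so passing `p` explicitly is recommended)
#' @return n x n dominance relationship matrix
#' @export
vitezica_dominance <- function(D, p) {
  if (anyNA(D)) stop("D contains missing values; impute first")
  if (missing(p)) stop("allele frequencies `p` are required")
  if (length(p) != ncol(D)) stop("length(p) must equal ncol(D)")
  tpq <- 2 * p * (1 - p)
  denom <- sum(tpq^2)
  if (denom <= 0) stop("no heterozygosity possible at any marker: zero denominator")
  W <- sweep(D, 2, tpq)
  G <- tcrossprod(W) / denom
  (G + t(G)) / 2
}

#' Gaussian kernels with bandwidth averaging
#'
#' Computes the squared Euclidean distance matrix `D2` between rows of `M`,
#' sets `h` to the given percentile of the off-diagonal `D2` values, and
#' returns one kernel `exp(-(m/h) * D2)` per bandwidth multiplier, ordered
#' local to global. The three defaults (5/h, 1/h, 0.2/h) are the kernel set
#' fitted jointly under kernel averaging.
#'
#' @param M complete matrix (rows = individuals)
#' @param percentile percentile (in percent) of off-diagonal squared
#'   distances defining the bandwidth constant `h`
#' @param multipliers bandwidth multipliers `m`, kernels returned in this order
#' @return list with `kernels` (named list of matrices), `h`, `percentile`,
#'   `multipliers`
#' @export
gaussian_kernels <- function(M, percentile = 5, multipliers = c(5, 1, 0.2)) {
  if (anyNA(M)) stop("M contains missing values; impute first")
  if (nrow(M) < 2) stop("need at least two rows")
  sq <- rowSums(M^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(M)
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  off <- D2[lower.tri(D2)]
  h <- unname(stats::quantile(off, percentile / 100, type = 7))
  if (h <= 0) stop("bandwidth constant h is zero (too many identical rows)")
  kernels <- lapply(multipliers, function(m) {
    K <- exp(-(m / h) * D2)
    dimnames(K) <- list(rownames(M), rownames(M))
    (K + t(K)) / 2
  })
  names(kernels) <- paste0("phi", mult_label(multipliers))
  list(kernels = kernels, h = h, percentile = percentile,
       multipliers = multipliers)
}

#' Record-level genotype-by-environment interaction kernel
#'
#' Hadamard product of the same-environment indicator `Z_E Z_E'` and the
#' genotype kernel expanded to records, `Z_1 K Z_1'`: entry (r, s) equals
#' `K[g_r, g_s]` when records r and s share an environment and 0 otherwise.
#'
#' @param env_assign environment label per record
#' @param genotype_assign genotype label per record
#' @param K genotype kernel with dimnames covering all genotype labels
#' @return records x records interaction kernel
#' @export
gxe_kernel <- function(env_assign, genotype_assign, K) {
  if (length(env_assign) != length(genotype_assign))
    stop("env_assign and genotype_assign must have equal length")
  idx <- match(genotype_assign, rownames(K))
  if (anyNA(idx))
    stop("genotype label(s) absent from K: ",
         paste(unique(genotype_assign[is.na(idx)]), collapse = ", "))
  same_env <- outer(env_assign, env_assign, "==") * 1
  Kexp <- K[idx, idx, drop = FALSE]
  out <- same_env * Kexp
  dimnames(out) <- list(NULL, NULL)
  (out + t(out)) / 2
}

#' Positive-semidefiniteness check with optional bending
#'
#' Reports the extreme eigenvalues; if the minimum eigenvalue falls below
#' `-tol * max(eigenvalue)` the matrix is flagged and a bent copy is returned
#' in which negative eigenvalues are raised to a small positive floor
#' (`floor_frac` of the maximum eigenvalue).
#'
#' @param K square symmetric matrix
#' @param tol relative tolerance on the minimum eigenvalue
#' @param floor_frac floor for bent eigenvalues, relative to the maximum
#' @return list with `psd` (logical), `min_eigenvalue`, `max_eigenvalue`,
#'   `bent` (logical) and `matrix` (input, or the bent copy when flagged)
#' @export
check_psd <- function(K, tol = 1e-8, floor_frac = 1e-6) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) stop("K must be a square matrix")
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stop("K must be symmetric")
  ee <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- ee$values
  mx <- max(lam)
  psd <- min(lam) >= -tol * max(mx, .Machine$double.eps)
  if (psd)
    return(list(psd = TRUE, min_eigenvalue = min(lam), max_eigenvalue = mx,
                bent = FALSE, matrix = K))
  lam_b <- pmax(lam, floor_frac * mx)
  Kb <- ee$vectors %*% (lam_b * t(ee$vectors))
  dimnames(Kb) <- dimnames(K)
  list(psd = FALSE, min_eigenvalue = min(lam), max_eigenvalue = mx,
       bent = TRUE, matrix = (Kb + t(Kb)) / 2)
}

#' Build the full kernel set for a hybrid population
#'
#' From filtered, mean-imputed hybrid matrices, constructs the VanRaden
#' additive matrix `Ga`, the Vitezica dominance matrix `Gd`, and the averaged
#' Gaussian kernel triplets `Ka*` / `Kd*` over the additive and dominance
#' matrices. Each matrix is PSD-checked (and bent if needed).
#'
#' @param hybrids a [hybrid_genotypes()] object (missing values allowed; mean
#'   imputation is applied here)
#' @param percentile,multipliers passed to [gaussian_kernels()]
#' @return object of class `kernel_set`: named list of matrices with a
#'   `meta` attribute recording kind, bandwidths and bending flags
#' @export
build_kernel_set <- function(hybrids, percentile = 5, multipliers = c(5, 1, 0.2)) {
  stopifnot(inherits(hybrids, "hybrid_genotypes"))
  A <- impute_mean(hybrids$additive)
  D <- impute_mean(hybrids$dominance)
  p <- colMeans(A) / 2

  entries <- list()
  meta <- list()
  add_entry <- function(name, K, kind, extra = list()) {
    chk <- check_psd(K)
    entries[[name]] <<- chk$matrix
    meta[[name]] <<- c(list(kind = kind, bent = chk$bent,
                            min_eigenvalue = chk$min_eigenvalue), extra)
  }
  add_entry("Ga", vanraden_additive(A, p), "additive")
  add_entry("Gd", vitezica_dominance(D, p), "dominance")
  gka <- gaussian_kernels(A, percentile, multipliers)
  for (i in seq_along(gka$kernels))
    add_entry(paste0("Ka", mult_label(multipliers[i])),
              gka$kernels[[i]], "gaussian_additive",
              list(h = gka$h, multiplier = multipliers[i],
                   percentile = percentile))
  gkd <- gaussian_kernels(D, percentile, multipliers)
  for (i in seq_along(gkd$kernels))
    add_entry(paste0("Kd", mult_label(multipliers[i])),
              gkd$kernels[[i]], "gaussian_dominance",
              list(h = gkd$h, multiplier = multipliers[i],
                   percentile = percentile))
  structure(entries, meta = meta, class = "kernel_set")
}

#' @export
print.kernel_set <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("kernel_set: %d kernels (n = %d)\n", length(x), nrow(x[[1]])))
  for (nm in names(x))
    cat(sprintf("  %-6s %s%s\n", nm, meta[[nm]]$kind,
                if (isTRUE(meta[[nm]]$bent)) " [bent]" else ""))
  invisible(x)
}
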