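#' @keywords internal
"_PACKAGE"

## Seed streams: each module derives its own substream from a user seed so
## regenerating one component does not perturb the others.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(genotypes = 11L, crossplan = 23L, effects = 37L, noise = 53L,
               design = 71L, folds = 89L, chain = 101L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 127L + off * 9973L) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Symmetric matrix square root via eigendecomposition
#'
#' Eigenvalues below `tol * max(eigenvalue)` are truncated to zero, so the
#' result is defined for positive semidefinite inputs (e.g. a singular
#' correlation matrix of perfectly correlated environments).
#' @param S symmetric positive semidefinite matrix
#' @param tol relative eigenvalue truncation tolerance
#' @return matrix `R` with `R %*% t(R)` equal to `S` up to truncation
#' @keywords internal
sym_sqrt <- function(S, tol = 1e-10) {
  ee <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- ee$values
  if (min(lam) < -tol * max(abs(lam)))
    stop("matrix is not positive semidefinite")
  lam[lam < tol * max(abs(lam))] <- 0
  ee$vectors %*% diag(sqrt(lam), nrow = length(lam))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_proportion <- function(x, name, open = FALSE) {
  lo <- if (open) x > 0 else x >= 0
  hi <- if (open) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || !lo || !hi)
    stop(sprintf("`%s` must be a proportion in %s", name,
                 if (open) "(0,1)" else "[0,1]"), call. = FALSE)
  as.numeric(x)
}
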