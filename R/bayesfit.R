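# Stage 2: Bayesian whole-genome regression on stage-1 BLUEs.
#
# Every random term (additive, dominance, each Gaussian bandwidth kernel,
# each G x E interaction kernel) is sampled in the eigenbasis of its kernel:
# one eigendecomposition per kernel up front, diagonal full conditionals when
# each record maps to a distinct kernel row, dense ones otherwise. Variances
# carry scaled-inverse-chi-square priors (single trait) or inverse-Wishart
# priors (multi-trait); the intercept and environment effects are flat.

#' Model specification
#'
#' @param method `"GBLUP"` (marker relationship matrices) or `"RKHS"`
#'   (averaged Gaussian kernels)
#' @param effects `"A"` (additive only) or `"AD"` (additive plus dominance)
#' @param traits `"single"` or `"multi"`
#' @param gxe add environment main effects and Hadamard-product interaction
#'   kernels
#' @return object of class `model_spec` with a `label` field (`AG`, `ADG`,
#'   `MAG`, `MADG`, `AR`, `ADR`, `MAR`, `MADR`)
#' @export
model_spec <- function(method = c("GBLUP", "RKHS"), effects = c("A", "AD"),
                       traits = c("single", "multi"), gxe = FALSE) {
  method <- match.arg(method); effects <- match.arg(effects)
  traits <- match.arg(traits)
  label <- paste0(if (traits == "multi") "M" else "", effects,
                  if (method == "GBLUP") "G" else "R")
  structure(list(method = method, effects = effects, traits = traits,
                 gxe = gxe, label = label), class = "model_spec")
}

#' Parse a model label back into a specification
#'
#' @param label one of AG, ADG, MAG, MADG, AR, ADR, MAR, MADR
#' @param gxe interaction flag (not encoded in the label)
#' @return a [model_spec()]
#' @export
parse_model_label <- function(label, gxe = FALSE) {
  stopifnot(is.character(label), length(label) == 1)
  x <- label
  traits <- if (startsWith(x, "M")) "multi" else "single"
  if (traits == "multi") x <- substring(x, 2)
  method <- switch(substring(x, nchar(x)), G = "GBLUP", R = "RKHS",
                   stop("unrecognized label: ", label))
  effects <- substring(x, 1, nchar(x) - 1)
  if (!effects %in% c("A", "AD")) stop("unrecognized label: ", label)
  model_spec(method, effects, traits, gxe)
}

#' The eight model structures (optionally doubled by the interaction flag)
#'
#' Full factorial \{GBLUP, RKHS\} x \{A, AD\} x \{single, multi\} in label
#' order AG, ADG, MAG, MADG, AR, ADR, MAR, MADR.
#'
#' @param gxe when `TRUE`, appends the same eight structures with G x E
#'   interaction terms, doubling the grid to sixteen
#' @return list of [model_spec()] objects
#' @export
enumerate_model_grid <- function(gxe = FALSE) {
  base <- list()
  for (method in c("GBLUP", "RKHS"))
    for (traits in c("single", "multi"))
      for (effects in c("A", "AD"))
        base[[length(base) + 1]] <- model_spec(method, effects, traits)
  ord <- c("AG", "ADG", "MAG", "MADG", "AR", "ADR", "MAR", "MADR")
  base <- base[match(ord, vapply(base, `[[`, "", "label"))]
  if (!gxe) return(base)
  c(base, lapply(base, function(s)
    model_spec(s$method, s$effects, s$traits, gxe = TRUE)))
}

#' Gibbs-chain configuration
#'
#' @param n_iter total iterations
#' @param burn_in iterations discarded before storage
#' @param thin sampling interval
#' @param seed integer seed; fixed seeds reproduce stored samples exactly
#' @return object of class `chain_config`; `n_stored` is
#'   `floor((n_iter - burn_in) / thin)`
#' @export
chain_config <- function(n_iter = 30000, burn_in = 3000, thin = 10, seed = 1) {
  n_iter <- check_count(n_iter, "n_iter")
  burn_in <- check_count(burn_in, "burn_in", min = 0L)
  thin <- check_count(thin, "thin")
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  n_stored <- (n_iter - burn_in) %/% thin
  if (n_stored < 1) stop("chain configuration stores no samples")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = seed, n_stored = n_stored),
            class = "chain_config")
}

# Kernel names used by a spec, split by genetic component.
spec_kernel_names <- function(kernels, spec) {
  meta <- attr(kernels, "meta")
  kind_of <- vapply(meta, `[[`, "", "kind")
  a_kind <- if (spec$method == "GBLUP") "additive" else "gaussian_additive"
  d_kind <- if (spec$method == "GBLUP") "dominance" else "gaussian_dominance"
  a <- names(kind_of)[kind_of == a_kind]
  d <- if (spec$effects == "AD") names(kind_of)[kind_of == d_kind] else character()
  if (!length(a)) stop("kernel set lacks kernels of kind ", a_kind)
  if (spec$effects == "AD" && !length(d))
    stop("kernel set lacks kernels of kind ", d_kind)
  list(a = a, d = d)
}

eigen_trunc <- function(K, tol = 1e-10) {
  ee <- eigen((K + t(K)) / 2, symmetric = TRUE)
  keep <- ee$values > tol * max(ee$values)
  if (!any(keep)) stop("kernel has no positive eigenvalues")
  list(U = ee$vectors[, keep, drop = FALSE], lam = ee$values[keep])
}

rinvwishart <- function(df, S) {
  W <- stats::rWishart(1, df, chol2inv(chol(S)))[, , 1]
  chol2inv(chol(W))
}

#' Closed-form single-trait GBLUP with known variance ratio
#'
#' Solves the mixed-model equations for genetic values given the ratio
#' `sigma2_e / sigma2_a`: `g_hat = K (K + ratio I)^{-1} (y - mean(y))`.
#' Serves as the analytic oracle for the Gibbs sampler.
#'
#' @param y complete response vector
#' @param K PSD genetic covariance matrix, same order as `y`
#' @param ratio residual-to-genetic variance ratio
#' @return vector of predicted genetic values
#' @export
closed_form_gblup <- function(y, K, ratio) {
  stopifnot(length(y) == nrow(K), ratio >= 0)
  yc <- y - mean(y)
  g <- K %*% solve(K + diag(ratio, nrow(K)), yc)
  stats::setNames(drop(g), rownames(K))
}

#' Fit a prediction model by Gibbs sampling
#'
#' Fits the model structure in `spec` to stage-1 BLUEs. Responses may contain
#' `NA` (unphenotyped hybrids, missing trait cells); they are imputed by data
#' augmentation each sweep, which is how predictions for untested hybrids are
#' produced. RKHS specs attach one random effect per bandwidth kernel, each
#' with its own variance (kernel averaging). G x E specs take a record-level
#' response (one row per environment x hybrid) with environment as a flat-
#' prior fixed effect and Hadamard-product interaction kernels.
#'
#' @param y response: named vector (single trait), or hybrids x traits matrix
#'   (multi-trait), or records x traits matrix with `env` and `hybrid` given
#'   (G x E). Row names (or `hybrid`) must index the kernels.
#' @param kernels a [build_kernel_set()] kernel set
#' @param spec a [model_spec()]
#' @param chain a [chain_config()]
#' @param env environment label per record (G x E specs only)
#' @param hybrid hybrid id per record; defaults to `rownames(y)`
#' @param all_hybrids optional superset of hybrid ids to model (hybrids
#'   without records receive genetic values through the kernel alone, e.g.
#'   untested hybrids in CV00)
#' @param fixed_variances optional named numeric fixing variances (names are
#'   term names, e.g. `"Ga"`, plus `"residual"`); single-trait only
#' @return object of class `posterior_fit`: posterior means/sds of the
#'   intercept, environment effects and each genetic term, stored variance
#'   draws, and chain bookkeeping
#' @export
fit_gibbs <- function(y, kernels, spec, chain = chain_config(),
                      env = NULL, hybrid = NULL, all_hybrids = NULL,
                      fixed_variances = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(chain, "chain_config"))
  if (is.vector(y)) y <- matrix(y, ncol = 1,
                                dimnames = list(names(y), "trait1"))
  n <- nrow(y); t <- ncol(y)
  if (is.null(colnames(y))) colnames(y) <- paste0("trait", seq_len(t))
  if (spec$traits == "single" && t != 1)
    stop("single-trait spec given a multi-column response")
  if (spec$traits == "multi" && t < 2)
    stop("multi-trait spec needs at least two response columns")
  hybrid <- hybrid %||% rownames(y)
  if (is.null(hybrid)) stop("response rows must be named by hybrid id")
  if (spec$gxe) {
    if (is.null(env)) stop("G x E spec requires `env` per record")
    if (length(env) != n) stop("`env` must have one label per record")
  } else if (!is.null(env) && length(unique(env)) > 1) {
    stop("multi-environment records require a G x E spec")
  }
  if (!is.null(fixed_variances) && t > 1)
    stop("fixed_variances is supported for single-trait fits only")

  kn <- spec_kernel_names(kernels, spec)
  hyb_levels <- union(unique(hybrid), all_hybrids)
  bad <- setdiff(hyb_levels, rownames(kernels[[kn$a[1]]]))
  if (length(bad))
    stop("hybrid(s) missing from kernels: ", paste(utils::head(bad, 5), collapse = ", "))

  # --- terms ------------------------------------------------------------
  map <- match(hybrid, hyb_levels)
  make_term <- function(name, K, component, record_level = FALSE) {
    ed <- eigen_trunc(K)
    m <- length(ed$lam)
    tmap <- if (record_level) seq_len(n) else map
    Zu <- ed$U[tmap, , drop = FALSE]
    A <- crossprod(Zu)
    identity <- max(abs(A - diag(m))) < 1e-8
    list(name = name, component = component, U = ed$U, lam = ed$lam,
         m = m, map = tmap, Zu = Zu, A = if (identity) NULL else A,
         identity = identity,
         level = if (record_level) "record" else "hybrid",
         ids = if (record_level) paste(env, hybrid, sep = ":") else hyb_levels)
  }
  terms <- list()
  for (nm in kn$a)
    terms[[nm]] <- make_term(nm, kernels[[nm]][hyb_levels, hyb_levels], "a")
  for (nm in kn$d)
    terms[[nm]] <- make_term(nm, kernels[[nm]][hyb_levels, hyb_levels], "d")
  if (spec$gxe) {
    for (nm in kn$a)
      terms[[paste0(nm, "xE")]] <- make_term(
        paste0(nm, "xE"),
        gxe_kernel(env, hybrid, kernels[[nm]]), "gxe_a", record_level = TRUE)
    for (nm in kn$d)
      terms[[paste0(nm, "xE")]] <- make_term(
        paste0(nm, "xE"),
        gxe_kernel(env, hybrid, kernels[[nm]]), "gxe_d", record_level = TRUE)
  }
  n_terms <- length(terms)

  # --- fixed effects ----------------------------------------------------
  X <- matrix(1, n, 1, dimnames = list(NULL, "mu"))
  if (spec$gxe && length(unique(env)) > 1) {
    envf <- factor(env)
    X <- cbind(X, stats::model.matrix(~envf)[, -1, drop = FALSE])
  }
  p <- ncol(X)
  XtXi <- chol2inv(chol(crossprod(X)))
  Lx <- t(chol(XtXi))                      # lower factor of (X'X)^-1

  # --- priors -----------------------------------------------------------
  obs <- !is.na(y)
  if (any(colSums(obs) < 3)) stop("each trait needs at least 3 observations")
  vy <- vapply(seq_len(t), function(k) stats::var(y[obs[, k], k]), 0)
  vy[vy <= 0] <- 1e-8
  nu <- 5
  mode_g <- 0.5 * vy / n_terms
  S_g <- mode_g * (nu + 2) / nu            # per-trait genetic prior scales
  S_e <- 0.5 * vy * (nu + 2) / nu
  nu0 <- t + 4                             # multi-trait inverse-Wishart df
  S0_g <- diag(mode_g, t) * (nu0 + t + 1)
  S0_e <- diag(0.5 * vy, t) * (nu0 + t + 1)

  # --- state ------------------------------------------------------------
  Yc <- y
  for (k in seq_len(t)) Yc[!obs[, k], k] <- mean(y[obs[, k], k])
  B <- matrix(0, p, t); B[1, ] <- colMeans(Yc)
  gamma <- lapply(terms, function(tr) matrix(0, tr$m, t))
  u_rec <- lapply(terms, function(tr) matrix(0, n, t))
  sig_k <- lapply(terms, function(tr) diag(mode_g, t))
  Sig_e <- diag(0.5 * vy, t)
  fixed_term <- rep(FALSE, n_terms); names(fixed_term) <- names(terms)
  fixed_resid <- FALSE
  if (!is.null(fixed_variances)) {
    for (nm in names(fixed_variances)) {
      if (nm == "residual") {
        Sig_e <- matrix(fixed_variances[[nm]], 1, 1); fixed_resid <- TRUE
      } else if (nm %in% names(terms)) {
        sig_k[[nm]] <- matrix(fixed_variances[[nm]], 1, 1)
        fixed_term[nm] <- TRUE
      } else stop("fixed_variances names unknown term: ", nm)
    }
  }

  # missingness pattern groups (multi-trait augmentation)
  mis_groups <- NULL
  if (any(!obs)) {
    pat <- apply(obs, 1, paste, collapse = "")
    mis_groups <- split(seq_len(n), pat)
    mis_groups <- mis_groups[vapply(mis_groups, function(i) any(!obs[i[1], ]), TRUE)]
  }

  n_stored <- chain$n_stored
  var_draws <- matrix(NA_real_, n_stored, n_terms + 1,
                      dimnames = list(NULL, c(names(terms), "residual")))
  cov_draws <- if (t > 1)
    lapply(stats::setNames(nm = c(names(terms), "residual")),
           function(nm) array(NA_real_, c(t, t, n_stored))) else NULL
  B_draws <- array(NA_real_, c(p, t, n_stored))
  eff_sum <- lapply(terms, function(tr) matrix(0, nrow(tr$U), t))
  eff_ssq <- lapply(terms, function(tr) matrix(0, nrow(tr$U), t))

  with_seed(substream_seed(chain$seed, "chain"), {
    Sig_e_inv <- chol2inv(chol(Sig_e))
    for (iter in seq_len(chain$n_iter)) {
      fitted <- X %*% B + Reduce(`+`, u_rec)

      ## 1. data augmentation of missing responses
      if (t == 1) {
        mis <- !obs[, 1]
        if (any(mis))
          Yc[mis, 1] <- fitted[mis, 1] +
            stats::rnorm(sum(mis), 0, sqrt(Sig_e[1, 1]))
      } else if (!is.null(mis_groups)) {
        Le <- t(chol(Sig_e))
        for (idx in mis_groups) {
          o <- obs[idx[1], ]; m_ <- !o
          if (!any(o)) {
            Z <- matrix(stats::rnorm(length(idx) * t), ncol = t)
            Yc[idx, ] <- fitted[idx, , drop = FALSE] + Z %*% t(Le)
          } else {
            Soo <- Sig_e[o, o, drop = FALSE]
            Smo <- Sig_e[m_, o, drop = FALSE]
            Smm <- Sig_e[m_, m_, drop = FALSE]
            W <- Smo %*% chol2inv(chol(Soo))
            Cm <- Smm - W %*% t(Smo)
            Lc <- t(chol((Cm + t(Cm)) / 2))
            dev <- Yc[idx, o, drop = FALSE] - fitted[idx, o, drop = FALSE]
            mu_m <- fitted[idx, m_, drop = FALSE] + dev %*% t(W)
            Z <- matrix(stats::rnorm(length(idx) * sum(m_)), ncol = sum(m_))
            Yc[idx, m_] <- mu_m + Z %*% t(Lc)
          }
        }
      }

      ## 2. fixed effects (flat prior)
      Rx <- Yc - Reduce(`+`, u_rec)
      Bhat <- XtXi %*% crossprod(X, Rx)
      if (t == 1) {
        B <- Bhat + Lx %*% stats::rnorm(p) * sqrt(Sig_e[1, 1])
      } else {
        Z <- matrix(stats::rnorm(p * t), p, t)
        B <- Bhat + Lx %*% Z %*% chol(Sig_e)
      }
      XB <- X %*% B
      Resid <- Yc - XB - Reduce(`+`, u_rec)

      ## 3. genetic terms
      for (k in seq_len(n_terms)) {
        tr <- terms[[k]]
        r_k <- Resid + u_rec[[k]]
        Ck <- crossprod(tr$Zu, r_k)               # m x t
        if (t == 1) {
          s2k <- sig_k[[k]][1, 1]; s2e <- Sig_e[1, 1]
          if (tr$identity) {
            prec <- 1 / s2e + 1 / (s2k * tr$lam)
            mu <- (Ck[, 1] / s2e) / prec
            g <- mu + stats::rnorm(tr$m) / sqrt(prec)
          } else {
            P <- tr$A / s2e + diag(1 / (s2k * tr$lam), tr$m)
            ch <- chol(P)
            mu <- backsolve(ch, forwardsolve(t(ch), Ck[, 1] / s2e))
            g <- mu + backsolve(ch, stats::rnorm(tr$m))
          }
          gamma[[k]] <- matrix(g, ncol = 1)
        } else {
          Sk_inv <- chol2inv(chol(sig_k[[k]]))
          G <- matrix(0, tr$m, t)
          if (tr$identity) {
            CE <- Ck %*% Sig_e_inv
            for (j in seq_len(tr$m)) {
              P <- Sig_e_inv + Sk_inv / tr$lam[j]
              ch <- chol(P)
              mu <- backsolve(ch, forwardsolve(t(ch), CE[j, ]))
              G[j, ] <- mu + backsolve(ch, stats::rnorm(t))
            }
          } else {
            P <- kronecker(tr$A, Sig_e_inv) +
              kronecker(diag(1 / tr$lam, tr$m), Sk_inv)
            b <- as.vector(t(Ck %*% Sig_e_inv))
            ch <- chol((P + t(P)) / 2)
            mu <- backsolve(ch, forwardsolve(t(ch), b))
            v <- mu + backsolve(ch, stats::rnorm(tr$m * t))
            G <- matrix(v, tr$m, t, byrow = TRUE)
          }
          gamma[[k]] <- G
        }
        u_new <- tr$Zu %*% gamma[[k]]
        Resid <- Resid + u_rec[[k]] - u_new
        u_rec[[k]] <- u_new

        ## variance of term k
        if (t == 1) {
          if (!fixed_term[k]) {
            SS <- sum(gamma[[k]][, 1]^2 / tr$lam)
            sig_k[[k]][1, 1] <- (nu * S_g[1] + SS) /
              stats::rchisq(1, nu + tr$m)
          }
        } else {
          Sg <- crossprod(gamma[[k]] / sqrt(tr$lam))
          sig_k[[k]] <- rinvwishart(nu0 + tr$m, S0_g + Sg)
        }
      }

      ## 4. residual (co)variance
      if (t == 1) {
        if (!fixed_resid)
          Sig_e[1, 1] <- (nu * S_e[1] + sum(Resid^2)) /
            stats::rchisq(1, nu + n)
      } else {
        Sig_e <- rinvwishart(nu0 + n, S0_e + crossprod(Resid))
        Sig_e_inv <- chol2inv(chol(Sig_e))
      }

      ## 5. storage
      if (iter > chain$burn_in && (iter - chain$burn_in) %% chain$thin == 0) {
        s <- (iter - chain$burn_in) %/% chain$thin
        for (k in seq_len(n_terms)) {
          var_draws[s, k] <- sig_k[[k]][1, 1]
          if (t > 1) cov_draws[[k]][, , s] <- sig_k[[k]]
          u_lvl <- terms[[k]]$U %*% gamma[[k]]
          eff_sum[[k]] <- eff_sum[[k]] + u_lvl
          eff_ssq[[k]] <- eff_ssq[[k]] + u_lvl^2
        }
        var_draws[s, n_terms + 1] <- Sig_e[1, 1]
        if (t > 1) cov_draws[["residual"]][, , s] <- Sig_e
        B_draws[, , s] <- B
      }
    }
  })

  effects <- lapply(seq_len(n_terms), function(k) {
    mu <- eff_sum[[k]] / n_stored
    v <- eff_ssq[[k]] / n_stored - mu^2
    v[v < 0] <- 0
    sdv <- sqrt(v)
    rownames(mu) <- rownames(sdv) <- terms[[k]]$ids
    colnames(mu) <- colnames(sdv) <- colnames(y)
    list(name = terms[[k]]$name, component = terms[[k]]$component,
         level = terms[[k]]$level, mean = mu, sd = sdv)
  })
  names(effects) <- names(terms)

  structure(list(
    spec = spec, chain = chain, n_stored = n_stored,
    traits = colnames(y), hybrids = hyb_levels,
    env_levels = if (spec$gxe) unique(env) else NULL,
    intercept = apply(B_draws, c(1, 2), mean),
    fixed_names = colnames(X),
    effects = effects,
    var_draws = var_draws,
    cov_draws = cov_draws,
    var_post_mean = colMeans(var_draws)
  ), class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("posterior_fit [%s%s]: %d stored samples, %d hybrids, %d trait(s)\n",
              x$spec$label, if (x$spec$gxe) " + GxE" else "",
              x$n_stored, length(x$hybrids), length(x$traits)))
  cat("  posterior mean variances:\n")
  print(round(x$var_post_mean, 4))
  invisible(x)
}

#' Extract predicted genetic values from a posterior fit
#'
#' Sums the posterior means of the requested genetic components. The default
#' mirrors prediction into new environments (CV0/CV00): additive values for A
#' specs, additive plus dominance for AD specs, interaction terms excluded.
#'
#' @param fit a [fit_gibbs()] posterior fit
#' @param targets hybrid ids to return (default: all hybrids in the fit)
#' @param include components to sum, subset of `"a"`, `"d"`, `"gxe_a"`,
#'   `"gxe_d"`; `"gxe_*"` components are record-level and only available for
#'   G x E fits
#' @return hybrids x traits matrix of predicted genetic values (hybrid-level
#'   components only; interaction components are returned separately as a
#'   `"records"` attribute when requested)
#' @export
predict_genetic_values <- function(fit, targets = NULL, include = NULL) {
  stopifnot(inherits(fit, "posterior_fit"))
  if (is.null(include))
    include <- if (fit$spec$effects == "AD") c("a", "d") else "a"
  comp <- vapply(fit$effects, `[[`, "", "component")
  missing_comp <- setdiff(include, comp)
  if (length(missing_comp))
    stop("component(s) absent from this fit: ",
         paste(missing_comp, collapse = ", "))
  targets <- targets %||% fit$hybrids
  bad <- setdiff(targets, fit$hybrids)
  if (length(bad)) stop("target hybrid(s) not covered by the fit: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  pred <- matrix(0, length(targets), length(fit$traits),
                 dimnames = list(targets, fit$traits))
  rec_pred <- NULL
  for (k in seq_along(fit$effects)) {
    ef <- fit$effects[[k]]
    if (!ef$component %in% include) next
    if (ef$level == "hybrid") {
      pred <- pred + ef$mean[targets, , drop = FALSE]
    } else {
      rec_pred <- if (is.null(rec_pred)) ef$mean else rec_pred + ef$mean
    }
  }
  if (!is.null(rec_pred)) attr(pred, "records") <- rec_pred
  pred
}
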