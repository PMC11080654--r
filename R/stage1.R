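# Stage 1: per-environment, per-trait linear mixed models.
#
# RCBD environments:      value ~ rep (fixed) + genotype (random)
# Augmented environments: value ~ rep + is_check (fixed) + block (random)
#                           + genotype (random)
# BLUEs come from the same model with genotype as a fixed effect (sum-to-zero
# replicate contrasts, so genotype coefficients are adjusted means).

stage1_prepare <- function(table) {
  needed <- c("env", "hybrid_id", "rep", "trait", "value")
  if (!all(needed %in% names(table)))
    stop("phenotype table must have columns: ", paste(needed, collapse = ", "))
  if (length(unique(table$env)) != 1)
    stop("fit one environment at a time")
  if (length(unique(table$trait)) != 1)
    stop("fit one trait at a time")
  dup <- duplicated(table[, c("hybrid_id", "rep", "block", "trait")[
    c("hybrid_id", "rep", "block", "trait") %in% names(table)]])
  if (any(dup)) stop("duplicated (hybrid, rep, block) records")
  d <- table[!is.na(table$value), , drop = FALSE]
  d$hybrid_f <- factor(d$hybrid_id)
  d$rep_f <- factor(d$rep)
  augmented <- "block" %in% names(d) && any(!is.na(d$block))
  if (augmented) {
    if (anyNA(d$block)) stop("block must be present for every augmented record")
    d$block_f <- factor(d$block)
  }
  if (!"is_check" %in% names(d)) d$is_check <- FALSE
  if (nlevels(d$hybrid_f) < 2) stop("need at least 2 genotypes with data")
  list(data = d, augmented = augmented)
}

stage1_fixed_formula <- function(d, augmented, genotype_fixed = FALSE) {
  terms <- character()
  if (genotype_fixed) terms <- c("0", "hybrid_f")
  if (nlevels(d$rep_f) > 1) terms <- c(terms, "rep_f")
  if (augmented && !genotype_fixed && length(unique(d$is_check)) > 1)
    terms <- c(terms, "is_check")
  if (!length(terms)) terms <- "1"
  stats::as.formula(paste("value ~", paste(terms, collapse = " + ")))
}

#' Per-environment, per-trait mixed-model fit
#'
#' Fits the stage-1 model for one environment and one trait by REML:
#' genotypes random (variance components, BLUPs, heritability) or fixed
#' (BLUEs, i.e. adjusted genotype means carried to stage 2). RCBD
#' environments model replicate as fixed; augmented environments additionally
#' model a check indicator as fixed and blocks as random.
#'
#' @param table phenotype table restricted to one env and one trait
#' @param genotype_as `"random"` (BLUPs + variance components) or `"fixed"`
#'   (BLUEs)
#' @param drop_random optionally drop one random term (`"genotype"` or
#'   `"block"`) to form the reduced model of a likelihood-ratio test
#' @return object of class `stage1_fit` with variance components, restricted
#'   log-likelihood (evaluated by [reml_loglik()] at the estimates), BLUPs or
#'   BLUEs, entry-mean heritability and the replicate summary
#' @export
fit_env_model <- function(table, genotype_as = c("random", "fixed"),
                          drop_random = NULL) {
  genotype_as <- match.arg(genotype_as)
  prep <- stage1_prepare(table)
  d <- prep$data
  augmented <- prep$augmented
  rand_terms <- c(
    if (genotype_as == "random" && !identical(drop_random, "genotype")) "hybrid_f",
    if (augmented && !identical(drop_random, "block")) "block_f")

  rep_counts <- table(d$hybrid_id)
  r_bar <- length(rep_counts) / sum(1 / rep_counts)   # harmonic mean
  vy <- stats::var(d$value)

  vc <- c(genotype = 0, block = 0, residual = 0)
  blup <- stats::setNames(rep(0, nlevels(d$hybrid_f)), levels(d$hybrid_f))
  blue <- NULL

  if (genotype_as == "fixed") {
    ff <- stage1_fixed_formula(d, augmented, genotype_fixed = TRUE)
    contr <- list()
    if (nlevels(d$rep_f) > 1) contr$rep_f <- stats::contr.sum
    if (augmented && nlevels(d$block_f) > 1) {
      fit <- lme4::lmer(stats::update(ff, . ~ . + (1 | block_f)), data = d,
                        REML = TRUE, contrasts = contr,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore", calc.derivs = FALSE))
      cf <- lme4::fixef(fit)
      vcd <- as.data.frame(lme4::VarCorr(fit))
      vc["block"] <- vcd$vcov[vcd$grp == "block_f"]
      vc["residual"] <- stats::sigma(fit)^2
    } else {
      fit <- stats::lm(ff, data = d, contrasts = contr)
      cf <- stats::coef(fit)
      vc["residual"] <- stats::sigma(fit)^2
    }
    bcoef <- cf[grep("^hybrid_f", names(cf))]
    names(bcoef) <- sub("^hybrid_f", "", names(bcoef))
    blue <- bcoef[levels(d$hybrid_f)]
    names(blue) <- levels(d$hybrid_f)
  } else if (vy < 1e-30) {
    # degenerate no-variation data: all components zero, BLUPs zero
  } else {
    ff <- stage1_fixed_formula(d, augmented)
    if (length(rand_terms)) {
      rf <- paste(sprintf("(1 | %s)", rand_terms), collapse = " + ")
      form <- stats::as.formula(paste(deparse(ff), "+", rf))
      fit <- lme4::lmer(form, data = d, REML = TRUE,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore", calc.derivs = FALSE))
      vcd <- as.data.frame(lme4::VarCorr(fit))
      if ("hybrid_f" %in% vcd$grp)
        vc["genotype"] <- vcd$vcov[vcd$grp == "hybrid_f"]
      if ("block_f" %in% vcd$grp)
        vc["block"] <- vcd$vcov[vcd$grp == "block_f"]
      vc["residual"] <- stats::sigma(fit)^2
      if ("hybrid_f" %in% rand_terms) {
        re <- lme4::ranef(fit)$hybrid_f
        blup <- stats::setNames(re[[1]], rownames(re))[levels(d$hybrid_f)]
        names(blup) <- levels(d$hybrid_f)
      }
    } else {
      fit <- stats::lm(ff, data = d)
      vc["residual"] <- stats::sigma(fit)^2
    }
  }

  ll <- reml_loglik(table,
                    sigma_g = if (genotype_as == "random" &&
                                  !identical(drop_random, "genotype"))
                      vc["genotype"] else 0,
                    sigma_p = if (augmented && !identical(drop_random, "block"))
                      vc["block"] else 0,
                    sigma_e = max(vc["residual"], 1e-12),
                    genotype_random = genotype_as == "random" &&
                      !identical(drop_random, "genotype"))

  h2 <- if (genotype_as == "random" && sum(vc[c("genotype", "residual")]) > 0)
    vc[["genotype"]] / (vc[["genotype"]] + vc[["residual"]] / r_bar) else NA_real_

  structure(list(
    env = unique(table$env), trait = unique(table$trait),
    design = if (augmented) "augmented" else "rcbd",
    genotype_as = genotype_as, drop_random = drop_random,
    varcomp = vc, loglik = ll, blup = blup, blue = blue,
    h2 = h2, r_bar = r_bar, n_geno = nlevels(d$hybrid_f),
    n_obs = nrow(d),
    fingerprint = c(n = nrow(d), sum = sum(d$value), ss = sum(d$value^2))
  ), class = "stage1_fit")
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat(sprintf("stage1_fit [%s / %s, %s, genotype %s]\n",
              x$env, x$trait, x$design, x$genotype_as))
  cat(sprintf("  sigma2_g = %.4g, sigma2_p = %.4g, sigma2_e = %.4g\n",
              x$varcomp["genotype"], x$varcomp["block"], x$varcomp["residual"]))
  if (!is.na(x$h2)) cat(sprintf("  h2 (entry-mean) = %.3f\n", x$h2))
  invisible(x)
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the REML log-likelihood of the stage-1 model for one environment
#' and trait at supplied variance components, using the same fixed-effect
#' design as [fit_env_model()]. The REML estimates returned by
#' [fit_env_model()] maximize this surface.
#'
#' @param table phenotype table restricted to one env and trait
#' @param sigma_g,sigma_p,sigma_e genotype, block and residual variances
#'   (`sigma_p` ignored for RCBD data)
#' @param genotype_random include the genotype variance term (set `FALSE` to
#'   evaluate the reduced model of an LRT)
#' @return restricted log-likelihood (scalar)
#' @export
reml_loglik <- function(table, sigma_g, sigma_e, sigma_p = 0,
                        genotype_random = TRUE) {
  if (sigma_e <= 0) stop("sigma_e must be positive")
  prep <- stage1_prepare(table)
  d <- prep$data
  if (!genotype_random && nlevels(d$hybrid_f) < 2)
    stop("degenerate table: fewer than 2 genotypes")
  n <- nrow(d)
  X <- stats::model.matrix(stage1_fixed_formula(d, prep$augmented), d)
  qrX <- qr(X)
  X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  V <- diag(sigma_e, n)
  if (genotype_random && sigma_g > 0) {
    Zg <- stats::model.matrix(~ 0 + hybrid_f, d)
    V <- V + sigma_g * tcrossprod(Zg)
  }
  if (prep$augmented && sigma_p > 0) {
    Zp <- stats::model.matrix(~ 0 + block_f, d)
    V <- V + sigma_p * tcrossprod(Zp)
  }
  ch <- chol(V)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), d$value))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  XtViy <- crossprod(X, Vi_y)
  beta <- solve(XtViX, XtViy)
  yPy <- sum(d$value * Vi_y) - sum(XtViy * beta)
  p <- ncol(X)
  -0.5 * (logdetV + determinant(XtViX, logarithm = TRUE)$modulus[1] +
            yPy + (n - p) * log(2 * pi))
}

#' Likelihood-ratio test for a random effect
#'
#' Twice the difference in restricted log-likelihood between a full fit and a
#' reduced fit with one random term dropped, referred to a chi-square with
#' one degree of freedom. Because the null places the variance on the
#' boundary, the 50:50 mixture p-value (half the chi-square(1) tail) is also
#' reported.
#'
#' @param full,reduced [fit_env_model()] fits of the same data, the reduced
#'   one with one random term dropped
#' @param alpha significance level for the flag
#' @return list with `statistic`, `p_value` (plain chi-square(1)),
#'   `p_value_mixture`, and `significant`
#' @export
lrt_random_effect <- function(full, reduced, alpha = 0.05) {
  stopifnot(inherits(full, "stage1_fit"), inherits(reduced, "stage1_fit"))
  if (max(abs(full$fingerprint - reduced$fingerprint)) > 1e-8)
    stop("full and reduced fits are not on the same data")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p, p_value_mixture = p / 2,
       significant = p < alpha)
}

#' Heritability from a stage-1 fit
#'
#' Entry-mean heritability `h2 = sigma2_g / (sigma2_g + sigma2_e / r_bar)`
#' with `r_bar` the harmonic-mean replicate count, or plot-level
#' `sigma2_g / (sigma2_g + sigma2_e)`.
#'
#' @param fit a random-genotype [fit_env_model()] fit
#' @param type `"entry_mean"` or `"plot"`
#' @return heritability in `[0, 1]`
#' @export
heritability <- function(fit, type = c("entry_mean", "plot")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "stage1_fit"))
  if (fit$genotype_as != "random")
    stop("heritability requires a random-genotype fit")
  vg <- fit$varcomp[["genotype"]]
  ve <- fit$varcomp[["residual"]]
  div <- if (type == "entry_mean") fit$r_bar else 1
  if (vg + ve / div <= 0) {
    if (vg == 0) return(0)
    stop("zero total variance")
  }
  vg / (vg + ve / div)
}

#' BLUP correlations between traits within an environment
#'
#' Pearson correlations between paired per-hybrid BLUP vectors for every
#' trait pair, with two-sided t-test significance flags.
#'
#' @param fits list of random-genotype [fit_env_model()] fits for different
#'   traits of the same environment
#' @param alpha significance level
#' @return data.frame with `trait1`, `trait2`, `r`, `n`, `p_value`,
#'   `significant`
#' @export
blup_correlations <- function(fits, alpha = 0.10) {
  stopifnot(length(fits) >= 2)
  traits <- vapply(fits, function(f) f$trait, "")
  out <- list()
  for (i in seq_len(length(fits) - 1)) for (j in seq(i + 1, length(fits))) {
    shared <- intersect(names(fits[[i]]$blup), names(fits[[j]]$blup))
    if (length(shared) < 3)
      stop("fewer than 3 shared hybrids between ", traits[i], " and ", traits[j])
    x <- fits[[i]]$blup[shared]; y <- fits[[j]]$blup[shared]
    ct <- stats::cor.test(x, y, alternative = "two.sided")
    out[[length(out) + 1]] <- data.frame(
      trait1 = traits[i], trait2 = traits[j],
      r = unname(ct$estimate), n = length(shared),
      p_value = ct$p.value, significant = ct$p.value < alpha,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Stage-1 analysis over all environments and traits
#'
#' Runs [fit_env_model()] with genotypes random (components, BLUPs, h2) and
#' fixed (BLUEs) for every environment x trait cell present in the table.
#'
#' @param pheno long-format phenotype table
#' @param traits optional subset of traits
#' @param envs optional subset of environments
#' @return list with `summary` (env, trait, variance components, h2, loglik),
#'   `blues` (long data.frame env, hybrid_id, trait, value), `blups`
#'   (same shape), and `fits` (nested list env -> trait -> fit)
#' @export
stage1_all <- function(pheno, traits = NULL, envs = NULL) {
  envs <- envs %||% unique(pheno$env)
  summ <- list(); blues <- list(); blups <- list(); fits <- list()
  for (e in envs) {
    de <- pheno[pheno$env == e, , drop = FALSE]
    trs <- intersect(traits %||% unique(de$trait), unique(de$trait))
    fits[[e]] <- list()
    for (tr in trs) {
      dt <- de[de$trait == tr, , drop = FALSE]
      fr <- fit_env_model(dt, "random")
      fb <- fit_env_model(dt, "fixed")
      fits[[e]][[tr]] <- list(random = fr, fixed = fb)
      summ[[length(summ) + 1]] <- data.frame(
        env = e, trait = tr, design = fr$design,
        sigma2_g = fr$varcomp[["genotype"]],
        sigma2_p = fr$varcomp[["block"]],
        sigma2_e = fr$varcomp[["residual"]],
        h2 = fr$h2, loglik = fr$loglik, n_geno = fr$n_geno,
        stringsAsFactors = FALSE)
      blues[[length(blues) + 1]] <- data.frame(
        env = e, hybrid_id = names(fb$blue), trait = tr,
        value = unname(fb$blue), stringsAsFactors = FALSE)
      blups[[length(blups) + 1]] <- data.frame(
        env = e, hybrid_id = names(fr$blup), trait = tr,
        value = unname(fr$blup), stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, summ), blues = do.call(rbind, blues),
       blups = do.call(rbind, blups), fits = fits)
}
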