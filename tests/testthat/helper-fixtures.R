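# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small single-site scenario: 80 hybrids, 3 traits, 2 envs (year 1 augmented,
# year 2 rcbd), used across kernel / bayesfit / crossval tests
small_scenario <- function() {
  fixture("small_scenario", function() {
    simulate_scenario(n_parents = 24, n_markers = 400, n_hybrids = 80,
                      trait_config = default_trait_config(3), n_sites = 1,
                      seed = 101)
  })
}

small_kernels <- function() {
  fixture("small_kernels", function() build_kernel_set(small_scenario()$hybrids))
}

# hand-built parent panel for coding-rule tests
toy_panel <- function(genotypes, group = NULL) {
  n <- nrow(genotypes)
  ids <- rownames(genotypes) %||% sprintf("P%02d", seq_len(n))
  rownames(genotypes) <- ids
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- sprintf("M%03d", seq_len(ncol(genotypes)))
  structure(list(
    parent_ids = ids,
    group = stats::setNames(group %||% rep("G1", n), ids),
    genotypes = genotypes,
    marker_ids = colnames(genotypes),
    allele_freq = colMeans(genotypes, na.rm = TRUE) / 2
  ), class = "parent_panel")
}

toy_plan <- function(parent1, parent2) {
  plan <- data.frame(hybrid_id = sprintf("H%02d", seq_along(parent1)),
                     parent1 = parent1, parent2 = parent2,
                     stringsAsFactors = FALSE)
  class(plan) <- c("cross_plan", "data.frame")
  plan
}

# balanced RCBD phenotype data with known variance components
sim_rcbd <- function(n_geno, n_reps, sigma_g = 1, sigma_e = 1, seed = 1,
                     env = "E1", trait = "T1") {
  set.seed(seed)
  g <- rnorm(n_geno, 0, sqrt(sigma_g))
  d <- expand.grid(hybrid_id = sprintf("H%03d", seq_len(n_geno)),
                   rep = seq_len(n_reps), stringsAsFactors = FALSE)
  d$env <- env
  d$trait <- trait
  r_eff <- rnorm(n_reps, 0, 0.3)
  d$value <- g[match(d$hybrid_id, sprintf("H%03d", seq_len(n_geno)))] +
    r_eff[d$rep] + rnorm(nrow(d), 0, sqrt(sigma_e))
  d
}

# independent optimizer over the package's own restricted likelihood surface
# (nested golden-section searches; no lme4 involved)
reml_grid_oracle <- function(d) {
  prof <- function(log_ratio) {
    inner <- stats::optimize(function(log_se) {
      se <- exp(log_se)
      -reml_loglik(d, sigma_g = exp(log_ratio) * se, sigma_e = se)
    }, c(-12, 6), tol = 1e-12)
    inner$objective
  }
  outer <- stats::optimize(prof, c(-14, 10), tol = 1e-10)
  log_ratio <- outer$minimum
  inner <- stats::optimize(function(log_se) {
    se <- exp(log_se)
    -reml_loglik(d, sigma_g = exp(log_ratio) * se, sigma_e = se)
  }, c(-12, 6), tol = 1e-12)
  se <- exp(inner$minimum)
  c(sigma_g = exp(log_ratio) * se, sigma_e = se)
}
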