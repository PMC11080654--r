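test_that("constant phenotypes give zero genotype variance and zero BLUPs", {
  d <- expand.grid(hybrid_id = paste0("H", 1:6), rep = 1:2,
                   stringsAsFactors = FALSE)
  d$env <- "E1"; d$trait <- "T1"; d$value <- 5
  fit <- fit_env_model(d, "random")
  expect_lt(fit$varcomp[["genotype"]], 1e-8)
  expect_true(all(abs(fit$blup) < 1e-8))
})

test_that("REML recovers known variance components on balanced RCBD data", {
  ests <- t(vapply(1:20, function(s) {
    d <- sim_rcbd(200, 3, sigma_g = 1, sigma_e = 1, seed = s)
    fit <- fit_env_model(d, "random")
    fit$varcomp[c("genotype", "residual")]
  }, c(genotype = 0, residual = 0)))
  expect_lt(abs(mean(ests[, "genotype"]) - 1), 0.15)
  expect_lt(abs(mean(ests[, "residual"]) - 1), 0.15)
})

test_that("REML estimates maximize the package's own restricted likelihood", {
  d <- sim_rcbd(12, 3, seed = 4)
  fit <- fit_env_model(d, "random")
  vg <- fit$varcomp[["genotype"]]; ve <- fit$varcomp[["residual"]]
  ll0 <- reml_loglik(d, vg, ve)
  expect_equal(fit$loglik, ll0, tolerance = 1e-8)
  for (f in c(0.9, 1.1)) {
    expect_lte(reml_loglik(d, vg * f, ve), ll0 + 1e-9)
    expect_lte(reml_loglik(d, vg, ve * f), ll0 + 1e-9)
  }
  expect_error(reml_loglik(d, 1, 0), "positive")
})

test_that("tiny balanced fits agree with an exhaustive variance-ratio search", {
  for (s in 1:3) {
    d <- sim_rcbd(5, 3, sigma_g = 0.8, sigma_e = 0.5, seed = s + 20)
    fit <- fit_env_model(d, "random")
    oracle <- reml_grid_oracle(d)
    expect_equal(fit$varcomp[["genotype"]], oracle[["sigma_g"]],
                 tolerance = 1e-4)
    expect_equal(fit$varcomp[["residual"]], oracle[["sigma_e"]],
                 tolerance = 1e-4)
  }
})

test_that("likelihood-ratio tests follow the chi-square(1) convention", {
  d <- sim_rcbd(40, 2, sigma_g = 1, sigma_e = 1, seed = 3)
  full <- fit_env_model(d, "random")
  reduced <- fit_env_model(d, "random", drop_random = "genotype")
  lrt <- lrt_random_effect(full, reduced)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$p_value,
               pchisq(lrt$statistic, 1, lower.tail = FALSE))
  expect_equal(lrt$p_value_mixture, lrt$p_value / 2)
  expect_true(lrt$significant)     # strong genetic signal

  # no improvement: statistic clipped at zero, p = 1
  same <- lrt_random_effect(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  d2 <- sim_rcbd(40, 2, seed = 99)
  other <- fit_env_model(d2, "random")
  expect_error(lrt_random_effect(full, other), "same data")
})

test_that("null simulations keep the LRT rejection rate near its level", {
  rej <- vapply(1:200, function(s) {
    d <- sim_rcbd(25, 2, sigma_g = 0, sigma_e = 1, seed = 5000 + s)
    full <- fit_env_model(d, "random")
    reduced <- fit_env_model(d, "random", drop_random = "genotype")
    lrt_random_effect(full, reduced)$significant
  }, TRUE)
  expect_lte(mean(rej), 0.075)
})

test_that("heritability follows the entry-mean formula", {
  mk_fit <- function(vg, ve, r_bar) structure(
    list(genotype_as = "random", varcomp = c(genotype = vg, block = 0,
                                             residual = ve), r_bar = r_bar),
    class = "stage1_fit")
  expect_equal(heritability(mk_fit(1, 1, 1)), 0.5)
  expect_equal(heritability(mk_fit(0, 1, 1)), 0)
  expect_equal(heritability(mk_fit(1, 1, 2)), 2 / 3)
  expect_equal(heritability(mk_fit(1, 1, 3), type = "plot"), 0.5)
})

test_that("BLUP correlations match the direct Pearson computation", {
  mk_fit <- function(trait, blup) structure(
    list(trait = trait, blup = blup, genotype_as = "random"),
    class = "stage1_fit")
  v <- c(H1 = 0.3, H2 = -0.1, H3 = 0.5, H4 = 0.0, H5 = -0.6)
  w <- c(H1 = 1.1, H2 = 0.2, H3 = -0.3, H4 = 0.8, H5 = 0.4)
  self_cor <- blup_correlations(list(mk_fit("A", v), mk_fit("B", v)))
  expect_equal(self_cor$r, 1)
  neg <- blup_correlations(list(mk_fit("A", v), mk_fit("B", -v)))
  expect_equal(neg$r, -1)
  toy <- blup_correlations(list(mk_fit("A", v), mk_fit("B", w)), alpha = 0.1)
  hand <- sum((v - mean(v)) * (w - mean(w))) /
    sqrt(sum((v - mean(v))^2) * sum((w - mean(w))^2))
  expect_equal(toy$r, hand, tolerance = 1e-12)
  expect_identical(toy$significant, toy$p_value < 0.1)
  expect_error(blup_correlations(list(mk_fit("A", v[1:2]),
                                      mk_fit("B", w[1:2]))), "shared")
})

test_that("fits are invariant to record order and genotype relabeling", {
  d <- sim_rcbd(15, 2, seed = 8)
  fit <- fit_env_model(d, "random")
  ds <- d[sample(nrow(d)), ]
  fit_s <- fit_env_model(ds, "random")
  expect_equal(fit$varcomp, fit_s$varcomp, tolerance = 1e-8)
  expect_equal(fit$blup, fit_s$blup[names(fit$blup)], tolerance = 1e-8)

  dr <- d
  dr$hybrid_id <- paste0("X", dr$hybrid_id)
  fit_r <- fit_env_model(dr, "random")
  expect_equal(unname(fit$varcomp), unname(fit_r$varcomp), tolerance = 1e-8)
  expect_equal(unname(fit$blup), unname(fit_r$blup[paste0("X", names(fit$blup))]),
               tolerance = 1e-8)
})

test_that("BLUPs shrink toward zero relative to BLUEs and converge when signal dominates", {
  d <- sim_rcbd(30, 3, sigma_g = 1, sigma_e = 1, seed = 11)
  fr <- fit_env_model(d, "random")
  fb <- fit_env_model(d, "fixed")
  centered_blue <- fb$blue - mean(fb$blue)
  expect_true(all(abs(fr$blup) <= abs(centered_blue[names(fr$blup)]) + 1e-8))

  # when genetic variance dominates, BLUPs approach BLUEs
  dh <- sim_rcbd(30, 3, sigma_g = 50, sigma_e = 0.05, seed = 12)
  frh <- fit_env_model(dh, "random")
  fbh <- fit_env_model(dh, "fixed")
  expect_gt(cor(frh$blup, fbh$blue[names(frh$blup)] - mean(fbh$blue)), 0.999)

  # single genotype is unidentifiable
  d1 <- data.frame(env = "E1", hybrid_id = "H1", rep = 1:3, trait = "T1",
                   value = rnorm(3))
  expect_error(fit_env_model(d1, "random"), "2 genotypes")
})

test_that("augmented-design fits estimate block variance and produce entry BLUEs", {
  scn <- small_scenario()
  d <- subset(scn$pheno, env == "S120" & trait == "DTP")
  fr <- fit_env_model(d, "random")
  expect_equal(fr$design, "augmented")
  expect_true(all(fr$varcomp >= 0))
  fb <- fit_env_model(d, "fixed")
  expect_true(all(unique(d$hybrid_id) %in% names(fb$blue)))
  # BLUEs track true genetic values for a heritable trait
  truth <- scn$truth[names(fb$blue), "DTP", 1]
  expect_gt(cor(fb$blue, truth), 0.6)

  full <- fr
  red_block <- fit_env_model(d, "random", drop_random = "block")
  lrt <- lrt_random_effect(full, red_block)
  expect_gte(lrt$statistic, 0)
})

test_that("stage1_all assembles summaries, BLUEs and BLUPs for every cell", {
  scn <- small_scenario()
  s1 <- stage1_all(scn$pheno, traits = c("DTP", "STC"))
  expect_setequal(unique(s1$summary$env), c("S120", "S121"))
  expect_setequal(unique(s1$summary$trait), c("DTP", "STC"))
  expect_true(all(s1$summary$h2 >= 0 & s1$summary$h2 <= 1))
  expect_true(all(c("env", "hybrid_id", "trait", "value") %in% names(s1$blues)))
  # high-heritability trait estimated above low-heritability trait on average
  h2 <- tapply(s1$summary$h2, s1$summary$trait, mean)
  expect_gt(h2[["DTP"]], h2[["STC"]])
})
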