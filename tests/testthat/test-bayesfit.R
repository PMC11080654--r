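test_that("the model grid enumerates the eight labelled structures", {
  grid <- enumerate_model_grid()
  labels <- vapply(grid, `[[`, "", "label")
  expect_length(grid, 8)
  expect_identical(labels,
                   c("AG", "ADG", "MAG", "MADG", "AR", "ADR", "MAR", "MADR"))
  expect_equal(sum(labels == "AG"), 1)
  expect_equal(sum(labels == "MADR"), 1)
  expect_length(enumerate_model_grid(gxe = TRUE), 16)

  # label/spec round trip
  for (spec in grid) {
    back <- parse_model_label(spec$label)
    expect_identical(back[c("method", "effects", "traits")],
                     spec[c("method", "effects", "traits")])
  }
  expect_error(parse_model_label("XYZ"), "unrecognized")
})

test_that("chain bookkeeping stores floor((n_iter - burn_in)/thin) samples", {
  ch <- chain_config(30000, 3000, 10)
  expect_equal(ch$n_stored, 2700)
  expect_equal(chain_config(1000, 100, 7)$n_stored, (1000 - 100) %/% 7)
  expect_error(chain_config(100, 100, 1), "burn_in")
  expect_error(chain_config(100, 99, 50), "no samples")
})

test_that("closed-form GBLUP matches its analytic special cases", {
  y <- c(a = 1, b = 3, c = 5, d = 2)
  g <- closed_form_gblup(y, diag(4), ratio = 1)
  expect_equal(unname(g), unname(y - mean(y)) / 2, tolerance = 1e-12)
  g0 <- closed_form_gblup(y, diag(4), ratio = 1e-12)
  expect_equal(unname(g0), unname(y - mean(y)), tolerance = 1e-5)

  set.seed(5)
  K <- crossprod(matrix(rnorm(25), 5)) + diag(0.1, 5)
  y5 <- rnorm(5)
  direct <- K %*% solve(K + diag(2, 5)) %*% (y5 - mean(y5))
  expect_lt(max(abs(closed_form_gblup(y5, K, 2) - direct)), 1e-10)
})

test_that("fixed-variance Gibbs posterior means track the closed-form BLUP", {
  kern <- small_kernels()
  G <- kern$Ga
  set.seed(21)
  L <- t(chol(G + diag(1e-6, nrow(G))))
  g_true <- drop(L %*% rnorm(nrow(G)))
  y <- stats::setNames(10 + g_true + rnorm(length(g_true)), rownames(G))
  fit <- fit_gibbs(y, kern, model_spec("GBLUP", "A", "single"),
                   chain_config(4000, 1000, 5, seed = 31),
                   fixed_variances = c(Ga = 1, residual = 1))
  oracle <- closed_form_gblup(y, G, ratio = 1)
  pred <- predict_genetic_values(fit)
  expect_gt(cor(pred[, 1], oracle[rownames(pred)]), 0.99)
  expect_equal(fit$n_stored, (4000 - 1000) %/% 5)
  expect_true(all(fit$var_draws >= 0))
})

test_that("fixed seeds reproduce chains exactly and variances stay estimable", {
  kern <- small_kernels()
  set.seed(22)
  y <- stats::setNames(rnorm(nrow(kern$Ga)) + 5, rownames(kern$Ga))
  ch <- chain_config(600, 100, 5, seed = 77)
  f1 <- fit_gibbs(y, kern, model_spec("GBLUP", "AD", "single"), ch)
  f2 <- fit_gibbs(y, kern, model_spec("GBLUP", "AD", "single"), ch)
  expect_identical(f1$var_draws, f2$var_draws)
  expect_identical(f1$effects$Ga$mean, f2$effects$Ga$mean)
  f3 <- fit_gibbs(y, kern, model_spec("GBLUP", "AD", "single"),
                  chain_config(600, 100, 5, seed = 78))
  expect_false(identical(f1$var_draws, f3$var_draws))
})

test_that("RKHS specs attach one variance per bandwidth kernel", {
  kern <- small_kernels()
  set.seed(23)
  y <- stats::setNames(rnorm(nrow(kern$Ga)), rownames(kern$Ga))
  fit <- fit_gibbs(y, kern, model_spec("RKHS", "AD", "single"),
                   chain_config(500, 100, 5, seed = 3))
  expect_setequal(colnames(fit$var_draws),
                  c("Ka5", "Ka1", "Ka02", "Kd5", "Kd1", "Kd02", "residual"))
  comps <- vapply(fit$effects, `[[`, "", "component")
  expect_equal(sum(comps == "a"), 3L)
  expect_equal(sum(comps == "d"), 3L)
})

test_that("multi-trait fits return symmetric PSD covariance draws", {
  kern <- small_kernels()
  scn <- small_scenario()
  Y <- scn$truth[rownames(kern$Ga), c("DTP", "STC"), 1] +
    matrix(rnorm(2 * nrow(kern$Ga), 0, 0.5), ncol = 2)
  fit <- fit_gibbs(Y, kern, model_spec("GBLUP", "A", "multi"),
                   chain_config(600, 200, 10, seed = 5))
  expect_equal(fit$n_stored, 40)
  for (nm in c("Ga", "residual")) {
    draws <- fit$cov_draws[[nm]]
    for (s in c(1, 20, 40)) {
      S <- draws[, , s]
      expect_equal(S, t(S), tolerance = 1e-10)
      expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-10)
    }
  }
})

test_that("multi-trait prediction of uncorrelated traits matches single-trait", {
  kern <- small_kernels()
  G <- kern$Ga
  n <- nrow(G)
  L <- t(chol(G + diag(1e-6, n)))
  diffs <- vapply(1:10, function(s) {
    set.seed(400 + s)
    g1 <- drop(L %*% rnorm(n)); g2 <- drop(L %*% rnorm(n))
    Y <- cbind(t1 = g1 + rnorm(n, 0, 0.8), t2 = g2 + rnorm(n, 0, 0.8))
    rownames(Y) <- rownames(G)
    test_h <- rownames(G)[1:16]
    Ymask <- Y; Ymask[test_h, ] <- NA
    chm <- chain_config(1200, 300, 5, seed = 500 + s)
    fm <- fit_gibbs(Ymask, kern, model_spec("GBLUP", "A", "multi"), chm)
    pm <- predict_genetic_values(fm)[test_h, "t1"]
    ys <- Ymask[, "t1"]
    fs <- fit_gibbs(ys, kern, model_spec("GBLUP", "A", "single"), chm)
    ps <- predict_genetic_values(fs)[test_h, 1]
    cor(pm, g1[1:16]) - cor(ps, g1[1:16])
  }, 0)
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("prediction components decompose additively", {
  kern <- small_kernels()
  set.seed(25)
  y <- stats::setNames(rnorm(nrow(kern$Ga)), rownames(kern$Ga))
  fit <- fit_gibbs(y, kern, model_spec("GBLUP", "AD", "single"),
                   chain_config(500, 100, 5, seed = 9))
  pa <- predict_genetic_values(fit, include = "a")
  pad <- predict_genetic_values(fit, include = c("a", "d"))
  expect_equal(pad - pa, fit$effects$Gd$mean, tolerance = 1e-12)
  expect_equal(pa, fit$effects$Ga$mean, tolerance = 1e-12)
  expect_error(predict_genetic_values(fit, include = "gxe_a"), "absent")

  fa <- fit_gibbs(y, kern, model_spec("GBLUP", "A", "single"),
                  chain_config(400, 100, 5, seed = 9))
  expect_error(predict_genetic_values(fa, include = "d"), "absent")
})

test_that("an unphenotyped hybrid with a duplicated kernel row gets the same prediction", {
  scn <- small_scenario()
  hyb <- scn$hybrids
  dup <- structure(list(
    hybrid_ids = c(hyb$hybrid_ids, "HDUP"),
    additive = rbind(hyb$additive, HDUP = hyb$additive[1, ]),
    dominance = rbind(hyb$dominance, HDUP = hyb$dominance[1, ]),
    marker_ids = hyb$marker_ids), class = "hybrid_genotypes")
  kern <- build_kernel_set(dup)
  set.seed(26)
  y <- stats::setNames(c(rnorm(length(hyb$hybrid_ids)), NA),
                       c(hyb$hybrid_ids, "HDUP"))
  fit <- fit_gibbs(y, kern, model_spec("GBLUP", "A", "single"),
                   chain_config(800, 200, 5, seed = 13))
  pred <- predict_genetic_values(fit)
  expect_equal(pred["HDUP", 1], pred[hyb$hybrid_ids[1], 1], tolerance = 1e-8)
})

test_that("GxE fits partition variance between main and interaction kernels", {
  kern <- small_kernels()
  G <- kern$Ga
  n <- nrow(G)
  set.seed(27)
  L <- t(chol(G + diag(1e-6, n)))
  g_main <- drop(L %*% rnorm(n))
  g_e1 <- drop(L %*% rnorm(n)) * 0.7
  g_e2 <- drop(L %*% rnorm(n)) * 0.7
  y <- c(2 + g_main + g_e1 + rnorm(n, 0, 0.5),
         4 + g_main + g_e2 + rnorm(n, 0, 0.5))
  env <- rep(c("E1", "E2"), each = n)
  hybrid <- rep(rownames(G), 2)
  fit <- fit_gibbs(matrix(y, ncol = 1), kern,
                   model_spec("GBLUP", "A", "single", gxe = TRUE),
                   chain_config(1500, 300, 5, seed = 15),
                   env = env, hybrid = hybrid)
  expect_setequal(colnames(fit$var_draws), c("Ga", "GaxE", "residual"))
  expect_gt(fit$var_post_mean[["GaxE"]], 0.05)
  pred <- predict_genetic_values(fit)
  expect_gt(cor(pred[rownames(G), 1], g_main), 0.7)
  # environment fixed effect recovered (difference of intercepts about 2)
  expect_length(fit$fixed_names, 2)
})
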