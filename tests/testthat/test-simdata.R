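test_that("parent panels honor heterozygosity, dimensions and determinism", {
  p <- simulate_parents(62, 2000, n_groups = 2, seed = 7)
  expect_equal(dim(p$genotypes), c(62, 2000))
  expect_length(unique(p$group), 2)
  expect_true(all(p$genotypes %in% c(0, 2)))      # no residual heterozygosity
  expect_equal(colMeans(p$genotypes) / 2, p$allele_freq, tolerance = 1e-12)

  p2 <- simulate_parents(62, 2000, n_groups = 2, seed = 7)
  expect_identical(p$genotypes, p2$genotypes)
  p3 <- simulate_parents(62, 2000, n_groups = 2, seed = 8)
  expect_false(identical(p$genotypes, p3$genotypes))

  ph <- simulate_parents(40, 500, residual_het_rate = 0.2, seed = 1)
  expect_true(any(ph$genotypes == 1))
  expect_true(all(ph$genotypes %in% 0:2))

  pm <- simulate_parents(20, 200, missing_rate = 0.1, seed = 2)
  expect_true(anyNA(pm$genotypes))
  expect_true(all(pm$genotypes %in% 0:2 | is.na(pm$genotypes)))

  expect_error(simulate_parents(1, 10), "n_parents")
  expect_error(simulate_parents(10, 10, maf_range = c(0, 0.6)), "maf_range")
})

test_that("crossing plans enumerate unordered pairs under both schemes", {
  p100 <- simulate_parents(100, 10, n_groups = 2, seed = 1)
  full <- make_cross_plan(p100, scheme = "full_diallel", seed = 1)
  expect_equal(nrow(full), 100 * 99 / 2)
  expect_true(all(full$parent1 != full$parent2))
  key <- apply(cbind(pmin(full$parent1, full$parent2),
                     pmax(full$parent1, full$parent2)), 1, paste, collapse = "|")
  expect_equal(anyDuplicated(key), 0L)

  p2 <- simulate_parents(2, 10, n_groups = 1, seed = 1)
  expect_equal(nrow(make_cross_plan(p2, scheme = "full_diallel")), 1)

  # inter-group factorial: brute-force enumeration oracle for groups of 3 and 4
  p7 <- simulate_parents(7, 10, n_groups = 1, seed = 1)
  p7$group[] <- rep(c("A", "B"), c(3, 4))
  oracle <- sum(outer(p7$group, p7$group, "!=")[upper.tri(diag(7))])
  ig <- make_cross_plan(p7, scheme = "inter_group_factorial")
  expect_equal(nrow(ig), 12)
  expect_equal(nrow(ig), oracle)
  expect_true(all(p7$group[ig$parent1] != p7$group[ig$parent2]))

  expect_error(make_cross_plan(p7, n_hybrids = 13,
                               scheme = "inter_group_factorial"),
               "exceeds admissible")
  sub <- make_cross_plan(p100, n_hybrids = 50, scheme = "full_diallel", seed = 3)
  expect_equal(nrow(sub), 50)
  expect_identical(sub, make_cross_plan(p100, n_hybrids = 50,
                                        scheme = "full_diallel", seed = 3))
})

test_that("marker effects respect dominance ratio and environment correlation", {
  p <- simulate_parents(20, 300, seed = 3)
  cfg <- data.frame(trait = c("A1", "A2"), h2 = c(0.5, 0.5),
                    dominance_ratio = c(0, 0), group = "g1")
  eff <- simulate_effects(p, cfg, n_envs = 2, seed = 4)
  expect_true(all(eff$dominance_effects == 0))

  # perfect genetic correlation across environments: identical env values
  plan <- make_cross_plan(p, 40, seed = 1)
  ones <- matrix(1, 2, 2)
  eff1 <- simulate_effects(p, cfg, n_envs = 2, gxe_correlation = ones, seed = 4)
  design <- trial_design(
    data.frame(env = c("E1", "E2"), site = "S", year = 1:2, design = "rcbd",
               n_reps = 2, n_blocks = NA),
    list(E1 = plan$hybrid_id, E2 = plan$hybrid_id))
  tr <- simulate_trial(p, plan, eff1, design, seed = 5)
  expect_equal(tr$truth[, , 1], tr$truth[, , 2], tolerance = 1e-12)

  expect_error(simulate_effects(p, cfg, n_envs = 2,
                                gxe_correlation = matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite|correlation")
})

test_that("cross-group genetic-value correlation tracks the configured level", {
  p <- simulate_parents(40, 500, seed = 11)
  plan <- make_cross_plan(p, 500, scheme = "full_diallel", seed = 11)
  cfg <- data.frame(trait = c("T1", "T2"), h2 = c(0.6, 0.6),
                    dominance_ratio = 0, group = c("g1", "g2"))
  design <- trial_design(
    data.frame(env = "E1", site = "S", year = 1, design = "rcbd",
               n_reps = 1, n_blocks = NA),
    list(E1 = plan$hybrid_id))
  # Monte-Carlo: realized correlation averaged over independent effect draws
  r <- vapply(1:5, function(s) {
    eff <- simulate_effects(p, cfg, n_envs = 1, r_between = 0.1,
                            seed = 12 + s)
    tr <- simulate_trial(p, plan, eff, design, seed = 13 + s)
    cor(tr$truth[, 1, 1], tr$truth[, 2, 1])
  }, 0)
  expect_lt(abs(mean(r) - 0.1), 0.15)
})

test_that("trials honor design bookkeeping and the noise-free limit", {
  scn <- small_scenario()
  p <- scn$panel; plan <- scn$plan; eff <- scn$effects

  # noise-free single-rep trial reproduces true genetic values exactly
  d0 <- trial_design(
    data.frame(env = "E1", site = "S", year = 1, design = "rcbd",
               n_reps = 1, n_blocks = NA),
    list(E1 = plan$hybrid_id))
  tr0 <- simulate_trial(p, plan, eff, d0, rep_sd = 0, residual_scale = 0,
                        seed = 3)
  expect_equal(tr0$pheno$value,
               tr0$truth[, , 1][cbind(tr0$pheno$hybrid_id, tr0$pheno$trait)],
               tolerance = 1e-12)

  # rcbd with 3 reps: every hybrid appears exactly 3 times per trait
  d3 <- trial_design(
    data.frame(env = "E1", site = "S", year = 1, design = "rcbd",
               n_reps = 3, n_blocks = NA),
    list(E1 = plan$hybrid_id[1:30]))
  tr3 <- simulate_trial(p, plan, eff, d3, seed = 4)
  one_tr <- subset(tr3$pheno, trait == tr3$pheno$trait[1])
  expect_true(all(table(one_tr$hybrid_id) == 3))

  # augmented design: every check occurs in every block
  aug <- subset(scn$pheno, env == "S120" & trait == scn$pheno$trait[1])
  expect_true(any(aug$is_check))
  checks <- unique(aug$hybrid_id[aug$is_check])
  blocks <- unique(aug$block)
  for (ck in checks)
    expect_setequal(unique(aug$block[aug$hybrid_id == ck]), blocks)

  # unknown hybrids rejected
  dbad <- trial_design(
    data.frame(env = "E1", site = "S", year = 1, design = "rcbd",
               n_reps = 2, n_blocks = NA),
    list(E1 = c(plan$hybrid_id[1], "NOPE")))
  expect_error(simulate_trial(p, plan, eff, dbad, seed = 1), "absent")

  # determinism of the full table
  tr_a <- simulate_trial(p, plan, eff, d3, seed = 9)
  tr_b <- simulate_trial(p, plan, eff, d3, seed = 9)
  expect_identical(tr_a$pheno, tr_b$pheno)
})

test_that("plot-level heritability is calibrated across replicate simulations", {
  cfg <- data.frame(trait = "T1", h2 = 0.5, dominance_ratio = 0.2,
                    group = "g1")
  h2_emp <- vapply(1:20, function(s) {
    p <- simulate_parents(20, 200, seed = s)
    plan <- make_cross_plan(p, 120, scheme = "full_diallel", seed = s)
    eff <- simulate_effects(p, cfg, n_envs = 1, seed = s)
    d <- trial_design(
      data.frame(env = "E1", site = "S", year = 1, design = "rcbd",
                 n_reps = 2, n_blocks = NA),
      list(E1 = plan$hybrid_id))
    tr <- simulate_trial(p, plan, eff, d, rep_sd = 0, seed = s + 1000)
    g <- tr$truth[tr$pheno$hybrid_id, 1, 1]
    var(tr$truth[, 1, 1]) / (var(tr$truth[, 1, 1]) + var(tr$pheno$value - g))
  }, 0)
  expect_lt(abs(mean(h2_emp) - 0.5), 0.1)
})

test_that("year-2 subsets control hybrid overlap between years", {
  scn <- small_scenario()
  h20 <- scn$design$hybrids_per_env[["S120"]]
  h21 <- scn$design$hybrids_per_env[["S121"]]
  expect_gt(length(intersect(h20, h21)), 0)      # some tested hybrids return
  expect_lt(length(h21), length(h20))            # year 2 smaller
})
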