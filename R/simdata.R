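# Synthetic breeding-program data: inbred parent panels, crossing plans,
# marker-effect architectures and multi-environment trial phenotypes.

#' Simulate a panel of inbred parents
#'
#' Draws per-marker allele frequencies independently for each heterotic group
#' from the same frequency range, then samples parents as (mostly) homozygous
#' inbreds: at each locus a parent carries dosage 2 with probability equal to
#' its group's allele frequency, dosage 0 otherwise, and is heterozygous
#' (dosage 1) with probability `residual_het_rate`.
#'
#' @param n_parents number of inbred parents (>= 2)
#' @param n_markers number of biallelic markers
#' @param n_groups number of heterotic groups; parents are split into
#'   contiguous blocks of (near) equal size
#' @param maf_range numeric length-2 interval in (0, 0.5] from which per-group
#'   allele frequencies are drawn uniformly
#' @param residual_het_rate probability that a parent is heterozygous at a
#'   locus (residual heterozygosity of incompletely inbred lines)
#' @param missing_rate probability that a genotype call is missing
#' @param seed integer seed; identical seeds reproduce identical panels
#' @return an object of class `parent_panel`: list with `parent_ids`, `group`,
#'   `genotypes` (parents x markers dosage matrix in \{0,1,2\} with `NA`
#'   allowed), `marker_ids`, and `allele_freq` (realized frequency per marker)
#' @export
simulate_parents <- function(n_parents, n_markers, n_groups = 2,
                             maf_range = c(0.1, 0.5), residual_het_rate = 0,
                             missing_rate = 0, seed = 1) {
  n_parents <- check_count(n_parents, "n_parents", min = 2L)
  n_markers <- check_count(n_markers, "n_markers")
  n_groups <- check_count(n_groups, "n_groups")
  if (length(maf_range) != 2 || diff(maf_range) < 0 ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("`maf_range` must be an interval within (0, 0.5]")
  check_proportion(residual_het_rate, "residual_het_rate")
  check_proportion(missing_rate, "missing_rate")

  group <- rep(seq_len(n_groups), length.out = n_parents)
  group <- sort(group)
  G <- with_seed(substream_seed(seed, "genotypes"), {
    freq <- matrix(stats::runif(n_groups * n_markers, maf_range[1], maf_range[2]),
                   nrow = n_groups)
    g <- matrix(0L, n_parents, n_markers)
    for (i in seq_len(n_parents)) {
      p <- freq[group[i], ]
      het <- stats::runif(n_markers) < residual_het_rate
      hom2 <- stats::runif(n_markers) < p
      g[i, ] <- ifelse(het, 1L, ifelse(hom2, 2L, 0L))
    }
    if (missing_rate > 0)
      g[matrix(stats::runif(length(g)) < missing_rate, nrow(g))] <- NA
    g
  })
  parent_ids <- sprintf("P%03d", seq_len(n_parents))
  marker_ids <- sprintf("M%05d", seq_len(n_markers))
  dimnames(G) <- list(parent_ids, marker_ids)
  structure(list(
    parent_ids = parent_ids,
    group = stats::setNames(paste0("G", group), parent_ids),
    genotypes = G,
    marker_ids = marker_ids,
    allele_freq = colMeans(G, na.rm = TRUE) / 2
  ), class = "parent_panel")
}

#' @export
print.parent_panel <- function(x, ...) {
  cat(sprintf("parent_panel: %d parents (%d groups) x %d markers\n",
              length(x$parent_ids), length(unique(x$group)),
              length(x$marker_ids)))
  invisible(x)
}

#' Build a crossing plan from a parent panel
#'
#' `"full_diallel"` enumerates all `N(N-1)/2` unordered parent pairs (no
#' reciprocals, no selfs) and subsamples `n_hybrids` of them;
#' `"inter_group_factorial"` restricts to pairs whose parents belong to
#' different heterotic groups, emulating crosses between two breeding pools.
#'
#' @param panel a [`simulate_parents()`] panel
#' @param n_hybrids number of crosses to retain; `NULL` keeps all admissible
#'   pairs
#' @param scheme `"full_diallel"` or `"inter_group_factorial"`
#' @param seed integer seed controlling the subsample
#' @return an object of class `cross_plan`: data.frame with columns
#'   `hybrid_id`, `parent1`, `parent2`
#' @export
make_cross_plan <- function(panel, n_hybrids = NULL,
                            scheme = c("inter_group_factorial", "full_diallel"),
                            seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(panel, "parent_panel"))
  ids <- panel$parent_ids
  pairs <- utils::combn(ids, 2)
  if (scheme == "inter_group_factorial") {
    keep <- panel$group[pairs[1, ]] != panel$group[pairs[2, ]]
    pairs <- pairs[, keep, drop = FALSE]
  }
  n_adm <- ncol(pairs)
  if (is.null(n_hybrids)) n_hybrids <- n_adm
  n_hybrids <- check_count(n_hybrids, "n_hybrids")
  if (n_hybrids > n_adm)
    stop(sprintf("n_hybrids (%d) exceeds admissible pairs (%d) under scheme '%s'",
                 n_hybrids, n_adm, scheme))
  sel <- if (n_hybrids < n_adm) {
    with_seed(substream_seed(seed, "crossplan"),
              sort(sample.int(n_adm, n_hybrids)))
  } else seq_len(n_adm)
  plan <- data.frame(
    hybrid_id = sprintf("H%04d", seq_len(n_hybrids)),
    parent1 = pairs[1, sel],
    parent2 = pairs[2, sel],
    stringsAsFactors = FALSE
  )
  class(plan) <- c("cross_plan", "data.frame")
  plan
}

trait_corr_matrix <- function(groups, r_within = 0.7, r_between = 0.1) {
  t <- length(groups)
  R <- matrix(r_between, t, t)
  same <- outer(groups, groups, "==")
  R[same] <- r_within
  diag(R) <- 1
  R
}

#' Default trait architecture
#'
#' Twenty traits in three correlated groups (plant, ear, flavor) with
#' heritability targets spanning 0.05-0.85 and mild dominance, emulating the
#' qualitative pattern of a fresh-market sweet corn program. Used by
#' [simulate_scenario()] when no trait table is supplied.
#'
#' @param n_traits number of traits to keep (first `n_traits` rows)
#' @return data.frame with columns `trait`, `h2`, `dominance_ratio`, `group`
#' @export
default_trait_config <- function(n_traits = 20) {
  traits <- data.frame(
    trait = c("STC", "DTP", "DTS", "PH", "EH",
              "EL", "EW", "TPF", "HP", "KRN", "SOL", "TP", "CUR",
              "HAP", "RAP", "ES", "CR", "RT",
              "FLA", "TXT"),
    h2 = c(0.35, 0.82, 0.78, 0.60, 0.28,
           0.80, 0.65, 0.55, 0.45, 0.75, 0.25, 0.40, 0.12,
           0.50, 0.45, 0.55, 0.60, 0.50,
           0.05, 0.31),
    dominance_ratio = rep(c(0.2, 0.3, 0.25), c(5, 13, 2)),
    group = rep(c("plant", "ear", "flavor"), c(5, 13, 2)),
    stringsAsFactors = FALSE
  )
  utils::head(traits, check_count(n_traits, "n_traits"))
}

#' Simulate marker-effect architecture
#'
#' Draws additive and dominance marker effects with a block trait-correlation
#' structure (high within trait group, low between) and, across environments,
#' a genetic correlation given by `gxe_correlation`, so environment-specific
#' genetic values deviate in a controlled way. Effects are scaled so that the
#' expected additive genetic variance of each trait (under the panel's allele
#' frequencies) equals its heritability target on a unit phenotypic scale and
#' the dominance variance equals `dominance_ratio` times the additive
#' variance.
#'
#' @param panel a [`simulate_parents()`] panel
#' @param trait_config data.frame with columns `trait`, `h2` in (0,1),
#'   `dominance_ratio` >= 0 and `group`
#' @param n_envs number of environments
#' @param gxe_correlation `n_envs` x `n_envs` genetic correlation matrix
#'   across environments (unit diagonal, PSD); default 0.6 off-diagonal
#' @param r_within,r_between genetic correlation among traits within / between
#'   trait groups
#' @param seed integer seed
#' @return an object of class `effect_set` with marker-effect arrays
#'   `additive` and `dominance` of dimension `[n_markers, n_traits, n_envs]`,
#'   trait covariance matrices, `env_correlation` and `target_h2`
#' @export
simulate_effects <- function(panel, trait_config = default_trait_config(),
                             n_envs = 1, gxe_correlation = NULL,
                             r_within = 0.7, r_between = 0.1, seed = 1) {
  stopifnot(inherits(panel, "parent_panel"))
  n_envs <- check_count(n_envs, "n_envs")
  stopifnot(all(c("trait", "h2", "dominance_ratio", "group") %in%
                  names(trait_config)))
  if (any(trait_config$h2 <= 0 | trait_config$h2 >= 1))
    stop("heritability targets must lie in (0,1)")
  if (any(trait_config$dominance_ratio < 0))
    stop("dominance_ratio must be >= 0")
  if (is.null(gxe_correlation)) {
    gxe_correlation <- matrix(0.6, n_envs, n_envs)
    diag(gxe_correlation) <- 1
  }
  if (!isTRUE(all.equal(dim(gxe_correlation), c(n_envs, n_envs))) ||
      any(abs(diag(gxe_correlation) - 1) > 1e-8) ||
      any(abs(gxe_correlation) > 1 + 1e-8))
    stop("gxe_correlation must be an n_envs x n_envs correlation matrix")
  Renv <- sym_sqrt(gxe_correlation)          # errors if not PSD

  m <- length(panel$marker_ids)
  t <- nrow(trait_config)
  Rtrait <- trait_corr_matrix(trait_config$group, r_within, r_between)
  Lt <- sym_sqrt(Rtrait)

  p <- panel$allele_freq
  p[is.na(p)] <- 0.5
  wa <- 2 * p * (1 - p)                      # additive variance weight
  wd <- (2 * p * (1 - p))^2                  # dominance variance weight

  draw_effects <- function(weights, target_var) {
    X <- array(stats::rnorm(m * t * n_envs), dim = c(m, t, n_envs))
    eff <- array(0, dim = c(m, t, n_envs))
    for (j in seq_len(m))
      eff[j, , ] <- Lt %*% X[j, , , drop = TRUE] %*% t(Renv)
    # scale each trait so expected genetic variance hits its target
    for (k in seq_len(t)) {
      if (target_var[k] == 0) { eff[, k, ] <- 0; next }
      v0 <- sum(weights * eff[, k, 1]^2)
      if (v0 > 0) eff[, k, ] <- eff[, k, ] * sqrt(target_var[k] / v0)
    }
    eff
  }

  va <- trait_config$h2
  vd <- trait_config$dominance_ratio * va
  eff <- with_seed(substream_seed(seed, "effects"), {
    list(additive = draw_effects(wa, va), dominance = draw_effects(wd, vd))
  })
  dn <- list(panel$marker_ids, trait_config$trait, paste0("env", seq_len(n_envs)))
  dimnames(eff$additive) <- dn
  dimnames(eff$dominance) <- dn

  sd_a <- sqrt(va); sd_d <- sqrt(vd)
  structure(list(
    additive_effects = eff$additive,
    dominance_effects = eff$dominance,
    trait_cov_additive = Rtrait * tcrossprod(sd_a),
    trait_cov_dominance = Rtrait * tcrossprod(sd_d),
    env_correlation = gxe_correlation,
    target_h2 = stats::setNames(va, trait_config$trait),
    dominance_ratio = stats::setNames(trait_config$dominance_ratio,
                                      trait_config$trait),
    trait_config = trait_config
  ), class = "effect_set")
}

#' Multi-environment trial design specification
#'
#' @param envs data.frame with columns `env`, `site`, `year`, `design`
#'   (`"rcbd"` or `"augmented"`), `n_reps`, and `n_blocks` (augmented only;
#'   total blocks, divided evenly among replications)
#' @param hybrids_per_env named list (by env) of hybrid ids grown in each
#'   environment
#' @param checks character vector of check entries; required when any
#'   environment is augmented. Checks appear in every block.
#' @return an object of class `trial_design`
#' @export
trial_design <- function(envs, hybrids_per_env, checks = character()) {
  stopifnot(all(c("env", "site", "year", "design", "n_reps") %in% names(envs)))
  stopifnot(all(envs$design %in% c("rcbd", "augmented")))
  if (any(envs$design == "augmented")) {
    if (!"n_blocks" %in% names(envs)) stop("augmented designs need `n_blocks`")
    if (length(checks) < 1)
      stop("augmented designs need at least one check entry")
  }
  if (!all(envs$env %in% names(hybrids_per_env)))
    stop("every env must have an entry in `hybrids_per_env`")
  structure(list(envs = envs, hybrids_per_env = hybrids_per_env,
                 checks = checks), class = "trial_design")
}

#' Unbalanced two-year, multi-site design emulating a hybrid trial series
#'
#' Year-1 environments receive large hybrid sets; year-2 environments receive
#' smaller sets built by subsampling year-1 hybrids (fraction `overlap`) plus
#' new hybrids, which makes prediction of tested vs. untested hybrids in the
#' new year (CV0 vs CV00) distinguishable.
#'
#' @param hybrid_ids all hybrid ids available
#' @param n_sites number of sites
#' @param year1_frac,year2_frac fraction of hybrids grown per site in year 1 /
#'   year 2
#' @param overlap fraction of each year-2 set drawn from the same site's
#'   year-1 set
#' @param design_year1,design_year2 `"rcbd"` or `"augmented"` per year
#' @param n_reps replications per environment
#' @param n_blocks total blocks for augmented environments
#' @param n_checks number of check entries (taken from the first hybrids and
#'   excluded from test sets)
#' @param seed integer seed
#' @return a [`trial_design()`] object
#' @export
multi_env_design <- function(hybrid_ids, n_sites = 3,
                             year1_frac = 0.6, year2_frac = 0.15,
                             overlap = 0.6,
                             design_year1 = c("augmented", "rcbd", "rcbd"),
                             design_year2 = c("rcbd", "augmented", "rcbd"),
                             n_reps = 2, n_blocks = 10, n_checks = 4,
                             seed = 1) {
  n_sites <- check_count(n_sites, "n_sites")
  design_year1 <- rep(design_year1, length.out = n_sites)
  design_year2 <- rep(design_year2, length.out = n_sites)
  checks <- utils::head(hybrid_ids, n_checks)
  pool <- setdiff(hybrid_ids, checks)
  sites <- paste0("S", seq_len(n_sites))
  envs <- expand.grid(site = sites, year = c(2020L, 2021L),
                      stringsAsFactors = FALSE)
  envs$env <- paste0(envs$site, substr(envs$year, 3, 4))
  envs$design <- c(design_year1, design_year2)[
    (envs$year - 2020L) * n_sites + match(envs$site, sites)]
  envs$n_reps <- n_reps
  envs$n_blocks <- ifelse(envs$design == "augmented", n_blocks, NA_integer_)
  hybrids_per_env <- with_seed(substream_seed(seed, "design"), {
    out <- list()
    for (s in sites) {
      y1 <- sample(pool, max(2, round(year1_frac * length(pool))))
      n2 <- max(2, round(year2_frac * length(pool)))
      n_keep <- min(round(overlap * n2), length(y1))
      y2 <- c(sample(y1, n_keep),
              sample(setdiff(pool, y1), n2 - n_keep))
      out[[paste0(s, "20")]] <- sort(y1)
      out[[paste0(s, "21")]] <- sort(y2)
    }
    out
  })
  needs_checks <- any(envs$design == "augmented")
  trial_design(envs[, c("env", "site", "year", "design", "n_reps", "n_blocks")],
               hybrids_per_env,
               checks = if (needs_checks) checks else character())
}

# True (expected-genotype) hybrid marker content used to form genetic values:
# additive = parental mean dosage; dominance content = expected
# heterozygosity of the cross (1 for opposite homozygotes, 0 for identical
# homozygotes, 0.5 when a parent is heterozygous).
true_hybrid_content <- function(panel, plan) {
  G <- panel$genotypes
  g1 <- G[plan$parent1, , drop = FALSE]
  g2 <- G[plan$parent2, , drop = FALSE]
  add <- (g1 + g2) / 2
  dom <- matrix(0.5, nrow(add), ncol(add))
  dom[g1 == 0 & g2 == 0] <- 0
  dom[g1 == 2 & g2 == 2] <- 0
  dom[(g1 == 0 & g2 == 2) | (g1 == 2 & g2 == 0)] <- 1
  dom[g1 == 1 & g2 == 1] <- 0.5
  rownames(add) <- rownames(dom) <- plan$hybrid_id
  colnames(dom) <- colnames(add)
  list(additive = add, dominance = dom)
}

# Genetic value array [n_hybrids x n_traits x n_envs] from an effect set.
genetic_values <- function(panel, plan, effects) {
  hc <- true_hybrid_content(panel, plan)
  A <- scale(hc$additive, center = TRUE, scale = FALSE)
  D <- scale(hc$dominance, center = TRUE, scale = FALSE)
  A[is.na(A)] <- 0; D[is.na(D)] <- 0
  dims <- dim(effects$additive_effects)
  out <- array(0, dim = c(nrow(A), dims[2], dims[3]),
               dimnames = c(list(plan$hybrid_id), dimnames(effects$additive_effects)[2:3]))
  for (e in seq_len(dims[3]))
    out[, , e] <- A %*% effects$additive_effects[, , e] +
      D %*% effects$dominance_effects[, , e]
  out
}

#' Simulate a multi-environment trial
#'
#' Generates plot-level phenotypes as genetic value + replicate effect +
#' (block effect, augmented designs) + residual. Residual variance per trait
#' is calibrated against the realized genetic variance of the hybrid set so
#' that plot-level heritability `Vg / (Vg + Ve)` matches each trait's target.
#'
#' @param panel,plan,effects panel, crossing plan and effect set the hybrids
#'   derive from
#' @param design a [`trial_design()`]
#' @param traits_per_env optional named list restricting which traits are
#'   measured in each environment (missing trait x env cells)
#' @param rep_sd,block_sd standard deviations of replicate and block effects,
#'   expressed as multiples of the residual standard deviation
#' @param residual_scale multiplier on the calibrated residual standard
#'   deviation (0 gives noise-free phenotypes equal to genetic value plus
#'   design effects)
#' @param seed integer seed
#' @return list with `pheno` (long-format data.frame: env, site, year,
#'   hybrid_id, rep, block, is_check, trait, value) and `truth`
#'   (`[n_hybrids, n_traits, n_envs]` array of true genetic values)
#' @export
simulate_trial <- function(panel, plan, effects, design,
                           traits_per_env = NULL,
                           rep_sd = 0.3, block_sd = 0.3,
                           residual_scale = 1, seed = 1) {
  stopifnot(inherits(design, "trial_design"))
  all_h <- unique(unlist(design$hybrids_per_env))
  if (!all(all_h %in% plan$hybrid_id))
    stop("design references hybrids absent from the crossing plan")
  if (length(design$checks) && !all(design$checks %in% plan$hybrid_id))
    stop("design references check entries absent from the crossing plan")

  truth <- genetic_values(panel, plan, effects)
  traits <- dimnames(truth)[[2]]
  n_envs_eff <- dim(truth)[3]
  envs <- design$envs
  if (nrow(envs) > n_envs_eff)
    stop("effect set has fewer environments than the design")

  # residual sd per trait from realized genetic variance (mean across envs)
  vg <- apply(truth, c(2, 3), stats::var)
  vg_bar <- rowMeans(vg)
  h2 <- effects$target_h2[traits]
  sd_e <- sqrt(vg_bar * (1 - h2) / h2)
  sd_e[vg_bar == 0] <- 1

  rows <- with_seed(substream_seed(seed, "noise"), {
    out <- vector("list", nrow(envs))
    for (ei in seq_len(nrow(envs))) {
      env <- envs$env[ei]
      hyb <- design$hybrids_per_env[[env]]
      tr <- if (is.null(traits_per_env)) traits else
        intersect(traits_per_env[[env]] %||% traits, traits)
      n_reps <- envs$n_reps[ei]
      if (envs$design[ei] == "rcbd") {
        plots <- data.frame(
          hybrid_id = rep(hyb, times = n_reps),
          rep = rep(seq_len(n_reps), each = length(hyb)),
          block = NA_integer_, is_check = FALSE,
          stringsAsFactors = FALSE)
      } else {
        checks <- design$checks
        entries <- setdiff(hyb, checks)
        blocks_per_rep <- max(1L, envs$n_blocks[ei] %/% n_reps)
        plots <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
          blk <- rep(seq_len(blocks_per_rep), length.out = length(entries))
          blk <- sample(blk)
          rbind(
            data.frame(hybrid_id = entries, rep = r,
                       block = (r - 1L) * blocks_per_rep + blk,
                       is_check = FALSE, stringsAsFactors = FALSE),
            data.frame(hybrid_id = rep(checks, each = blocks_per_rep),
                       rep = r,
                       block = (r - 1L) * blocks_per_rep +
                         rep(seq_len(blocks_per_rep), length(checks)),
                       is_check = TRUE, stringsAsFactors = FALSE))
        }))
      }
      rep_eff <- stats::rnorm(n_reps)
      blk_ids <- sort(unique(plots$block))
      blk_eff <- stats::setNames(stats::rnorm(length(blk_ids)), blk_ids)
      env_rows <- lapply(tr, function(trait) {
        g <- truth[plots$hybrid_id, trait, ei]
        noise <- stats::rnorm(nrow(plots), 0, residual_scale * sd_e[trait])
        val <- g + rep_sd * sd_e[trait] * rep_eff[plots$rep] + noise
        if (envs$design[ei] == "augmented")
          val <- val + block_sd * sd_e[trait] * blk_eff[as.character(plots$block)]
        data.frame(env = env, site = envs$site[ei], year = envs$year[ei],
                   plots, trait = trait, value = val,
                   stringsAsFactors = FALSE)
      })
      out[[ei]] <- do.call(rbind, env_rows)
    }
    out
  })
  pheno <- do.call(rbind, rows)
  rownames(pheno) <- NULL
  list(pheno = pheno, truth = truth)
}

#' Simulate a complete hybrid-prediction scenario
#'
#' One-stop generator: parent panel, inter-group crossing plan, hybrid
#' genotype coding, marker effects and a multi-environment phenotype table.
#' Defaults emulate a two-pool breeding program: 62 inbred parents in two
#' heterotic groups, ~500 inter-group hybrids, three sites by two years with
#' unbalanced hybrid sets, and twenty traits in three correlated groups with
#' heritabilities spanning 0.05-0.85.
#'
#' @param n_parents,n_markers,n_groups panel dimensions
#' @param n_hybrids number of inter-group crosses
#' @param trait_config trait table (see [default_trait_config()])
#' @param n_sites number of sites (environments = sites x 2 years)
#' @param env_corr genetic correlation between environments
#' @param overlap fraction of each year-2 hybrid set re-grown from year 1
#' @param seed integer seed driving all substreams
#' @param ... passed to [multi_env_design()]
#' @return list with components `panel`, `plan`, `hybrids`
#'   ([hybrid_genotypes()]), `effects`, `design`, `pheno`, `truth`
#' @export
simulate_scenario <- function(n_parents = 62, n_markers = 2000, n_groups = 2,
                              n_hybrids = 506,
                              trait_config = default_trait_config(),
                              n_sites = 3, env_corr = 0.6, overlap = 0.6,
                              seed = 1, ...) {
  panel <- simulate_parents(n_parents, n_markers, n_groups, seed = seed)
  plan <- make_cross_plan(panel, n_hybrids = n_hybrids,
                          scheme = "inter_group_factorial", seed = seed)
  n_envs <- 2L * n_sites
  R <- matrix(env_corr, n_envs, n_envs); diag(R) <- 1
  effects <- simulate_effects(panel, trait_config, n_envs = n_envs,
                              gxe_correlation = R, seed = seed)
  design <- multi_env_design(plan$hybrid_id, n_sites = n_sites,
                             overlap = overlap, seed = seed, ...)
  trial <- simulate_trial(panel, plan, effects, design, seed = seed)
  hybrids <- hybrid_genotypes(panel, plan)
  list(panel = panel, plan = plan, hybrids = hybrids, effects = effects,
       design = design, pheno = trial$pheno, truth = trial$truth)
}
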