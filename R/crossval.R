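# CV1 / CV0 / CV00 cross-validation schemes and prediction accuracy.

#' CV1 fold assignments (untested hybrids in tested environments)
#'
#' Per repeat, randomly partitions the hybrid set into `k` folds of equal
#' size (within one), each fold serving once as the test set (so each fold
#' holds 1/k of the hybrids); folds are re-randomized every repeat.
#'
#' @param hybrids hybrid ids
#' @param k number of folds
#' @param n_repeats number of independent repeats
#' @param seed integer seed
#' @return object of class `cv1_folds`: list of per-repeat fold assignments
#'   (integer vector in `1..k` named by hybrid)
#' @export
make_cv1_folds <- function(hybrids, k = 5, n_repeats = 20, seed = 1) {
  k <- check_count(k, "k", min = 2L)
  n_repeats <- check_count(n_repeats, "n_repeats")
  n <- length(hybrids)
  if (n < k) stop("need at least k hybrids")
  folds <- with_seed(substream_seed(seed, "folds"), {
    lapply(seq_len(n_repeats), function(r)
      stats::setNames(sample(rep(seq_len(k), length.out = n)), hybrids))
  })
  structure(folds, scheme = "CV1", k = k, n_repeats = n_repeats,
            class = "cv1_folds")
}

#' CV0 split (tested hybrids in untested environments)
#'
#' All records of the training environments train; all records of the test
#' environment are predicted. Hybrids may occur on both sides: the hybrids
#' are tested, the environment is not.
#'
#' @param table table with `env` and `hybrid_id` columns (phenotypes or
#'   stage-1 BLUEs)
#' @param train_envs,test_env disjoint environment ids present in `table`
#' @return object of class `cv_partition` with `train` and `test` record
#'   data.frames (env, hybrid_id)
#' @export
make_cv0_split <- function(table, train_envs, test_env) {
  stopifnot(all(c("env", "hybrid_id") %in% names(table)))
  if (length(intersect(train_envs, test_env)))
    stop("train and test environments must be disjoint")
  present <- unique(table$env)
  missing_env <- setdiff(c(train_envs, test_env), present)
  if (length(missing_env))
    stop("environment(s) absent from table: ",
         paste(missing_env, collapse = ", "))
  train <- table[table$env %in% train_envs, c("env", "hybrid_id")]
  test <- table[table$env %in% test_env, c("env", "hybrid_id")]
  rownames(train) <- rownames(test) <- NULL
  structure(list(scheme = "CV0", train = train, test = test),
            class = "cv_partition")
}

#' CV00 split (untested hybrids in untested environments)
#'
#' As [make_cv0_split()], then removes every training record whose hybrid
#' also occurs in the test environment, so no hybrid id appears on both
#' sides.
#'
#' @inheritParams make_cv0_split
#' @return a `cv_partition` with scheme `"CV00"`
#' @export
make_cv00_split <- function(table, train_envs, test_env) {
  part <- make_cv0_split(table, train_envs, test_env)
  overlap <- part$train$hybrid_id %in% unique(part$test$hybrid_id)
  part$train <- part$train[!overlap, , drop = FALSE]
  rownames(part$train) <- NULL
  if (nrow(part$train) == 0)
    stop("training set is empty after removing overlapping hybrids")
  part$scheme <- "CV00"
  part
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted genetic values and stage-1 BLUEs.
#'
#' @param pred,blue paired numeric vectors of equal length >= 3
#' @return correlation coefficient in `[-1, 1]`
#' @export
accuracy <- function(pred, blue) {
  if (length(pred) != length(blue)) stop("vectors must have equal length")
  keep <- !is.na(pred) & !is.na(blue)
  pred <- pred[keep]; blue <- blue[keep]
  if (length(pred) < 3) stop("need at least 3 paired values")
  if (stats::sd(pred) == 0 || stats::sd(blue) == 0)
    stop("zero variance in predictions or BLUEs")
  stats::cor(pred, blue)
}

blues_wide <- function(blues, env) {
  b <- blues[blues$env == env, , drop = FALSE]
  hy <- unique(b$hybrid_id); tr <- unique(b$trait)
  W <- matrix(NA_real_, length(hy), length(tr), dimnames = list(hy, tr))
  W[cbind(match(b$hybrid_id, hy), match(b$trait, tr))] <- b$value
  W
}

fit_and_predict <- function(Y, kernels, spec, chain, env = NULL,
                            hybrid = NULL, all_hybrids = NULL,
                            include = NULL) {
  fit <- fit_gibbs(Y, kernels, spec, chain, env = env, hybrid = hybrid,
                   all_hybrids = all_hybrids)
  predict_genetic_values(fit, include = include)
}

#' Run a cross-validation scheme over a model grid
#'
#' For every partition x model spec x trait, fits the model on the training
#' responses (test responses withheld), predicts the test hybrids'
#' genetic values, and scores the Pearson correlation against the withheld
#' test-environment BLUEs. CV1 partitions take the BLUEs of a single
#' environment; CV0/CV00 partitions train on the training environments'
#' BLUEs. G x E specs fit the record-level response with environment fixed
#' effects and interaction kernels; prediction into the untested environment
#' uses the genetic main effects only.
#'
#' @param blues long-format stage-1 BLUE table (env, hybrid_id, trait, value)
#' @param kernels a [build_kernel_set()] covering all hybrids involved
#' @param specs list of [model_spec()]s (or a single spec)
#' @param partitions a [make_cv1_folds()] object, a single `cv_partition`,
#'   or a list of `cv_partition`s
#' @param chain a [chain_config()]; per-fit seeds are derived from its seed
#' @param traits optional subset of traits
#' @param include components used for prediction (default: `"a"` for A
#'   specs, `c("a","d")` for AD specs)
#' @return an accuracy table: data.frame with scheme, model, trait, env,
#'   accuracy (fold-averaged per repeat for CV1), n_test and repeat
#' @export
run_scheme <- function(blues, kernels, specs, partitions,
                       chain = chain_config(), traits = NULL, include = NULL) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  counter <- 0
  next_chain <- function() {
    counter <<- counter + 1
    chain_config(chain$n_iter, chain$burn_in, chain$thin,
                 seed = (chain$seed + 97L * counter) %% 2147483647)
  }
  rows <- list()
  add_row <- function(scheme, model, trait, env, acc, n_test, rep_i) {
    rows[[length(rows) + 1]] <<- data.frame(
      scheme = scheme, model = model, trait = trait, env = env,
      accuracy = acc, n_test = n_test, repeat_ = rep_i,
      stringsAsFactors = FALSE)
  }

  if (inherits(partitions, "cv1_folds")) {
    env <- unique(blues$env)
    if (length(env) != 1)
      stop("CV1 runs on the BLUEs of a single environment")
    W <- blues_wide(blues, env)
    trs <- intersect(traits %||% colnames(W), colnames(W))
    k <- attr(partitions, "k")
    for (spec in specs) {
      multi <- spec$traits == "multi"
      for (r in seq_along(partitions)) {
        fold_of <- partitions[[r]]
        fold_of <- fold_of[names(fold_of) %in% rownames(W)]
        acc_ft <- matrix(NA_real_, k, length(trs),
                         dimnames = list(NULL, trs))
        n_ft <- matrix(0L, k, length(trs))
        for (f in seq_len(k)) {
          test_h <- names(fold_of)[fold_of == f]
          if (multi) {
            Y <- W[, trs, drop = FALSE]
            Y[test_h, ] <- NA
            pred <- fit_and_predict(Y, kernels, spec, next_chain(),
                                    include = include)
            for (tr in trs) {
              th <- test_h[!is.na(W[test_h, tr])]
              if (length(th) >= 3) {
                acc_ft[f, tr] <- accuracy(pred[th, tr], W[th, tr])
                n_ft[f, match(tr, trs)] <- length(th)
              }
            }
          } else {
            for (tr in trs) {
              y <- W[, tr]
              y <- y[!is.na(y)]
              th <- intersect(test_h, names(y))
              if (length(th) < 3) next
              y_train <- y; y_train[th] <- NA
              pred <- fit_and_predict(y_train, kernels, spec, next_chain(),
                                      include = include)
              acc_ft[f, tr] <- accuracy(pred[th, 1], y[th])
              n_ft[f, match(tr, trs)] <- length(th)
            }
          }
        }
        for (tr in trs)
          add_row("CV1", spec$label, tr, env,
                  mean(acc_ft[, tr], na.rm = TRUE),
                  sum(n_ft[, match(tr, trs)]), r)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }

  if (inherits(partitions, "cv_partition")) partitions <- list(partitions)
  for (part in partitions) {
    stopifnot(inherits(part, "cv_partition"))
    train_envs <- unique(part$train$env)
    test_env <- unique(part$test$env)
    if (length(test_env) != 1) stop("one test environment per partition")
    test_h_all <- unique(part$test$hybrid_id)
    Wtest <- blues_wide(blues, test_env)
    trs <- intersect(traits %||% colnames(Wtest), colnames(Wtest))
    for (spec in specs) {
      multi <- spec$traits == "multi"
      if (spec$gxe) {
        ## record-level response over training environments
        btr <- blues[blues$env %in% train_envs, , drop = FALSE]
        keep_key <- paste(part$train$env, part$train$hybrid_id)
        btr <- btr[paste(btr$env, btr$hybrid_id) %in% keep_key, , drop = FALSE]
        recs <- unique(btr[, c("env", "hybrid_id")])
        Y <- matrix(NA_real_, nrow(recs), length(trs),
                    dimnames = list(NULL, trs))
        for (tr in trs) {
          bt <- btr[btr$trait == tr, ]
          idx <- match(paste(recs$env, recs$hybrid_id),
                       paste(bt$env, bt$hybrid_id))
          Y[, tr] <- bt$value[idx]
        }
        all_h <- union(recs$hybrid_id, test_h_all)
        run_traits <- if (multi) list(trs) else as.list(trs)
        for (tset in run_traits) {
          Ysub <- Y[, tset, drop = FALSE]
          ok <- rowSums(!is.na(Ysub)) > 0
          if (!multi) Ysub <- Ysub[ok, , drop = FALSE] else Ysub <- Ysub[ok, , drop = FALSE]
          pred <- fit_and_predict(
            if (multi) Ysub else stats::setNames(Ysub[, 1], NULL),
            kernels, spec, next_chain(),
            env = recs$env[ok], hybrid = recs$hybrid_id[ok],
            all_hybrids = all_h, include = include)
          for (tr in tset) {
            th <- intersect(test_h_all, rownames(Wtest))
            th <- th[!is.na(Wtest[th, tr])]
            if (length(th) < 3) next
            add_row(part$scheme, spec$label, tr, test_env,
                    accuracy(pred[th, if (multi) tr else 1], Wtest[th, tr]),
                    length(th), 1L)
          }
        }
      } else {
        if (length(train_envs) != 1)
          stop("non-GxE specs require a single training environment; ",
               "use a G x E spec for multi-environment training sets")
        Wtrain <- blues_wide(blues, train_envs)
        train_h <- unique(part$train$hybrid_id)
        all_h <- union(train_h, test_h_all)
        ## response over all hybrids; non-training hybrids stay NA
        Yfull <- matrix(NA_real_, length(all_h), length(trs),
                        dimnames = list(all_h, trs))
        hin <- intersect(train_h, rownames(Wtrain))
        Yfull[hin, ] <- Wtrain[hin, trs, drop = FALSE]
        if (multi) {
          pred <- fit_and_predict(Yfull, kernels, spec, next_chain(),
                                  include = include)
          for (tr in trs) {
            th <- intersect(test_h_all, rownames(Wtest))
            th <- th[!is.na(Wtest[th, tr])]
            if (length(th) < 3) next
            add_row(part$scheme, spec$label, tr, test_env,
                    accuracy(pred[th, tr], Wtest[th, tr]), length(th), 1L)
          }
        } else {
          for (tr in trs) {
            y <- Yfull[, tr]
            pred <- fit_and_predict(y, kernels, spec, next_chain(),
                                    include = include)
            th <- intersect(test_h_all, rownames(Wtest))
            th <- th[!is.na(Wtest[th, tr])]
            if (length(th) < 3) next
            add_row(part$scheme, spec$label, tr, test_env,
                    accuracy(pred[th, 1], Wtest[th, tr]), length(th), 1L)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate an accuracy table over repeats
#'
#' @param acc output of [run_scheme()]
#' @return data.frame with mean accuracy and its standard deviation per
#'   scheme x model x trait x env
#' @export
aggregate_accuracy <- function(acc) {
  key <- interaction(acc$scheme, acc$model, acc$trait, acc$env, drop = TRUE)
  out <- do.call(rbind, lapply(split(acc, key), function(d) {
    data.frame(scheme = d$scheme[1], model = d$model[1], trait = d$trait[1],
               env = d$env[1], mean_accuracy = mean(d$accuracy, na.rm = TRUE),
               sd_accuracy = stats::sd(d$accuracy),
               n_repeats = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
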