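test_that("fold plans partition positives into near-equal disjoint parts", {
  A <- make_assoc(10, 8, density = 0.25, seed = 1)
  n_pos <- sum(A)
  plan <- make_folds(A, 5, seed = 3)
  expect_equal(sort(unique(plan$fold_pos)), 1:5)
  sizes <- tabulate(plan$fold_pos, 5)
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sum(sizes), n_pos)
  # every positive appears exactly once
  keys <- paste(plan$positives[, 1], plan$positives[, 2])
  expect_equal(sort(keys),
               sort(unname(apply(which(unclass(A) == 1, arr.ind = TRUE), 1,
                                 paste, collapse = " "))))
  # negatives are zero entries, distinct, equal in count
  expect_equal(nrow(plan$negatives), n_pos)
  expect_true(all(unclass(A)[plan$negatives] == 0))
  expect_false(anyDuplicated(paste(plan$negatives[, 1],
                                   plan$negatives[, 2])) > 0)
  # determinism and balanced remainder rule
  expect_identical(make_folds(A, 5, seed = 3), plan)
  A11 <- make_assoc(11, 6, density = 0.17, seed = 4) # give 11 positives
  n11 <- sum(A11)
  s <- tabulate(make_folds(A11, 5, seed = 1)$fold_pos, 5)
  expect_equal(sort(s, decreasing = TRUE),
               sort(c(rep(n11 %/% 5 + 1, n11 %% 5),
                      rep(n11 %/% 5, 5 - n11 %% 5)), decreasing = TRUE))
})

test_that("metrics match hand-derived confusion-matrix values", {
  m <- compute_metrics(c(0.9, 0.1), c(1, 0))
  expect_equal(m$auroc, 1)
  expect_equal(m$aupr, 1)
  m2 <- compute_metrics(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0))
  expect_equal(m2$auroc, 0.75)
  expect_equal(m2$accuracy, 0.5) # TP=1 FP=1 FN=1 TN=1 at 0.5
  expect_equal(m2$f1, 0.5)
  expect_error(compute_metrics(c(0.2, 0.3), c(1, 1)), "negative")
})

test_that("AUROC and AUPR match exhaustive references on short vectors", {
  set.seed(11)
  # all label patterns for n <= 8 (both classes present), scores with ties
  for (n in c(3, 5, 8)) {
    for (rep_i in 1:40) {
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) next
      scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
      m <- compute_metrics(scores, labels)
      expect_equal(m$auroc, reference_auroc(scores, labels),
                   tolerance = 1e-12)
      expect_equal(m$aupr, reference_aupr(scores, labels),
                   tolerance = 1e-12)
    }
  }
})

test_that("AUROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  scores <- runif(60); labels <- rbinom(60, 1, 0.4)
  expect_equal(compute_metrics(scores, labels)$auroc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<",
                                              levels = c("0", "1")))))
})

test_that("the CV pipeline pools fold scores and honours injected scorers", {
  A <- make_assoc(10, 8, density = 0.25, seed = 5)
  cfg <- ogn_config(k = 4, L_conv = 1, epochs = 1, seed = 7)
  truth_scorer <- function(network, A_train, train_mask, config) {
    # oracle: score with the full ground truth (including held-out pairs)
    unclass(A) * 0.9 + 0.05
  }
  rep_o <- run_cv(A, config = cfg, n_repeats = 2, scorer = truth_scorer)
  expect_true(all(rep_o$per_repeat$auroc == 1))
  const_scorer <- function(network, A_train, train_mask, config) {
    array(0.5, dim(A))
  }
  rep_c <- run_cv(A, config = cfg, n_repeats = 1, scorer = const_scorer)
  expect_equal(rep_c$per_repeat$auroc, 0.5)
})

test_that("no held-out pair influences its fold's training loss or kernels", {
  A <- make_assoc(10, 8, density = 0.25, seed = 6)
  cfg <- ogn_config(k = 4, L_conv = 1, epochs = 1, seed = 1)
  seen <- list()
  spy <- function(network, A_train, train_mask, config) {
    seen[[length(seen) + 1]] <<- list(A_train = unclass(A_train),
                                      mask = train_mask,
                                      H = network$H)
    array(0.5, dim(A))
  }
  plan <- make_folds(A, 5, seed = ordlink:::sub_seed(cfg$seed, "repeat1"))
  invisible(run_cv(A, config = cfg, n_repeats = 1, scorer = spy))
  expect_length(seen, 5)
  Nd <- nrow(A)
  for (f in 1:5) {
    held_pos <- plan$positives[plan$fold_pos == f, , drop = FALSE]
    held_neg <- plan$negatives[plan$fold_neg == f, , drop = FALSE]
    # held-out positives are zeroed in the training matrix
    expect_true(all(seen[[f]]$A_train[held_pos] == 0))
    # and masked out of the loss, as are the held-out negatives
    expect_true(all(!seen[[f]]$mask[held_pos]))
    expect_true(all(!seen[[f]]$mask[held_neg]))
    # all other pairs are masked in
    expect_equal(sum(!seen[[f]]$mask), nrow(held_pos) + nrow(held_neg))
    # leakage-safe kernels: similarity blocks derive from the masked matrix
    net_ref <- prepare_fold_inputs(A, held_pos, leakage_safe = TRUE)
    expect_equal(seen[[f]]$H, net_ref$H)
  }
})

test_that("paired ablation shares fold plans across arms", {
  A <- make_assoc(9, 7, density = 0.3, seed = 8)
  cfg <- ogn_config(k = 4, L_conv = 2, epochs = 3, seed = 5)
  plans <- list(ordered = NULL, plain = NULL)
  spy_plans <- new.env(); spy_plans$masks <- list()
  spy <- function(network, A_train, train_mask, config) {
    spy_plans$masks[[length(spy_plans$masks) + 1]] <- train_mask
    array(0.5, dim(A))
  }
  invisible(run_cv(A, config = cfg, n_repeats = 1, scorer = spy))
  masks1 <- spy_plans$masks; spy_plans$masks <- list()
  cfg_p <- cfg; cfg_p$model <- "plain"
  invisible(run_cv(A, config = cfg_p, n_repeats = 1, scorer = spy))
  expect_identical(masks1, spy_plans$masks) # identical seeds -> identical splits
  # the real thing: run_ablation produces both arms
  pair <- run_ablation(A, config = ogn_config(k = 4, L_conv = 1, epochs = 2,
                                              seed = 3),
                       n_repeats = 1)
  expect_s3_class(pair$ordered, "ogn_metrics_report")
  expect_s3_class(pair$plain, "ogn_metrics_report")
  expect_equal(pair$plain$config$model, "plain")
})

test_that("the hyperparameter sweep covers the deduplicated grid", {
  A <- make_assoc(8, 6, density = 0.3, seed = 2)
  cfg <- ogn_config(k = 4, L_conv = 1, epochs = 2, seed = 1)
  tab <- sweep_hyperparameters(A, list(L_conv = c(1, 2, 1), k = c(4, 6)),
                               cfg, n_repeats = 1)
  expect_equal(nrow(tab), 4) # duplicates removed
  expect_true(all(tab$mean_auroc >= 0 & tab$mean_auroc <= 1))
  expect_setequal(tab$L_conv, c(1, 2))
  expect_error(sweep_hyperparameters(A, list(L_conv = c(), k = 1), cfg),
               "grid")
})

test_that("metrics JSON is byte-identical across reruns with one seed", {
  A <- make_assoc(9, 7, density = 0.3, seed = 4)
  cfg <- ogn_config(k = 4, L_conv = 1, epochs = 3, seed = 11)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(run_cv(A, config = cfg, n_repeats = 2), f1)
  write_metrics_json(run_cv(A, config = cfg, n_repeats = 2), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
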