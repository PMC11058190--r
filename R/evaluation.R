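# Cross-validation protocol and metrics. Known associations are split
# equally into 5 folds; a sampled negative set of the same size is split
# likewise; per repeat, every fold's held-out scores are pooled into one
# combined test set and the metrics are computed once on it. Reports are
# means +/- standard deviations across independent repeats.

#' Build a cross-validation fold plan
#'
#' Shuffles all known positives into `n_folds` near-equal parts (sizes
#' differ by at most one) and samples an equally sized negative set
#' uniformly without replacement from the zero entries, partitioned the
#' same way. Deterministic given the seed.
#'
#' @param A an [association_matrix()].
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @return an `"ogn_fold_plan"`: `positives`/`negatives` (two-column index
#'   matrices), `fold_pos`/`fold_neg` (fold labels in 1..n_folds),
#'   `n_folds`, `seed`.
#' @export
make_folds <- function(A, n_folds = 5L, seed = 1L) {
  Am <- unclass_matrix(A)
  pos <- which(Am == 1, arr.ind = TRUE)
  zero <- which(Am == 0, arr.ind = TRUE)
  n_pos <- nrow(pos)
  if (n_pos < n_folds)
    stop_input("need at least %d positives for %d folds", n_folds, n_folds)
  if (nrow(zero) < n_pos)
    stop_input("fewer zero entries than positives: cannot sample negatives")
  with_seed(seed, {
    pos <- pos[sample.int(n_pos), , drop = FALSE]
    neg <- zero[sample.int(nrow(zero), n_pos), , drop = FALSE]
  })
  fold_sizes <- function(n) {
    base <- n %/% n_folds
    sizes <- rep(base, n_folds)
    extra <- n - base * n_folds
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    sizes
  }
  labels <- rep(seq_len(n_folds), times = fold_sizes(n_pos))
  structure(list(positives = unname(pos[, 1:2]),
                 negatives = unname(neg[, 1:2]),
                 fold_pos = labels, fold_neg = labels,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "ogn_fold_plan")
}

#' Threshold-free and thresholded classification metrics
#'
#' AUROC is the Mann-Whitney rank statistic (ties count 1/2); AUPR is the
#' area under the precision-recall step curve evaluated at the distinct
#' score thresholds; accuracy and F1 use `score >= threshold`.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector of the same length, both classes present.
#' @param threshold cutoff for accuracy/F1 (default 0.5).
#' @return list with `auroc`, `aupr`, `accuracy`, `f1`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop_input("scores and labels differ in length")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop_input("metrics need at least one positive and one negative label")
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # PR step curve over distinct thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE) # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  aupr <- sum(diff(c(0, recall)) * precision)
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1 & labels == 1); FP <- sum(pred == 1 & labels == 0)
  FN <- sum(pred == 0 & labels == 1)
  accuracy <- mean(pred == labels)
  f1 <- if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN)
  list(auroc = auroc, aupr = aupr, accuracy = accuracy, f1 = f1)
}

default_scorer <- function(network, A_train, train_mask, config) {
  state <- train_model(network, A_train, train_mask, config)
  predict_scores(state, network)
}

#' Run the repeated 5-fold cross-validation study
#'
#' Per repeat: build a fold plan; for each fold, zero that fold's
#' positives out of the training matrix, rebuild the heterogeneous
#' network ([prepare_fold_inputs()]), train, and score the fold's
#' held-out positives and sampled negatives; pool every fold's test
#' scores into one combined test set and compute the metrics once.
#' Reported values are means and standard deviations across repeats.
#'
#' @param A an [association_matrix()].
#' @param DSS,MFS optional curated similarity matrices.
#' @param config an [ogn_config()]; `config$seed` is the run seed from
#'   which all per-repeat and per-fold seeds are derived.
#' @param n_repeats number of independent repetitions (default 10).
#' @param n_folds number of folds (default 5).
#' @param scorer scoring backend: a
#'   `function(network, A_train, train_mask, config)` returning a score
#'   matrix. The default trains the model; injectable for protocol tests.
#' @return an `"ogn_metrics_report"`: `per_repeat` data frame and a
#'   `summary` data frame of mean/sd per metric.
#' @export
run_cv <- function(A, DSS = NULL, MFS = NULL, config = ogn_config(),
                   n_repeats = 10L, n_folds = 5L,
                   scorer = default_scorer) {
  per <- vector("list", n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    rep_seed <- sub_seed(config$seed, paste0("repeat", rep_i))
    plan <- make_folds(A, n_folds = n_folds, seed = rep_seed)
    scores_all <- numeric(0); labels_all <- integer(0)
    for (f in seq_len(plan$n_folds)) {
      held_pos <- plan$positives[plan$fold_pos == f, , drop = FALSE]
      held_neg <- plan$negatives[plan$fold_neg == f, , drop = FALSE]
      network <- prepare_fold_inputs(A, held_pos, DSS, MFS,
                                     leakage_safe = config$leakage_safe)
      train_mask <- array(TRUE, dim(A))
      train_mask[held_pos] <- FALSE
      train_mask[held_neg] <- FALSE
      fold_config <- config
      fold_config$seed <- sub_seed(rep_seed, paste0("fold", f))
      S <- scorer(network, network$A, train_mask, fold_config)
      scores_all <- c(scores_all, S[held_pos], S[held_neg])
      labels_all <- c(labels_all, rep(1L, nrow(held_pos)),
                      rep(0L, nrow(held_neg)))
    }
    m <- compute_metrics(scores_all, labels_all, config$threshold)
    per[[rep_i]] <- data.frame(repeat_id = rep_i, auroc = m$auroc,
                               aupr = m$aupr, accuracy = m$accuracy,
                               f1 = m$f1)
  }
  per <- do.call(rbind, per)
  metrics <- c("auroc", "aupr", "accuracy", "f1")
  summary <- data.frame(metric = metrics,
                        mean = vapply(metrics, function(m) mean(per[[m]]), 0),
                        sd = vapply(metrics, function(m) stats::sd(per[[m]]), 0),
                        row.names = NULL)
  summary$sd[is.na(summary$sd)] <- 0
  structure(list(per_repeat = per, summary = summary,
                 n_repeats = n_repeats, n_folds = n_folds,
                 config = config),
            class = "ogn_metrics_report")
}

#' @export
print.ogn_metrics_report <- function(x, ...) {
  cat(sprintf("ogn_metrics_report: %d repeats of %d-fold CV (model: %s)\n",
              x$n_repeats, x$n_folds, x$config$model))
  with(x$summary,
       cat(sprintf("  %-9s %.4f +/- %.4f\n", metric, mean, sd), sep = ""))
  invisible(x)
}

#' Paired ablation: ordered gating vs plain mean-aggregation baseline
#'
#' Runs the cross-validation study twice with identical seeds (hence
#' bit-identical fold plans): once with the full ordered model and once
#' with the baseline whose layer is `h = LN(0.5 h_prev + 0.5 m)` — a
#' plain mean-aggregator GNN sharing every other component — so the
#' comparison isolates exactly the ordered gating mechanism.
#'
#' @inheritParams run_cv
#' @param baseline `"plain"` (1:1 blend, default) or `"message"`.
#' @return list with elements `ordered` and `plain`, both
#'   `"ogn_metrics_report"`.
#' @export
run_ablation <- function(A, DSS = NULL, MFS = NULL, config = ogn_config(),
                         n_repeats = 1L, n_folds = 5L,
                         baseline = c("plain", "message")) {
  baseline <- match.arg(baseline)
  cfg_o <- config; cfg_o$model <- "ordered"
  cfg_b <- config; cfg_b$model <- baseline
  list(ordered = run_cv(A, DSS, MFS, cfg_o, n_repeats, n_folds),
       plain = run_cv(A, DSS, MFS, cfg_b, n_repeats, n_folds))
}

#' Grid search over depth and embedding dimension
#'
#' Runs [run_cv()] at every (L_conv, k) grid point (duplicates removed)
#' and returns a tidy table ready for heatmap plotting.
#'
#' @inheritParams run_cv
#' @param grid list with numeric vectors `L_conv` and `k`.
#' @param base_config an [ogn_config()] supplying all other settings.
#' @return data frame with columns `L_conv`, `k`, `mean_auroc`,
#'   `sd_auroc`.
#' @export
sweep_hyperparameters <- function(A, grid, base_config = ogn_config(),
                                  DSS = NULL, MFS = NULL,
                                  n_repeats = 1L, n_folds = 5L) {
  if (!length(grid$L_conv) || !length(grid$k))
    stop_input("grid must supply non-empty L_conv and k vectors")
  pts <- unique(expand.grid(L_conv = grid$L_conv, k = grid$k))
  out <- lapply(seq_len(nrow(pts)), function(i) {
    cfg <- base_config
    cfg$L_conv <- as.integer(pts$L_conv[i])
    cfg$k <- as.integer(pts$k[i])
    rep_ <- run_cv(A, DSS, MFS, cfg, n_repeats, n_folds)
    data.frame(L_conv = cfg$L_conv, k = cfg$k,
               mean_auroc = rep_$summary$mean[rep_$summary$metric == "auroc"],
               sd_auroc = rep_$summary$sd[rep_$summary$metric == "auroc"])
  })
  do.call(rbind, out)
}

#' Write a metrics report as JSON
#'
#' Schema: `repeats` (list keyed by repeat id with the four metrics) and
#' `summary` (mean/sd per metric). Byte-stable for identical reports.
#' @param report an `"ogn_metrics_report"`.
#' @param path output path.
#' @export
write_metrics_json <- function(report, path) {
  reps <- lapply(seq_len(nrow(report$per_repeat)), function(i) {
    as.list(report$per_repeat[i, c("auroc", "aupr", "accuracy", "f1")])
  })
  names(reps) <- report$per_repeat$repeat_id
  summ <- lapply(seq_len(nrow(report$summary)), function(i) {
    list(mean = report$summary$mean[i], sd = report$summary$sd[i])
  })
  names(summ) <- report$summary$metric
  jsonlite::write_json(list(repeats = reps, summary = summ), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write pooled ROC and PR curve tables
#'
#' Emits TSVs of (fpr, tpr) and (recall, precision) points at every
#' distinct score threshold, for external plotting.
#' @param scores,labels pooled test scores and 0/1 labels.
#' @param roc_path,pr_path output paths (`NULL` to skip one).
#' @export
write_curves <- function(scores, labels, roc_path = NULL, pr_path = NULL) {
  ord <- order(scores, decreasing = TRUE)
  y <- as.integer(labels)[ord]; s <- scores[ord]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  if (!is.null(roc_path)) {
    utils::write.table(data.frame(fpr = c(0, fp / n_neg),
                                  tpr = c(0, tp / n_pos)),
                       roc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(pr_path)) {
    utils::write.table(data.frame(recall = tp / n_pos,
                                  precision = tp / (tp + fp)),
                       pr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
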