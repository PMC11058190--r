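# Full-batch training: Adam on the weighted cross-entropy, with node and
# feature dropout during training only. All randomness (initialisation,
# dropout) fans out deterministically from the config seed.

#' Training configuration
#'
#' Defaults follow the reference protocol: embedding dimension `k = 512`
#' and `L_conv = 12` message-passing layers (the grid-search optimum),
#' two MLP layers, Adam learning rate `r = 0.008`, `epochs = 600`, node
#' dropout `beta = 0.6`, feature dropout `gamma = 0.4`. Studies at desk
#' scale typically reduce `k`, `L_conv` and `epochs`.
#'
#' @param k embedding dimension (>= 2).
#' @param L_conv number of message-passing layers (>= 1).
#' @param L_fc number of MLP layers (fixed at 2).
#' @param learning_rate Adam step size.
#' @param epochs number of full-batch epochs (>= 1).
#' @param node_dropout rate `beta` in [0, 1): whole message rows dropped.
#' @param feature_dropout rate `gamma` in [0, 1): element-wise on layer
#'   outputs.
#' @param leakage_safe recompute GIP kernels per fold from the masked
#'   matrix (default `TRUE`).
#' @param threshold classification cutoff for accuracy/F1 (default 0.5).
#' @param model `"ordered"` (full model), `"plain"` (ablation baseline,
#'   gate fixed at 0.5) or `"message"` (pure-message baseline, gate 0).
#' @param consistency_weight weight of the optional two-forward-pass
#'   consistency penalty on the predictive distributions (0 = off,
#'   the default; when on, each epoch runs two stochastic forwards and
#'   adds a symmetric KL term between their score matrices).
#' @param seed integer run seed.
#' @return an `"ogn_config"` list.
#' @export
ogn_config <- function(k = 512, L_conv = 12, L_fc = 2,
                       learning_rate = 0.008, epochs = 600,
                       node_dropout = 0.6, feature_dropout = 0.4,
                       leakage_safe = TRUE, threshold = 0.5,
                       model = c("ordered", "plain", "message"),
                       consistency_weight = 0, seed = 1L) {
  model <- match.arg(model)
  if (k < 2) stop_input("k must be >= 2")
  if (L_conv < 1) stop_input("L_conv must be >= 1")
  if (L_fc != 2) stop_input("the MLP embedding is fixed at two layers")
  if (learning_rate <= 0) stop_input("learning_rate must be positive")
  if (epochs < 1) stop_input("epochs must be >= 1")
  if (node_dropout < 0 || node_dropout >= 1)
    stop_input("node_dropout must lie in [0, 1)")
  if (feature_dropout < 0 || feature_dropout >= 1)
    stop_input("feature_dropout must lie in [0, 1)")
  if (threshold <= 0 || threshold >= 1)
    stop_input("threshold must lie in (0, 1)")
  if (consistency_weight < 0) stop_input("consistency_weight must be >= 0")
  structure(list(k = as.integer(k), L_conv = as.integer(L_conv),
                 L_fc = 2L, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 node_dropout = node_dropout,
                 feature_dropout = feature_dropout,
                 leakage_safe = isTRUE(leakage_safe),
                 threshold = threshold, model = model,
                 consistency_weight = consistency_weight,
                 seed = as.integer(seed)),
            class = "ogn_config")
}

gate_mode_of <- function(config) {
  if (config$model == "ordered") "ordered" else "fixed"
}
fixed_gate_of <- function(config) {
  if (config$model == "message") 0 else 0.5
}

#' Train the model on one (masked) association matrix
#'
#' Runs `epochs` full-batch iterations of encode -> decode -> weighted
#' cross-entropy -> Adam step. The balance factor `lambda` is the ratio
#' of masked-in negatives to masked-in positives, recomputed here for
#' every call. Dropout is active during training only; with both rates
#' zero the run is a pure deterministic function of (seed, inputs,
#' config).
#'
#' @param network a `"heterogeneous_network"` (from
#'   [prepare_fold_inputs()] or [build_heterogeneous()]).
#' @param A_train binary training association matrix (held-out positives
#'   already zeroed); defaults to `network$A`.
#' @param train_mask logical Nd x Nm matrix; `FALSE` marks pairs excluded
#'   from the loss (held-out test positives and test negatives).
#' @param config an [ogn_config()].
#' @return an `"ogn_state"` list: `params`, `epoch`, `loss_history`,
#'   `lambda`, `config`.
#' @export
train_model <- function(network, A_train = network$A, train_mask = NULL,
                        config = ogn_config()) {
  A <- unclass_matrix(A_train)
  if (is.null(train_mask)) train_mask <- array(TRUE, dim(A))
  n_pos <- sum(train_mask & A == 1)
  n_neg <- sum(train_mask & A == 0)
  if (n_pos == 0) stop_input("no positive training pairs under the mask")
  lambda <- n_neg / n_pos
  n <- network$Nd + network$Nm
  Wagg <- agg_operator(network$H)
  params <- init_parameters(n, config$k, config$L_conv,
                            seed = sub_seed(config$seed, "init"))
  opt <- adam_new(params, config$learning_rate)
  dropout <- list(node = config$node_dropout,
                  feature = config$feature_dropout)
  gate_mode <- gate_mode_of(config)
  fixed_gate <- fixed_gate_of(config)
  loss_history <- numeric(config$epochs)
  drug_rows <- seq_len(network$Nd)

  loss_and_grads <- function() {
    fw <- ogn_forward(Wagg, network$H_init, params,
                      gate_mode = gate_mode, fixed_gate = fixed_gate,
                      dropout = dropout, training = TRUE)
    h_d <- fw$h[drug_rows, , drop = FALSE]
    h_m <- fw$h[-drug_rows, , drop = FALSE]
    S <- h_d %*% params$W_B %*% t(h_m)
    P <- sigmoid(S)
    loss <- weighted_bce_loss(P, A, train_mask, lambda)
    list(fw = fw, h_d = h_d, h_m = h_m, S = S, P = P, loss = loss)
  }
  backward_from <- function(pass, dS) {
    grads <- list(W_B = crossprod(pass$h_d, dS %*% pass$h_m))
    dh_d <- dS %*% pass$h_m %*% t(params$W_B)
    dh_m <- crossprod(dS, pass$h_d) %*% params$W_B
    enc <- ogn_backward(pass$fw, params, rbind(dh_d, dh_m))
    c(grads, enc)
  }

  with_seed(sub_seed(config$seed, "dropout"), {
    for (epoch in seq_len(config$epochs)) {
      p1 <- loss_and_grads()
      dS1 <- bce_score_grad(p1$P, A, train_mask, lambda)
      loss <- p1$loss
      if (config$consistency_weight > 0) {
        # R-Drop style: a second stochastic forward plus a symmetric-KL
        # penalty between the two Bernoulli score fields
        p2 <- loss_and_grads()
        dS2 <- bce_score_grad(p2$P, A, train_mask, lambda)
        w <- config$consistency_weight
        nm <- sum(train_mask)
        d1 <- p1$P[train_mask]; d2 <- p2$P[train_mask]
        s1 <- p1$S[train_mask]; s2 <- p2$S[train_mask]
        kl <- 0.5 * sum((d1 - d2) * (s1 - s2)) / nm # symmetric Bernoulli KL
        loss <- 0.5 * (p1$loss + p2$loss) + w * kl
        cons1 <- matrix(0, nrow(A), ncol(A))
        cons1[train_mask] <- 0.5 * (d1 * (1 - d1) * (s1 - s2) + (d1 - d2)) / nm
        cons2 <- matrix(0, nrow(A), ncol(A))
        cons2[train_mask] <- 0.5 * (d2 * (1 - d2) * (s2 - s1) + (d2 - d1)) / nm
        g1 <- backward_from(p1, 0.5 * dS1 + w * cons1)
        g2 <- backward_from(p2, 0.5 * dS2 + w * cons2)
        grads <- mapply(function(a, b) a + b, g1, g2[names(g1)],
                        SIMPLIFY = FALSE)
      } else {
        grads <- backward_from(p1, dS1)
      }
      params <- adam_step(opt, params, grads)
      loss_history[epoch] <- loss
    }
  })
  structure(list(params = params, epoch = config$epochs,
                 loss_history = loss_history, lambda = lambda,
                 config = config),
            class = "ogn_state")
}

#' @export
print.ogn_state <- function(x, ...) {
  cat(sprintf("ogn_state: %d epochs, lambda = %.3f, final loss %.5f\n",
              x$epoch, x$lambda, utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Score all pairs with a trained model
#'
#' Evaluation-mode forward pass (no dropout, gate reset to zero), hence
#' deterministic: repeated calls give bit-identical scores.
#'
#' @param state an `"ogn_state"` from [train_model()].
#' @param network the `"heterogeneous_network"` to score.
#' @return Nd x Nm score matrix in (0, 1) with entity dimnames.
#' @export
predict_scores <- function(state, network) {
  cfg <- state$config
  emb <- encode(network$H, network$H_init, state$params, Nd = network$Nd,
                gate_mode = gate_mode_of(cfg),
                fixed_gate = fixed_gate_of(cfg))
  S <- decode(emb$h_d, emb$h_m, state$params$W_B)
  dimnames(S) <- list(network$drug_ids, network$microbe_ids)
  S
}

# --- Adam optimiser (decoupled from the model; operates on the flat
#     named parameter list) -------------------------------------------------

adam_new <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps; e$t <- 0
  e$m <- lapply(params, function(p) p * 0)
  e$v <- e$m
  e
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next # parameters unused by this model variant
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    step <- opt$lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + opt$eps)
    params[[nm]] <- params[[nm]] - step
  }
  params
}

# --- checkpointing ---------------------------------------------------------

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  f <- tempfile(); writeLines(s, f); on.exit(unlink(f))
  unname(tools::md5sum(f))
}

#' Save a trained model as a JSON checkpoint
#'
#' Parameters are serialised with shape metadata and a hash of the
#' configuration, so a checkpoint can be validated before reuse. Plain
#' text, full precision.
#' @param state an `"ogn_state"`.
#' @param path output `.json` path.
#' @export
save_checkpoint <- function(state, path) {
  p <- state$params
  ser <- lapply(p, function(x) list(dim = dim(as.array(x)),
                                    data = as.numeric(x)))
  obj <- list(format = "ordlink-checkpoint-1",
              meta = list(n_nodes = attr(p, "n_nodes"), k = attr(p, "k"),
                          L_conv = attr(p, "L_conv")),
              config = unclass(state$config),
              config_hash = config_hash(state$config),
              lambda = state$lambda, epoch = state$epoch,
              loss_history = state$loss_history, params = ser)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a JSON checkpoint
#' @param path checkpoint written by [save_checkpoint()].
#' @return an `"ogn_state"`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ordlink-checkpoint-1"))
    stop_input("not an ordlink checkpoint: %s", path)
  params <- lapply(obj$params, function(x) {
    if (length(x$dim) == 2) matrix(x$data, x$dim[1], x$dim[2]) else x$data
  })
  attr(params, "n_nodes") <- obj$meta$n_nodes
  attr(params, "k") <- obj$meta$k
  attr(params, "L_conv") <- obj$meta$L_conv
  class(params) <- "ogn_parameters"
  config <- do.call(ogn_config, obj$config)
  if (!identical(config_hash(config), obj$config_hash))
    warning("checkpoint config hash mismatch; file may have been edited")
  structure(list(params = params, epoch = obj$epoch,
                 loss_history = obj$loss_history, lambda = obj$lambda,
                 config = config),
            class = "ogn_state")
}
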