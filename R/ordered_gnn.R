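# The model core: two-layer MLP initial embedding, L_conv ordered
# message-passing layers, bilinear decoder and weighted cross-entropy
# loss. Everything is a pure function of (parameters, inputs), dense and
# full-batch; the analytic backward pass lives at the bottom of this file
# and is verified against finite differences in the test suite.
#
# Ordered message passing counters over-smoothing in deep GNNs: each node
# carries a monotone gate vector g in [0,1]^k whose reversed-cumsum shape
# (1 = frozen) progressively freezes low-index features, so early-layer
# (near-neighbourhood) information survives many rounds of aggregation.

#' Initialise model parameters
#'
#' Weights are Xavier-uniform (bound `sqrt(6/(fan_in+fan_out))` per
#' tensor), biases zero, layer-norm gains one and offsets zero. The same
#' seed yields bit-identical parameters.
#'
#' @param n_nodes total node count (drugs + microbes).
#' @param k embedding dimension (>= 2).
#' @param L_conv number of message-passing layers (>= 1).
#' @param seed integer RNG seed.
#' @return an `"ogn_parameters"` list: `W_fc1` (n x k), `B_fc1`, `W_fc2`
#'   (k x k), `B_fc2`, per layer `W_g` (2k x k), `B_g`, `ln_gain`,
#'   `ln_offset`, and the bilinear `W_B` (k x k).
#' @export
init_parameters <- function(n_nodes, k, L_conv, seed = 1L) {
  if (k < 2) stop_input("embedding dimension k must be >= 2")
  if (L_conv < 1) stop_input("L_conv must be >= 1")
  xavier <- function(nin, nout) {
    b <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -b, b), nin, nout)
  }
  with_seed(seed, {
    p <- list(W_fc1 = xavier(n_nodes, k), B_fc1 = numeric(k),
              W_fc2 = xavier(k, k), B_fc2 = numeric(k))
    for (l in seq_len(L_conv)) {
      p[[paste0("W_g_", l)]] <- xavier(2 * k, k)
      p[[paste0("B_g_", l)]] <- numeric(k)
      p[[paste0("ln_gain_", l)]] <- rep(1, k)
      p[[paste0("ln_offset_", l)]] <- numeric(k)
    }
    p$W_B <- xavier(k, k)
    structure(p, n_nodes = n_nodes, k = k, L_conv = L_conv,
              class = "ogn_parameters")
  })
}

#' @export
print.ogn_parameters <- function(x, ...) {
  cat(sprintf("ogn_parameters: %d nodes, k = %d, L_conv = %d (%d trainable values)\n",
              attr(x, "n_nodes"), attr(x, "k"), attr(x, "L_conv"),
              sum(vapply(x, length, 1L))))
  invisible(x)
}

#' Initial node embedding via a two-layer MLP
#'
#' `h0 = ReLU(ReLU(H_init W_fc1 + B_fc1) W_fc2 + B_fc2)`; rows of `H_init`
#' (the zero-diagonal-block association matrix) are the raw node features.
#'
#' @param H_init (Nd+Nm) square matrix, `[[0, A], [A', 0]]`.
#' @param params an `"ogn_parameters"` object.
#' @return (Nd+Nm) x k non-negative embedding matrix.
#' @export
encode_initial <- function(H_init, params) {
  if (any(!is.finite(H_init))) stop_input("non-finite entries in H_init")
  a1 <- sweep(H_init %*% params$W_fc1, 2, params$B_fc1, "+")
  r1 <- pmax(a1, 0)
  a2 <- sweep(r1 %*% params$W_fc2, 2, params$B_fc2, "+")
  pmax(a2, 0)
}

#' Mean-aggregate neighbour messages over the weighted graph
#'
#' Each node receives the weighted mean of its neighbours' embeddings,
#' with the edge values of `H` as weights:
#' `m[v] = sum_u H[v,u] h[u] / sum_u H[v,u]`; a zero row (isolated node)
#' yields a zero message.
#'
#' @param h node embedding matrix (n x k).
#' @param H non-negative weighted adjacency (n x n).
#' @return message matrix (n x k).
#' @export
aggregate_messages <- function(h, H) {
  if (any(H < 0)) stop_input("negative edge weights in H")
  rs <- rowSums(H)
  W <- H / ifelse(rs > 0, rs, 1)
  W[rs == 0, ] <- 0
  W %*% h
}

# row-normalised aggregation operator, precomputed once per training run
agg_operator <- function(H) {
  if (any(H < 0)) stop_input("negative edge weights in H")
  rs <- rowSums(H)
  W <- H / ifelse(rs > 0, rs, 1)
  W[rs == 0, ] <- 0
  W
}

#' One gate update
#'
#' Per node: logits are a biased linear projection of the concatenated
#' previous embedding and incoming message, `z = [h_prev; m] W_g + B_g`;
#' `p = softmax(z)` over the k feature positions is the split-point
#' distribution; the predicted gate is its reversed cumulative sum
#' `g_hat[j] = sum_{i >= j} p[i]` (so `g_hat[1] = 1` and rows are
#' non-increasing); and the accumulated gate is the monotone update
#' `g = g_prev + (1 - g_prev) * g_hat`.
#'
#' @param h_prev previous embeddings (n x k).
#' @param m aggregated messages (n x k).
#' @param W_g 2k x k gate projection.
#' @param B_g length-k gate bias.
#' @param g_prev previous accumulated gate (n x k), entries in \[0, 1\].
#' @return list with `g_hat` and `g` (both n x k).
#' @export
compute_gate <- function(h_prev, m, W_g, B_g, g_prev) {
  if (any(g_prev < -1e-8 | g_prev > 1 + 1e-8))
    stop_input("g_prev entries must lie in [0, 1]")
  g_prev <- clamp(g_prev, 0, 1)
  z <- sweep(cbind(h_prev, m) %*% W_g, 2, B_g, "+")
  p <- row_softmax(z)
  g_hat <- row_revcumsum(p)
  # round-off in the cumulative sum can overshoot 1 by an ulp
  g <- clamp(g_prev + (1 - g_prev) * g_hat, 0, 1)
  list(g_hat = g_hat, g = g)
}

#' Gated node update with layer normalisation
#'
#' `h = LN(g * h_prev + (1 - g) * m)` element-wise, where LN normalises
#' each node row to zero mean / unit standard deviation (eps 1e-5) and
#' applies a learnable per-feature gain and offset.
#'
#' @param h_prev previous embeddings (n x k).
#' @param m aggregated messages (n x k).
#' @param g gate matrix (n x k).
#' @param ln_gain,ln_offset length-k layer-norm affine parameters.
#' @return updated embeddings (n x k).
#' @export
update_nodes <- function(h_prev, m, g, ln_gain, ln_offset) {
  u <- g * h_prev + (1 - g) * m
  layer_norm(u, ln_gain, ln_offset)$h
}

ln_eps <- 1e-5

layer_norm <- function(u, gain, offset) {
  mu <- rowMeans(u)
  v <- u - mu
  sd <- sqrt(rowMeans(v^2) + ln_eps)
  xhat <- v / sd
  list(h = sweep(xhat * rep(gain, each = nrow(u)), 2, offset, "+"),
       xhat = xhat, sd = sd)
}

#' Run the full encoder
#'
#' Computes the initial MLP embedding then applies `L_conv` ordered
#' message-passing layers (aggregate, gate, gated layer-normalised
#' update). The accumulated gate starts at zero on every forward pass, so
#' evaluation is independent of training history. During training
#' (`dropout` supplied and `training = TRUE`) node dropout zeroes whole
#' message rows at rate `beta` and feature dropout zeroes embedding
#' entries at rate `gamma`, each rescaled by 1/(1 - rate).
#'
#' @param H weighted heterogeneous adjacency ((Nd+Nm) square).
#' @param H_init initial feature matrix (same shape).
#' @param params `"ogn_parameters"`.
#' @param L_conv number of layers to run (default: all of `params`).
#' @param Nd number of drug nodes (first `Nd` rows are the drug block).
#' @param gate_mode `"ordered"` for the full model, `"fixed"` for the
#'   ablation baseline whose gate is frozen at `fixed_gate` (no gate
#'   parameters are used).
#' @param fixed_gate gate value for `gate_mode = "fixed"` (0.5 blends self
#'   and message 1:1; 0 is the pure-message variant).
#' @param dropout optional list `(node = beta, feature = gamma)`;
#'   only applied when `training = TRUE`.
#' @param training logical; dropout masks are drawn from the current RNG
#'   stream only in training mode.
#' @return list with `h_d` (Nd x k), `h_m` (Nm x k), `h` (all rows) and
#'   `gates` (per-layer mean accumulated gate, a diagnostic of the
#'   ordering behaviour).
#' @export
encode <- function(H, H_init, params, L_conv = attr(params, "L_conv"),
                   Nd, gate_mode = c("ordered", "fixed"), fixed_gate = 0.5,
                   dropout = NULL, training = FALSE) {
  gate_mode <- match.arg(gate_mode)
  fw <- ogn_forward(agg_operator(H), H_init, params, L_conv = L_conv,
                    gate_mode = gate_mode, fixed_gate = fixed_gate,
                    dropout = dropout, training = training,
                    keep_cache = FALSE)
  h <- fw$h
  list(h_d = h[seq_len(Nd), , drop = FALSE],
       h_m = h[-seq_len(Nd), , drop = FALSE],
       h = h, gates = fw$gate_means)
}

#' Bilinear decoder
#'
#' Scores every (drug, microbe) pair through a learnable interaction
#' matrix: `A' = sigmoid(h_d W_B h_m')`.
#'
#' @param h_d drug embeddings (Nd x k).
#' @param h_m microbe embeddings (Nm x k).
#' @param W_B k x k bilinear weight.
#' @return Nd x Nm score matrix with entries in (0, 1).
#' @export
decode <- function(h_d, h_m, W_B) {
  sigmoid(h_d %*% W_B %*% t(h_m))
}

#' Weighted cross-entropy reconstruction loss
#'
#' `L = -(1/(Nd*Nm)) * (lambda * sum_{pos} log a' + sum_{neg} log(1-a'))`
#' over the masked-in pairs, where `lambda` balances the scarce positives
#' against the abundant negatives (typically `|neg| / |pos|`). Scores are
#' clamped to `[1e-7, 1 - 1e-7]` so the loss is always finite.
#'
#' @param A_prime score matrix in (0, 1).
#' @param A_train binary matrix of the same shape.
#' @param train_mask logical matrix; `FALSE` entries (held-out test pairs)
#'   contribute nothing.
#' @param lambda positive balance factor.
#' @return scalar loss.
#' @export
weighted_bce_loss <- function(A_prime, A_train,
                              train_mask = NULL, lambda = 1) {
  if (lambda <= 0) stop_input("lambda must be positive")
  A <- unclass_matrix(A_train)
  P <- clamp(unclass_matrix(A_prime), 1e-7, 1 - 1e-7)
  if (is.null(train_mask)) train_mask <- array(TRUE, dim(A))
  pos <- train_mask & A == 1
  neg <- train_mask & A == 0
  -(lambda * sum(log(P[pos])) + sum(log1p(-P[neg]))) / length(A)
}

# ---------------------------------------------------------------------------
# cached forward / analytic backward (internal)

ogn_forward <- function(Wagg, H_init, params,
                        L_conv = attr(params, "L_conv"),
                        gate_mode = "ordered", fixed_gate = 0.5,
                        dropout = NULL, training = FALSE,
                        keep_cache = TRUE) {
  n <- nrow(H_init); k <- attr(params, "k")
  beta <- if (training && !is.null(dropout)) dropout$node else 0
  gam <- if (training && !is.null(dropout)) dropout$feature else 0
  if (is.null(beta)) beta <- 0
  if (is.null(gam)) gam <- 0

  a1 <- sweep(H_init %*% params$W_fc1, 2, params$B_fc1, "+")
  r1 <- pmax(a1, 0)
  a2 <- sweep(r1 %*% params$W_fc2, 2, params$B_fc2, "+")
  h <- pmax(a2, 0)

  g <- matrix(0, n, k) # gate resets at the start of every forward pass
  layers <- vector("list", L_conv)
  gate_means <- numeric(L_conv)
  for (l in seq_len(L_conv)) {
    h_prev <- h
    m_raw <- Wagg %*% h_prev
    node_mask <- NULL
    m <- m_raw
    if (beta > 0) {
      node_mask <- stats::rbinom(n, 1, 1 - beta) / (1 - beta)
      m <- m_raw * node_mask
    }
    g_prev <- g
    if (gate_mode == "ordered") {
      z <- sweep(cbind(h_prev, m) %*% params[[paste0("W_g_", l)]],
                 2, params[[paste0("B_g_", l)]], "+")
      p <- row_softmax(z)
      g_hat <- row_revcumsum(p)
      g <- clamp(g_prev + (1 - g_prev) * g_hat, 0, 1)
    } else {
      p <- NULL; g_hat <- NULL
      g <- matrix(fixed_gate, n, k)
    }
    u <- g * h_prev + (1 - g) * m
    ln <- layer_norm(u, params[[paste0("ln_gain_", l)]],
                     params[[paste0("ln_offset_", l)]])
    h <- ln$h
    feat_mask <- NULL
    if (gam > 0) {
      feat_mask <- matrix(stats::rbinom(n * k, 1, 1 - gam), n, k) / (1 - gam)
      h <- h * feat_mask
    }
    gate_means[l] <- mean(g)
    if (keep_cache)
      layers[[l]] <- list(h_prev = h_prev, node_mask = node_mask, m = m,
                          p = p, g_hat = g_hat, g_prev = g_prev, g = g,
                          xhat = ln$xhat, sd = ln$sd, feat_mask = feat_mask)
  }
  out <- list(h = h, gate_means = gate_means)
  if (keep_cache) {
    out$cache <- list(H_init = H_init, a1 = a1, r1 = r1, a2 = a2,
                      layers = layers, Wagg = Wagg, L_conv = L_conv,
                      gate_mode = gate_mode)
  }
  out
}

# Backpropagate d(loss)/d(final h) through the encoder; returns the
# gradient list aligned with the parameter list.
ogn_backward <- function(fw, params, dh) {
  cache <- fw$cache
  k <- attr(params, "k")
  grads <- list()
  dg_carry <- NULL # gradient w.r.t. this layer's accumulated gate from above
  for (l in rev(seq_len(cache$L_conv))) {
    ly <- cache$layers[[l]]
    if (!is.null(ly$feat_mask)) dh <- dh * ly$feat_mask
    # layer norm backward
    gain <- params[[paste0("ln_gain_", l)]]
    dgain <- colSums(dh * ly$xhat)
    doff <- colSums(dh)
    dxhat <- dh * rep(gain, each = nrow(dh))
    du <- (dxhat - rowMeans(dxhat) - ly$xhat * rowMeans(dxhat * ly$xhat)) / ly$sd
    grads[[paste0("ln_gain_", l)]] <- dgain
    grads[[paste0("ln_offset_", l)]] <- doff
    # u = g*h_prev + (1-g)*m
    dg <- du * (ly$h_prev - ly$m)
    if (!is.null(dg_carry)) dg <- dg + dg_carry
    dh_prev <- du * ly$g
    dm <- du * (1 - ly$g)
    if (cache$gate_mode == "ordered") {
      # g = g_prev + (1-g_prev) * g_hat
      dghat <- dg * (1 - ly$g_prev)
      dg_carry <- if (l > 1) dg * (1 - ly$g_hat) else NULL
      # g_hat = reversed cumsum of p  =>  dp = forward cumsum of dghat
      dp <- row_cumsum(dghat)
      dz <- ly$p * (dp - rowSums(ly$p * dp))
      W_g <- params[[paste0("W_g_", l)]]
      grads[[paste0("W_g_", l)]] <- crossprod(cbind(ly$h_prev, ly$m), dz)
      grads[[paste0("B_g_", l)]] <- colSums(dz)
      dcat <- dz %*% t(W_g)
      dh_prev <- dh_prev + dcat[, seq_len(k), drop = FALSE]
      dm <- dm + dcat[, k + seq_len(k), drop = FALSE]
    } else {
      dg_carry <- NULL
    }
    # node dropout then aggregation backward
    if (!is.null(ly$node_mask)) dm <- dm * ly$node_mask
    dh <- dh_prev + crossprod(cache$Wagg, dm)
  }
  # MLP backward
  da2 <- dh * (cache$a2 > 0)
  grads$W_fc2 <- crossprod(cache$r1, da2)
  grads$B_fc2 <- colSums(da2)
  dr1 <- da2 %*% t(params$W_fc2)
  da1 <- dr1 * (cache$a1 > 0)
  grads$W_fc1 <- crossprod(cache$H_init, da1)
  grads$B_fc1 <- colSums(da1)
  grads
}

# gradient of the masked weighted BCE w.r.t. the pre-sigmoid scores
bce_score_grad <- function(P, A, train_mask, lambda) {
  G <- matrix(0, nrow(A), ncol(A))
  pos <- train_mask & A == 1
  neg <- train_mask & A == 0
  G[pos] <- -lambda * (1 - P[pos])
  G[neg] <- P[neg]
  G / length(A)
}
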