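# Fixture builders and independent brute-force oracle implementations.
# The oracles are deliberately naive (explicit per-node / per-pair loops)
# and share no code with the package internals they check.

make_assoc <- function(Nd, Nm, density = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(rbinom(Nd * Nm, 1, density), Nd, Nm)
  if (sum(A) == 0) A[1, 1] <- 1
  association_matrix(A, sprintf("d%d", 1:Nd), sprintf("m%d", 1:Nm))
}

random_params <- function(n, k, L, seed = 1) {
  init_parameters(n, k, L, seed = seed)
}

# straight-line reference encoder: per-node loops, no matrix tricks
reference_encode <- function(H, H_init, params, L_conv, Nd) {
  n <- nrow(H_init); k <- attr(params, "k")
  relu <- function(x) ifelse(x > 0, x, 0)
  h <- matrix(0, n, k)
  for (v in 1:n) {
    a1 <- as.numeric(H_init[v, ] %*% params$W_fc1) + params$B_fc1
    a2 <- as.numeric(relu(a1) %*% params$W_fc2) + params$B_fc2
    h[v, ] <- relu(a2)
  }
  g <- matrix(0, n, k)
  for (l in seq_len(L_conv)) {
    m <- matrix(0, n, k)
    for (v in 1:n) {
      w <- H[v, ]
      if (sum(w) > 0) {
        acc <- rep(0, k)
        for (u in 1:n) acc <- acc + w[u] * h[u, ]
        m[v, ] <- acc / sum(w)
      }
    }
    h_new <- matrix(0, n, k)
    g_new <- matrix(0, n, k)
    for (v in 1:n) {
      z <- as.numeric(c(h[v, ], m[v, ]) %*% params[[paste0("W_g_", l)]]) +
        params[[paste0("B_g_", l)]]
      p <- exp(z - max(z)); p <- p / sum(p)
      ghat <- rev(cumsum(rev(p)))
      gv <- g[v, ] + (1 - g[v, ]) * ghat
      u_ <- gv * h[v, ] + (1 - gv) * m[v, ]
      mu <- mean(u_); sdv <- sqrt(mean((u_ - mu)^2) + 1e-5)
      h_new[v, ] <- ((u_ - mu) / sdv) * params[[paste0("ln_gain_", l)]] +
        params[[paste0("ln_offset_", l)]]
      g_new[v, ] <- gv
    }
    h <- h_new; g <- g_new
  }
  list(h_d = h[1:Nd, , drop = FALSE], h_m = h[-(1:Nd), , drop = FALSE],
       g = g)
}

# per-pair loop decoder
reference_decode <- function(h_d, h_m, W_B) {
  out <- matrix(0, nrow(h_d), nrow(h_m))
  for (i in seq_len(nrow(h_d)))
    for (j in seq_len(nrow(h_m)))
      out[i, j] <- 1 / (1 + exp(-sum(h_d[i, ] * (W_B %*% h_m[j, ]))))
  out
}

# exhaustive pairwise AUROC: ties count 1/2
reference_auroc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1
    else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# PR step curve walked threshold by threshold
reference_aupr <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0; prev_recall <- 0
  for (t in ths) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / n_pos
    area <- area + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  area
}
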