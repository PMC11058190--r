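test_that("parameter initialisation is seeded, bounded and shaped", {
  p1 <- init_parameters(10, 4, 3, seed = 11)
  p2 <- init_parameters(10, 4, 3, seed = 11)
  expect_identical(p1, p2)
  p3 <- init_parameters(10, 4, 3, seed = 12)
  expect_false(identical(p1$W_fc1, p3$W_fc1))
  expect_lte(max(abs(p1$W_fc1)), sqrt(6 / (10 + 4)))
  expect_equal(dim(p1$W_g_2), c(8, 4))
  expect_equal(p1$B_fc1, numeric(4))
  expect_equal(p1$ln_gain_1, rep(1, 4))
  expect_error(init_parameters(10, 1, 3), "k")
  expect_error(init_parameters(10, 4, 0), "L_conv")
})

test_that("the initial MLP embedding follows the two-layer ReLU form", {
  # 1-node toy: ReLU(ReLU(1*2 - 1) * 1 + 0) = 1
  p <- init_parameters(2, 2, 1, seed = 1)
  p$W_fc1 <- matrix(c(2, 0, 0, 0), 2, 2); p$B_fc1 <- c(-1, 0)
  p$W_fc2 <- diag(2); p$B_fc2 <- c(0, 0)
  h0 <- encode_initial(rbind(c(1, 0), c(0, 0)), p)
  expect_equal(h0[1, 1], 1)
  # zero input and zero biases give zero output; ReLU keeps things >= 0
  expect_true(all(encode_initial(matrix(0, 2, 2), p) == 0))
  pr <- init_parameters(6, 3, 1, seed = 3)
  expect_gte(min(encode_initial(matrix(rnorm(36), 6), pr)), 0)
  expect_error(encode_initial(matrix(NaN, 2, 2), p), "finite")
})

test_that("message aggregation is the edge-weighted neighbour mean", {
  h <- rbind(c(2, 0), c(4, 2))
  H <- rbind(c(0, 1), c(1, 0))
  expect_equal(aggregate_messages(h, H), rbind(c(4, 2), c(2, 0)))
  # weighted mean: m0 = (1*h1 + 3*h2) / 4
  h3 <- rbind(c(0, 0), c(1, 1), c(5, 9))
  H3 <- rbind(c(0, 1, 3), c(1, 0, 0), c(3, 0, 0))
  expect_equal(aggregate_messages(h3, H3)[1, ],
               (1 * h3[2, ] + 3 * h3[3, ]) / 4)
  # isolated node receives the zero message
  H0 <- rbind(c(0, 0), c(0, 1))
  expect_equal(aggregate_messages(h, H0)[1, ], c(0, 0))
  expect_error(aggregate_messages(h, -H), "negative")
})

test_that("gate prediction is the reversed cumsum of a softmax with monotone accumulation", {
  k <- 4
  h <- matrix(0, 1, k); m <- matrix(0, 1, k)
  W_g <- matrix(0, 2 * k, k); B_g <- rep(0, k) # uniform logits
  out <- compute_gate(h, m, W_g, B_g, matrix(0, 1, k))
  expect_equal(out$g_hat[1, ], c(1, 0.75, 0.5, 0.25))
  expect_equal(out$g, out$g_hat) # g_prev = 0 passes g_hat through
  # saturated gate is a fixed point
  ones <- matrix(1, 1, k)
  expect_equal(compute_gate(h, m, W_g, B_g, ones)$g, ones)
  # element-wise monotone update
  gp <- matrix(c(1, 0.5, 0, 0.25), 1)
  out2 <- compute_gate(h, m, W_g, B_g, gp)
  expect_equal(out2$g, gp + (1 - gp) * out2$g_hat)
  expect_error(compute_gate(h, m, W_g, B_g, matrix(2, 1, k)), "g_prev")
})

test_that("node update blends by the gate and layer-normalises each row", {
  k <- 2
  h_prev <- matrix(c(3, 1), 1); m <- matrix(c(1, 3), 1)
  gain <- rep(1, k); off <- rep(0, k)
  # g = 1 keeps the self representation; g = 0 keeps the message
  expect_equal(update_nodes(h_prev, m, matrix(1, 1, k), gain, off),
               update_nodes(h_prev, h_prev, matrix(0, 1, k), gain, off))
  # constant pre-LN row normalises to (offset) zero
  out <- update_nodes(matrix(c(2, 0), 1), matrix(c(0, 2), 1),
                      matrix(0.5, 1, k), gain, off)
  expect_equal(out, matrix(0, 1, k))
  # affine parameters rescale and shift
  out2 <- update_nodes(h_prev, m, matrix(1, 1, k), c(2, 2), c(1, 1))
  base <- update_nodes(h_prev, m, matrix(1, 1, k), gain, off)
  expect_equal(out2, base * 2 + 1)
})

test_that("encoder and decoder match straight-line reference implementations", {
  for (seed in 1:6) {
    set.seed(seed)
    Nd <- sample(3:10, 1); Nm <- sample(2:8, 1)
    k <- sample(3:8, 1); L <- sample(1:4, 1)
    A <- make_assoc(Nd, Nm, density = 0.35, seed = seed)
    net <- prepare_fold_inputs(A)
    params <- init_parameters(Nd + Nm, k, L, seed = seed + 100)
    got <- encode(net$H, net$H_init, params, L_conv = L, Nd = Nd)
    ref <- reference_encode(net$H, net$H_init, params, L, Nd)
    expect_equal(got$h_d, ref$h_d, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(got$h_m, ref$h_m, tolerance = 1e-6, ignore_attr = TRUE)
    S <- decode(got$h_d, got$h_m, params$W_B)
    expect_equal(S, reference_decode(got$h_d, got$h_m, params$W_B),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_true(all(S > 0 & S < 1))
  }
})

test_that("decoder reproduces hand values and the sigmoid null", {
  h_d <- matrix(c(1, 0), 1); h_m <- matrix(c(1, 0), 1)
  expect_equal(decode(h_d, h_m, diag(2))[1, 1], 1 / (1 + exp(-1)),
               tolerance = 1e-9)
  expect_equal(decode(h_d, h_m, matrix(0, 2, 2))[1, 1], 0.5)
})

test_that("evaluation-mode encoding is deterministic and resets the gate", {
  A <- make_assoc(5, 4, seed = 2)
  net <- prepare_fold_inputs(A)
  params <- init_parameters(9, 4, 3, seed = 7)
  e1 <- encode(net$H, net$H_init, params, Nd = 5)
  e2 <- encode(net$H, net$H_init, params, Nd = 5)
  expect_identical(e1, e2)
  # one layer: accumulated gate equals the predicted gate (g_prev = 0)
  e_l1 <- encode(net$H, net$H_init, params, L_conv = 1, Nd = 5)
  h0 <- encode_initial(net$H_init, params)
  m <- aggregate_messages(h0, net$H)
  gt <- compute_gate(h0, m, params$W_g_1, params$B_g_1,
                     matrix(0, 9, 4))
  expect_equal(e_l1$gates[1], mean(gt$g_hat))
})

test_that("a fixed-gate layer reduces to the plain mean-aggregation baseline", {
  A <- make_assoc(5, 4, seed = 8)
  net <- prepare_fold_inputs(A)
  params <- init_parameters(9, 4, 2, seed = 1)
  e <- encode(net$H, net$H_init, params, Nd = 5, gate_mode = "fixed",
              fixed_gate = 0.5)
  h <- encode_initial(net$H_init, params)
  for (l in 1:2) {
    m <- aggregate_messages(h, net$H)
    h <- update_nodes(h, m, matrix(0.5, 9, 4),
                      params[[paste0("ln_gain_", l)]],
                      params[[paste0("ln_offset_", l)]])
  }
  expect_equal(rbind(e$h_d, e$h_m), h, tolerance = 1e-12)
})

test_that("permuting node order permutes embeddings identically", {
  A <- make_assoc(6, 4, seed = 5)
  net <- prepare_fold_inputs(A)
  n <- 10; k <- 4
  params <- init_parameters(n, k, 2, seed = 3)
  e <- encode(net$H, net$H_init, params, Nd = 6)
  perm <- sample(n)
  params_p <- params
  params_p$W_fc1 <- params$W_fc1[perm, ] # row space follows the nodes
  Hp <- net$H[perm, perm]; Hip <- net$H_init[perm, perm]
  fw <- ordlink:::ogn_forward(ordlink:::agg_operator(Hp), Hip, params_p)
  expect_equal(fw$h, rbind(e$h_d, e$h_m)[perm, ], tolerance = 1e-9)
})

test_that("weighted cross-entropy matches hand values and clamps extremes", {
  A <- matrix(c(1, 0), 1, 2)
  P <- matrix(0.5, 1, 2)
  expect_equal(weighted_bce_loss(P, A, lambda = 1), log(2),
               tolerance = 1e-12)
  expect_equal(weighted_bce_loss(P, A, lambda = 3), 2 * log(2),
               tolerance = 1e-12)
  # perfect fit drives the loss to (clamped) zero
  P2 <- matrix(c(1 - 1e-12, 1e-12), 1, 2)
  expect_lt(weighted_bce_loss(P2, A, lambda = 1), 1e-5)
  expect_true(is.finite(weighted_bce_loss(matrix(c(1, 0), 1, 2), A)))
  # lambda = 1 equals the unweighted mean cross-entropy
  set.seed(1)
  P3 <- matrix(runif(12, 0.05, 0.95), 3, 4)
  A3 <- matrix(rbinom(12, 1, 0.5), 3, 4)
  expect_equal(weighted_bce_loss(P3, A3, lambda = 1),
               -mean(A3 * log(P3) + (1 - A3) * log(1 - P3)))
  # masked-out entries contribute nothing
  mask <- matrix(TRUE, 3, 4); mask[1, ] <- FALSE
  P4 <- P3; P4[1, ] <- 0.999
  expect_equal(weighted_bce_loss(P3, A3, mask, 2),
               weighted_bce_loss(P4, A3, mask, 2))
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(42)
  Nd <- 4; Nm <- 3; n <- 7; k <- 3; L <- 2
  A <- make_assoc(Nd, Nm, density = 0.4, seed = 6)
  net <- prepare_fold_inputs(A)
  params <- init_parameters(n, k, L, seed = 5)
  mask <- array(TRUE, dim(A)); mask[1, 1] <- FALSE
  lambda <- 2.5
  Am <- unclass(A)
  Wagg <- ordlink:::agg_operator(net$H)
  loss_fn <- function(p) {
    fw <- ordlink:::ogn_forward(Wagg, net$H_init, p, keep_cache = FALSE)
    h_d <- fw$h[1:Nd, , drop = FALSE]; h_m <- fw$h[-(1:Nd), , drop = FALSE]
    weighted_bce_loss(ordlink:::sigmoid(h_d %*% p$W_B %*% t(h_m)),
                      Am, mask, lambda)
  }
  fw <- ordlink:::ogn_forward(Wagg, net$H_init, params)
  h_d <- fw$h[1:Nd, , drop = FALSE]; h_m <- fw$h[-(1:Nd), , drop = FALSE]
  P <- ordlink:::sigmoid(h_d %*% params$W_B %*% t(h_m))
  dS <- ordlink:::bce_score_grad(P, Am, mask, lambda)
  grads <- c(list(W_B = crossprod(h_d, dS %*% h_m)),
             ordlink:::ogn_backward(fw, params,
                                    rbind(dS %*% h_m %*% t(params$W_B),
                                          crossprod(dS, h_d) %*% params$W_B)))
  eps <- 1e-6
  for (nm in names(params)) {
    num <- params[[nm]] * 0
    for (i in seq_along(num)) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num[i] <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
    }
    expect_lt(max(abs(grads[[nm]] - num)), 1e-6, label = nm)
  }
})
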