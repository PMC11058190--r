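# Similarity computation and heterogeneous-network assembly.
#
# Each entity class gets a Gaussian interaction profile (GIP) kernel
# similarity computed from the binary association matrix; where a curated
# similarity (drug chemical structure, microbe function) is available it
# is averaged with the kernel, and where it is absent (zero entries) the
# kernel alone is used. The fused similarities and the association matrix
# are then tiled into one square heterogeneous adjacency matrix over
# drugs-then-microbes.

#' Gaussian interaction profile kernel similarity
#'
#' For drugs, similarity between drugs i and j is
#' `exp(-gamma_d * ||A[i,] - A[j,]||^2)` where the bandwidth
#' `gamma_d = 1 / mean_i ||A[i,]||^2` is normalised by the average squared
#' interaction-profile norm; for microbes the column analogue. The result
#' is symmetric with unit diagonal and entries in (0, 1].
#'
#' @param A an [association_matrix()] with at least one known association.
#' @param axis `"drugs"` (row profiles) or `"microbes"` (column profiles).
#' @return a [similarity_matrix()] (DGS or MGS).
#' @examples
#' A <- association_matrix(diag(2), c("d1", "d2"), c("m1", "m2"))
#' gip_kernel(A, "drugs")["d1", "d2"] # exp(-2)
#' @export
gip_kernel <- function(A, axis = c("drugs", "microbes")) {
  axis <- match.arg(axis)
  P <- unclass_matrix(A)
  if (axis == "microbes") P <- t(P)
  ids <- rownames(P)
  sq <- rowSums(P^2)
  denom <- mean(sq)
  if (denom == 0)
    stop_input("all-zero association matrix: GIP bandwidth is undefined")
  gamma <- 1 / denom
  # squared Euclidean distance between all profile pairs
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0 # numerical guard
  S <- exp(-gamma * d2)
  diag(S) <- 1
  similarity_matrix(S, ids)
}

#' GIP kernel bandwidth
#'
#' The normalised bandwidth used by [gip_kernel()]:
#' `1 / ((1/N) * sum of squared profile norms)`.
#' @inheritParams gip_kernel
#' @return a positive scalar.
#' @export
gip_bandwidth <- function(A, axis = c("drugs", "microbes")) {
  axis <- match.arg(axis)
  P <- unclass_matrix(A)
  if (axis == "microbes") P <- t(P)
  denom <- mean(rowSums(P^2))
  if (denom == 0)
    stop_input("all-zero association matrix: GIP bandwidth is undefined")
  1 / denom
}

#' Fuse a curated similarity with the GIP kernel similarity
#'
#' Entry-wise: the arithmetic mean `(primary + gip) / 2` where the curated
#' similarity is non-zero, and the GIP value alone where it is zero (the
#' entity lacks curated information). The zero test is exact equality,
#' since curated values come from files, not computation.
#'
#' @param primary_sim curated [similarity_matrix()] (e.g. chemical
#'   structure or functional similarity), possibly with zero rows.
#' @param gip_sim the matching GIP kernel [similarity_matrix()].
#' @param counter optional environment; if supplied, fields `mean_branch`
#'   and `fallback_branch` receive the entry counts routed through each
#'   branch (diagnostic hook).
#' @return the integrated [similarity_matrix()] (DS or MS).
#' @export
integrate_similarity <- function(primary_sim, gip_sim, counter = NULL) {
  if (!identical(dim(primary_sim), dim(gip_sim)) ||
      !identical(rownames(primary_sim), rownames(gip_sim)))
    stop_input("similarity matrices must share shape and ID order")
  P <- unclass_matrix(primary_sim)
  G <- unclass_matrix(gip_sim)
  use_mean <- P != 0
  out <- ifelse(use_mean, (P + G) / 2, G)
  if (is.environment(counter)) {
    counter$mean_branch <- sum(use_mean)
    counter$fallback_branch <- sum(!use_mean)
  }
  similarity_matrix(out, rownames(primary_sim))
}

#' Assemble the heterogeneous drug-microbe network
#'
#' Tiles the fused drug similarity `DS`, fused microbe similarity `MS` and
#' the association matrix `A` into the square block matrix
#' `H = [[DS, A], [A', MS]]` over drugs-then-microbes, together with the
#' initial-feature matrix `H_init = [[0, A], [A', 0]]` fed to the MLP
#' embedding.
#'
#' @param DS drug [similarity_matrix()] (Nd x Nd).
#' @param MS microbe [similarity_matrix()] (Nm x Nm).
#' @param A [association_matrix()] (Nd x Nm) with matching IDs.
#' @return an object of class `"heterogeneous_network"`: list with `H`,
#'   `H_init`, `A`, `drug_ids`, `microbe_ids`, `Nd`, `Nm`.
#' @export
build_heterogeneous <- function(DS, MS, A) {
  Nd <- nrow(A); Nm <- ncol(A)
  if (!identical(dim(DS), c(Nd, Nd)))
    stop_input("DS must be %d x %d", Nd, Nd)
  if (!identical(dim(MS), c(Nm, Nm)))
    stop_input("MS must be %d x %d", Nm, Nm)
  if (!identical(rownames(DS), rownames(A)) ||
      !identical(rownames(MS), colnames(A)))
    stop_input("similarity IDs must match association IDs in order")
  Am <- unclass_matrix(A)
  H <- rbind(cbind(unclass_matrix(DS), Am),
             cbind(t(Am), unclass_matrix(MS)))
  H_init <- rbind(cbind(matrix(0, Nd, Nd), Am),
                  cbind(t(Am), matrix(0, Nm, Nm)))
  ids <- c(rownames(A), colnames(A))
  dimnames(H) <- dimnames(H_init) <- list(ids, ids)
  structure(list(H = H, H_init = H_init, A = A,
                 drug_ids = rownames(A), microbe_ids = colnames(A),
                 Nd = Nd, Nm = Nm),
            class = "heterogeneous_network")
}

#' @export
print.heterogeneous_network <- function(x, ...) {
  cat(sprintf("heterogeneous_network: %d drugs + %d microbes (%d nodes), %d associations\n",
              x$Nd, x$Nm, x$Nd + x$Nm, sum(x$A)))
  invisible(x)
}

#' Build the heterogeneous network for one cross-validation fold
#'
#' Zeroes the held-out positive pairs out of the association matrix, then
#' recomputes similarities and assembles the network from the masked
#' matrix. With `leakage_safe = TRUE` (default) the GIP kernels are
#' recomputed from the masked matrix so no held-out association can leak
#' into the fold's similarity structure; turning it off reproduces the
#' full-matrix kernel variant.
#'
#' @param A_full the complete [association_matrix()].
#' @param heldout_pairs two-column integer matrix of (drug row, microbe
#'   column) indices, a subset of the known positives; may have zero rows.
#' @param DSS optional curated drug similarity; `NULL` means pure-GIP mode.
#' @param MFS optional curated microbe similarity; `NULL` means pure-GIP
#'   mode.
#' @param leakage_safe logical (default `TRUE`), see above.
#' @return a `"heterogeneous_network"` built from the masked matrix (its
#'   `A` field is the masked training matrix).
#' @export
prepare_fold_inputs <- function(A_full, heldout_pairs = NULL,
                                DSS = NULL, MFS = NULL,
                                leakage_safe = TRUE) {
  A_train <- unclass_matrix(A_full)
  if (!is.null(heldout_pairs) && nrow(heldout_pairs)) {
    heldout_pairs <- as.matrix(heldout_pairs)[, 1:2, drop = FALSE]
    if (any(A_train[heldout_pairs] != 1))
      stop_input("held-out pairs must be known positives of the full matrix")
    A_train[heldout_pairs] <- 0
  }
  A_train <- association_matrix(A_train, rownames(A_full), colnames(A_full))
  A_kern <- if (leakage_safe) A_train else A_full
  DGS <- gip_kernel(A_kern, "drugs")
  MGS <- gip_kernel(A_kern, "microbes")
  DS <- if (is.null(DSS)) DGS else integrate_similarity(DSS, DGS)
  MS <- if (is.null(MFS)) MGS else integrate_similarity(MFS, MGS)
  build_heterogeneous(DS, MS, A_train)
}
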