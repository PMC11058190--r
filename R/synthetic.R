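# Synthetic bipartite association worlds. The generator emulates the
# statistical shape of curated microbe-drug datasets: a sparse binary
# association matrix with planted low-rank structure, plus noisy side
# similarities in which a fraction of entities has no information at all
# (zero rows), exercising the GIP-only fallback of similarity fusion.

#' Generate a synthetic association world
#'
#' Latent drug and microbe factors are drawn from a spherical normal;
#' association probabilities are `sigmoid(s * <u_i, v_j> + b)` with the
#' scale fixed at `3 / sqrt(rank)` and the intercept solved by bisection
#' so the mean probability matches `target_density` (tolerance 1e-3).
#' The binary matrix is sampled entry-wise Bernoulli from those
#' probabilities. Side similarities are clipped cosine similarities of
#' the latent factors plus centred symmetric noise, unit diagonal, with a
#' `missing_fraction` of rows/columns zeroed (diagonal included) to mimic
#' entities whose structure or function was never curated.
#'
#' @param Nd,Nm numbers of drugs and microbes.
#' @param rank latent dimension of the planted structure (>= 1).
#' @param target_density mean association probability, in (0, 0.5).
#' @param similarity_noise standard-deviation scale of the noise added to
#'   the side similarities.
#' @param missing_fraction fraction of entities with zeroed similarity
#'   rows, in [0, 1).
#' @param seed integer seed; the same seed reproduces the world exactly.
#' @return an `"ogn_world"`: `A` ([association_matrix()]), `true_prob`,
#'   `DSS_like`, `MFS_like` ([similarity_matrix()]s), `latent_drug`,
#'   `latent_microbe`, `seed`.
#' @examples
#' w <- generate_world(Nd = 30, Nm = 12, rank = 3, target_density = 0.1,
#'                     seed = 1)
#' mean(w$A)
#' @export
generate_world <- function(Nd = 120L, Nm = 40L, rank = 4L,
                           target_density = 0.05,
                           similarity_noise = 0.1,
                           missing_fraction = 0.2, seed = 17L) {
  if (target_density <= 0 || target_density >= 0.5)
    stop_input("target_density must lie in (0, 0.5)")
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop_input("missing_fraction must lie in [0, 1)")
  if (rank < 1) stop_input("rank must be >= 1")
  drug_ids <- sprintf("d%03d", seq_len(Nd))
  microbe_ids <- sprintf("m%03d", seq_len(Nm))
  with_seed(seed, {
    U <- matrix(stats::rnorm(Nd * rank), Nd, rank)
    V <- matrix(stats::rnorm(Nm * rank), Nm, rank)
    s <- 3 / sqrt(rank)
    Z <- s * tcrossprod(U, V)
    # intercept via bisection on the mean probability
    lo <- -40; hi <- 40
    for (i in 1:80) {
      b <- (lo + hi) / 2
      if (mean(sigmoid(Z + b)) < target_density) lo <- b else hi <- b
      if (abs(mean(sigmoid(Z + b)) - target_density) < 1e-3) break
    }
    true_prob <- sigmoid(Z + b)
    A <- matrix(stats::rbinom(Nd * Nm, 1, true_prob), Nd, Nm)
    DSS <- noisy_cosine(U, similarity_noise)
    MFS <- noisy_cosine(V, similarity_noise)
    miss_d <- sample.int(Nd, floor(missing_fraction * Nd))
    miss_m <- sample.int(Nm, floor(missing_fraction * Nm))
    DSS[miss_d, ] <- 0; DSS[, miss_d] <- 0
    MFS[miss_m, ] <- 0; MFS[, miss_m] <- 0
  })
  dimnames(true_prob) <- list(drug_ids, microbe_ids)
  structure(list(A = association_matrix(A, drug_ids, microbe_ids),
                 true_prob = true_prob,
                 DSS_like = similarity_matrix(DSS, drug_ids),
                 MFS_like = similarity_matrix(MFS, microbe_ids),
                 latent_drug = U, latent_microbe = V,
                 seed = as.integer(seed)),
            class = "ogn_world")
}

# cosine similarity of row factors, clipped to [0,1], plus centred
# symmetric noise, re-clipped, unit diagonal
noisy_cosine <- function(X, noise) {
  nrm <- sqrt(rowSums(X^2))
  C <- tcrossprod(X / nrm)
  C <- clamp(C, 0, 1)
  if (noise > 0) {
    E <- matrix(stats::rnorm(nrow(X)^2, sd = noise), nrow(X))
    C <- clamp(C + (E + t(E)) / 2, 0, 1)
  }
  diag(C) <- 1
  C
}

#' @export
print.ogn_world <- function(x, ...) {
  cat(sprintf("ogn_world: %d drugs x %d microbes, density %.4f, seed %d\n",
              nrow(x$A), ncol(x$A), mean(x$A), x$seed))
  invisible(x)
}

#' Write a synthetic world to a directory of plain-text files
#'
#' Emits `assoc.tsv` (edge list), `drug_sim.tsv`, `microbe_sim.tsv`,
#' `true_prob.tsv` and `world.json` (scalar metadata).
#' @param world an `"ogn_world"`.
#' @param dir output directory, created if needed.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_association_edgelist(world$A, file.path(dir, "assoc.tsv"))
  write_dense_matrix(world$DSS_like, file.path(dir, "drug_sim.tsv"))
  write_dense_matrix(world$MFS_like, file.path(dir, "microbe_sim.tsv"))
  write_dense_matrix(world$true_prob, file.path(dir, "true_prob.tsv"))
  jsonlite::write_json(list(Nd = nrow(world$A), Nm = ncol(world$A),
                            density = mean(unclass_matrix(world$A)),
                            seed = world$seed),
                       file.path(dir, "world.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
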