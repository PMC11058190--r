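# Core data containers: binary association matrices and similarity
# matrices. Both are plain numeric matrices with dimnames plus a class
# tag; validation happens at construction so downstream code can assume
# the invariants.

#' Construct a drug-microbe association matrix
#'
#' A binary adjacency matrix `A` over drugs (rows) and microbes (columns):
#' `A[i, j] = 1` when drug i has a known interaction association with
#' microbe j and 0 otherwise. The orientation drugs = rows, microbes =
#' columns is fixed throughout the package.
#'
#' @param values numeric matrix with entries in \{0, 1\}.
#' @param drug_ids character vector of unique row identifiers; defaults to
#'   existing rownames.
#' @param microbe_ids character vector of unique column identifiers;
#'   defaults to existing colnames.
#' @return a matrix of class `"association_matrix"` with dimnames set.
#' @examples
#' A <- association_matrix(rbind(c(1, 0), c(0, 1)),
#'                         drug_ids = c("d1", "d2"),
#'                         microbe_ids = c("m1", "m2"))
#' @export
association_matrix <- function(values,
                               drug_ids = rownames(values),
                               microbe_ids = colnames(values)) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop_input("association matrix must have at least one drug and one microbe")
  if (is.null(drug_ids)) drug_ids <- paste0("d", seq_len(nrow(values)))
  if (is.null(microbe_ids)) microbe_ids <- paste0("m", seq_len(ncol(values)))
  drug_ids <- as.character(drug_ids)
  microbe_ids <- as.character(microbe_ids)
  if (anyDuplicated(drug_ids)) stop_input("duplicate drug ids")
  if (anyDuplicated(microbe_ids)) stop_input("duplicate microbe ids")
  if (length(drug_ids) != nrow(values) || length(microbe_ids) != ncol(values))
    stop_input("id lengths do not match matrix dimensions")
  if (!all(values %in% c(0, 1)))
    stop_input("association matrix entries must all be 0 or 1")
  storage.mode(values) <- "double"
  dimnames(values) <- list(drug_ids, microbe_ids)
  class(values) <- c("association_matrix", class(values))
  values
}

#' Construct a similarity matrix over one entity class
#'
#' A square symmetric matrix with entries in \[0, 1\]. Rows of all zeros are
#' legal and mean "no information for this entity" (they route through the
#' GIP-only fallback when similarities are integrated); on any non-zero
#' row the diagonal must be 1.
#'
#' @param values square numeric matrix.
#' @param ids character vector of unique identifiers; defaults to rownames.
#' @param tol symmetry tolerance (default 1e-8).
#' @return a matrix of class `"similarity_matrix"`.
#' @export
similarity_matrix <- function(values, ids = rownames(values), tol = 1e-8) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop_input("similarity matrix must be square")
  if (is.null(ids)) ids <- paste0("e", seq_len(nrow(values)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_input("duplicate ids in similarity matrix")
  if (length(ids) != nrow(values))
    stop_input("id length does not match matrix dimension")
  if (any(!is.finite(values))) stop_input("non-finite similarity entries")
  if (any(values < 0 | values > 1))
    stop_input("similarity entries must lie in [0, 1]")
  if (max(abs(values - t(values))) > tol)
    stop_input("similarity matrix is asymmetric beyond tolerance %g", tol)
  nz <- rowSums(values != 0) > 0
  bad <- which(nz & abs(diag(values) - 1) > tol)
  if (length(bad))
    stop_input("non-zero similarity row '%s' must have diagonal 1", ids[bad[1]])
  values <- (values + t(values)) / 2
  storage.mode(values) <- "double"
  dimnames(values) <- list(ids, ids)
  class(values) <- c("similarity_matrix", class(values))
  values
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("association_matrix: %d drugs x %d microbes, %d known associations (density %.4f)\n",
              nrow(x), ncol(x), sum(x), mean(x)))
  invisible(x)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  nzero <- sum(rowSums(x != 0) == 0)
  cat(sprintf("similarity_matrix: %d entities, %d zero (uninformative) rows\n",
              nrow(x), nzero))
  invisible(x)
}

# strip the class tag so arithmetic dispatch stays on base matrices
unclass_matrix <- function(x) {
  class(x) <- "matrix"
  x
}
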