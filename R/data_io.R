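# Tabular input/output. All external files are delimited text keyed by
# string IDs; internal indexing is 0-free (plain R matrices with dimnames).
# Default delimiter is tab, matching common bioinformatics exchange.

#' Read a drug-microbe association edge list
#'
#' Reads a two-column delimited table of `(drug_id, microbe_id)` pairs and
#' returns the corresponding binary association matrix. Duplicate pairs
#' collapse to a single 1. When ID vectors are not supplied they are
#' inferred from the file in first-appearance order.
#'
#' @param path path to the edge-list file.
#' @param drug_ids,microbe_ids optional duplicate-free ID vectors fixing the
#'   row/column universe and order; pairs referencing unknown IDs are an
#'   error.
#' @param delimiter field separator (default tab).
#' @param header `"auto"` (skip a first row that looks like column names),
#'   `TRUE` or `FALSE`.
#' @return an [association_matrix()].
#' @export
read_association_edgelist <- function(path, drug_ids = NULL,
                                      microbe_ids = NULL,
                                      delimiter = "\t",
                                      header = "auto") {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (file.size(path) == 0 || !any(nzchar(readLines(path, warn = FALSE))))
    stop_input("empty association edge list: %s", path)
  raw <- utils::read.table(path, sep = delimiter, header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", blank.lines.skip = TRUE)
  if (identical(header, "auto")) {
    header <- nrow(raw) > 0 &&
      all(tolower(unlist(raw[1, 1:2])) %in%
            c("drug_id", "microbe_id", "drug", "microbe"))
  }
  if (isTRUE(header)) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0) stop_input("empty association edge list: %s", path)
  if (ncol(raw) < 2) stop_input("edge list needs two columns: %s", path)
  d <- as.character(raw[[1]])
  m <- as.character(raw[[2]])
  if (!is.null(drug_ids)) {
    if (anyDuplicated(drug_ids)) stop_input("duplicate ids in drug_ids")
    bad <- which(!(d %in% drug_ids))
    if (length(bad))
      stop_input("row %d references unknown drug id '%s'", bad[1], d[bad[1]])
  } else drug_ids <- unique(d)
  if (!is.null(microbe_ids)) {
    if (anyDuplicated(microbe_ids)) stop_input("duplicate ids in microbe_ids")
    bad <- which(!(m %in% microbe_ids))
    if (length(bad))
      stop_input("row %d references unknown microbe id '%s'", bad[1], m[bad[1]])
  } else microbe_ids <- unique(m)
  A <- matrix(0, length(drug_ids), length(microbe_ids),
              dimnames = list(drug_ids, microbe_ids))
  A[cbind(match(d, drug_ids), match(m, microbe_ids))] <- 1
  association_matrix(A, drug_ids, microbe_ids)
}

#' Write an association matrix as an edge list
#'
#' Inverse of [read_association_edgelist()]: one `(drug_id, microbe_id)`
#' row per known association, with a header.
#' @param A an [association_matrix()].
#' @param path output path.
#' @param delimiter field separator (default tab).
#' @export
write_association_edgelist <- function(A, path, delimiter = "\t") {
  idx <- which(unclass_matrix(A) == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(drug_id = rownames(A)[idx[, 1]],
                   microbe_id = colnames(A)[idx[, 2]])
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# full-precision numeric formatting for exact text round-trips
format_full <- function(x) formatC(x, digits = 17, format = "g")

#' Read a dense named matrix (similarity or score matrix)
#'
#' Expects a header row of column IDs and a first column of row IDs. With
#' `validate = "similarity"` the matrix is additionally checked for
#' symmetry (tolerance 1e-8), range \[0, 1\] and unit diagonal on non-zero
#' rows, and returned as a [similarity_matrix()].
#'
#' @param path input path.
#' @param expected_ids optional ID vector; the matrix is reordered to it and
#'   any mismatch is an error.
#' @param delimiter field separator (default tab).
#' @param validate `"similarity"` (default) or `"none"` for plain dense
#'   matrices such as score grids.
#' @export
read_dense_matrix <- function(path, expected_ids = NULL, delimiter = "\t",
                              validate = c("similarity", "none")) {
  validate <- match.arg(validate)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, quote = "",
                          comment.char = "", row.names = 1)
  x <- as.matrix(df)
  if (!is.numeric(x)) stop_input("non-numeric matrix body in %s", path)
  if (!is.null(expected_ids)) {
    expected_ids <- as.character(expected_ids)
    if (!setequal(rownames(x), expected_ids) ||
        (validate == "similarity" && !setequal(colnames(x), expected_ids)))
      stop_input("ids in %s do not match the expected id set", path)
    x <- x[expected_ids, if (validate == "similarity") expected_ids else colnames(x),
           drop = FALSE]
  }
  if (validate == "similarity") similarity_matrix(x, rownames(x)) else x
}

#' Write a dense named matrix
#'
#' Header row of column IDs, first column of row IDs, full-precision
#' numbers so a write/read round trip is exact.
#' @param x numeric matrix with dimnames.
#' @param path output path.
#' @param delimiter field separator (default tab).
#' @export
write_dense_matrix <- function(x, path, delimiter = "\t") {
  body <- apply(unclass_matrix(x), c(1, 2), format_full)
  df <- data.frame(id = rownames(x), body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("id", colnames(x))
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Rank and write candidate (drug, microbe) pairs
#'
#' Writes the top-ranked *unknown* pairs (entries already 1 in `known` are
#' excluded) sorted by descending score, ties broken lexicographically by
#' `(drug_id, microbe_id)`. One global list plus one list per drug is
#' written, distinguished by a `scope` column; this mirrors the usual
#' candidate-screening read-out where the top-k microbes are inspected for
#' each drug of interest.
#'
#' @param scores numeric matrix of prediction scores, same dimnames as
#'   `known`.
#' @param known the [association_matrix()] of known pairs to exclude.
#' @param top_k positive integer, list length.
#' @param path output path.
#' @param delimiter field separator (default tab).
#' @return invisibly, the ranked table (also written to `path`).
#' @export
write_ranked_pairs <- function(scores, known, top_k, path, delimiter = "\t") {
  if (!is.numeric(top_k) || length(top_k) != 1 || top_k < 1)
    stop_input("top_k must be a positive integer")
  top_k <- as.integer(top_k)
  if (!identical(dimnames(scores), dimnames(known)))
    stop_input("scores and known associations must share ID sets")
  unknown <- which(unclass_matrix(known) == 0, arr.ind = TRUE)
  tab <- data.frame(drug_id = rownames(scores)[unknown[, 1]],
                    microbe_id = colnames(scores)[unknown[, 2]],
                    score = scores[unknown],
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$score, tab$drug_id, tab$microbe_id), , drop = FALSE]
  take <- function(df, scope) {
    df <- utils::head(df, top_k)
    if (nrow(df) == 0) return(NULL)
    data.frame(scope = scope, rank = seq_len(nrow(df)), df,
               stringsAsFactors = FALSE)
  }
  out <- take(tab, "global")
  for (d in rownames(scores)) {
    out <- rbind(out, take(tab[tab$drug_id == d, , drop = FALSE],
                           paste0("drug:", d)))
  }
  if (is.null(out))
    out <- data.frame(scope = character(), rank = integer(),
                      drug_id = character(), microbe_id = character(),
                      score = numeric())
  out$score <- format_full(out$score)
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(out)
}

#' Read a run configuration file (YAML or JSON)
#'
#' Fields mirror [ogn_config()]; unknown fields are an error so typos fail
#' loudly.
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return an `ogn_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else stop_input("config must be .yaml/.yml or .json: %s", path)
  do.call(ogn_config, vals)
}
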