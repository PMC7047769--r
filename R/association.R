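#' Build a binary lncRNA-disease association matrix from a pair table
#'
#' Converts a long table of verified lncRNA-disease links into the binary
#' matrix `Y` (rows = lncRNAs, columns = diseases) used throughout the
#' package, together with identifier registries. Duplicate pairs are merged;
#' identifier order is first-appearance order; identifiers are matched
#' case-sensitively after whitespace trimming.
#'
#' @param pairs A data frame whose first two columns are lncRNA and disease
#'   identifiers (column names `lncrna_id`, `disease_id` are used when
#'   present, otherwise the first two columns).
#' @return An object of class `lda_assoc`: a list with elements `Y` (binary
#'   p x q matrix with dimnames), `lncrna_ids` and `disease_ids`.
#' @examples
#' pairs <- tibble::tibble(
#'   lncrna_id  = c("H19", "H19", "MALAT1"),
#'   disease_id = c("breast cancer", "lung cancer", "lung cancer")
#' )
#' assoc <- as_association_matrix(pairs)
#' assoc$Y
#' @export
as_association_matrix <- function(pairs) {
  if (inherits(pairs, "lda_assoc")) {
    return(pairs)
  }
  if (!is.data.frame(pairs) || ncol(pairs) < 2) {
    rlang::abort("`pairs` must be a data frame with at least two columns.",
      class = "mcglda_error_input")
  }
  cols <- if (all(c("lncrna_id", "disease_id") %in% names(pairs))) {
    c("lncrna_id", "disease_id")
  } else {
    names(pairs)[1:2]
  }
  l <- trimws(as.character(pairs[[cols[1]]]))
  d <- trimws(as.character(pairs[[cols[2]]]))
  bad <- which(is.na(l) | is.na(d) | l == "" | d == "")
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("Missing identifier in association row %d.", bad[1]),
      class = "mcglda_error_parse")
  }
  if (length(l) == 0) {
    rlang::abort("Association table contains no pairs.",
      class = "mcglda_error_empty")
  }
  lncrna_ids <- unique(l)
  disease_ids <- unique(d)
  Y <- matrix(0, length(lncrna_ids), length(disease_ids),
    dimnames = list(lncrna_ids, disease_ids))
  Y[cbind(match(l, lncrna_ids), match(d, disease_ids))] <- 1
  association_matrix(Y, lncrna_ids, disease_ids)
}

#' Low-level association matrix constructor
#'
#' @param Y Binary numeric matrix, rows = lncRNAs, columns = diseases.
#' @param lncrna_ids,disease_ids Unique identifier vectors matching the
#'   matrix dimensions; defaults taken from `dimnames(Y)`.
#' @return An `lda_assoc` object.
#' @export
association_matrix <- function(Y, lncrna_ids = rownames(Y),
                               disease_ids = colnames(Y)) {
  Y <- as.matrix(Y)
  if (is.null(lncrna_ids)) lncrna_ids <- paste0("L", seq_len(nrow(Y)))
  if (is.null(disease_ids)) disease_ids <- paste0("D", seq_len(ncol(Y)))
  if (anyDuplicated(lncrna_ids) || anyDuplicated(disease_ids)) {
    rlang::abort("Identifier lists must not contain duplicates.",
      class = "mcglda_error_identifier")
  }
  if (length(lncrna_ids) != nrow(Y) || length(disease_ids) != ncol(Y)) {
    rlang::abort("Identifier lengths must match the matrix dimensions.",
      class = "mcglda_error_shape")
  }
  if (!all(Y %in% c(0, 1))) {
    rlang::abort("Association matrix entries must be exactly 0 or 1.",
      class = "mcglda_error_input")
  }
  dimnames(Y) <- list(lncrna_ids, disease_ids)
  structure(
    list(Y = Y, lncrna_ids = lncrna_ids, disease_ids = disease_ids),
    class = "lda_assoc")
}

#' @export
print.lda_assoc <- function(x, ...) {
  cat(sprintf(
    "<lda_assoc> %d lncRNAs x %d diseases, %d known associations\n",
    nrow(x$Y), ncol(x$Y), sum(x$Y)))
  invisible(x)
}

#' @export
dim.lda_assoc <- function(x) dim(x$Y)

#' Long-format view of an association matrix
#'
#' @param x An `lda_assoc` object.
#' @param ... Unused.
#' @return A tibble with columns `lncrna_id`, `disease_id` listing the known
#'   (positive) pairs.
#' @method tidy lda_assoc
#' @export
tidy.lda_assoc <- function(x, ...) {
  idx <- which(x$Y == 1, arr.ind = TRUE)
  tibble::tibble(
    lncrna_id = x$lncrna_ids[idx[, 1]],
    disease_id = x$disease_ids[idx[, 2]]
  ) |>
    dplyr::arrange(.data$lncrna_id, .data$disease_id)
}
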