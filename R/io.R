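#' Read an lncRNA-disease association table
#'
#' Reads a headered delimited text file whose first two columns are
#' `lncrna_id` and `disease_id`. Duplicate pairs are merged; identifier
#' order follows first appearance; identifiers are trimmed of surrounding
#' whitespace and matched case-sensitively. TSV is the default dialect
#' because disease names frequently contain commas.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter (default tab).
#' @return An `lda_assoc` object.
#' @export
read_association_table <- function(path, delimiter = "\t") {
  as_association_matrix(read_checked(path, delimiter, min_cols = 2))
}

#' Read a disease ontology edge list
#'
#' Reads a headered delimited text file of `(parent_id, child_id)` edges
#' defining a rooted DAG. Cycles and self-edges are rejected.
#'
#' @inheritParams read_association_table
#' @return A [disease_ontology()] object.
#' @export
read_ontology <- function(path, delimiter = "\t") {
  disease_ontology(read_checked(path, delimiter, min_cols = 2))
}

read_checked <- function(path, delimiter, min_cols) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path),
      class = "mcglda_error_io")
  }
  df <- readr::read_delim(path, delim = delimiter, trim_ws = TRUE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE)
  if (nrow(df) == 0) {
    rlang::abort(sprintf("Empty input file: %s", path),
      class = "mcglda_error_empty")
  }
  if (ncol(df) < min_cols) {
    rlang::abort(
      sprintf("%s: expected at least %d columns, found %d.", path,
        min_cols, ncol(df)),
      class = "mcglda_error_parse")
  }
  bad <- which(is.na(df[[1]]) | is.na(df[[2]]) | df[[1]] == "" |
    df[[2]] == "")
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("%s: malformed row at line %d (missing field).", path,
        bad[1] + 1L),
      class = "mcglda_error_parse")
  }
  df
}

#' Write an association pair table
#'
#' @param assoc An `lda_assoc` object.
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @export
write_association_table <- function(assoc, path, delimiter = "\t") {
  readr::write_delim(tidy.lda_assoc(assoc), path, delim = delimiter)
  invisible(path)
}

#' Write an ontology edge list
#'
#' @param ontology A [disease_ontology()] object.
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @export
write_ontology <- function(ontology, path, delimiter = "\t") {
  edges <- tibble::tibble(
    parent_id = rep(names(ontology$children), lengths(ontology$children)),
    child_id = unlist(ontology$children, use.names = FALSE))
  readr::write_delim(edges, path, delim = delimiter)
  invisible(path)
}

#' Write predicted association scores
#'
#' Writes the full long-format prediction table (`lncrna_id`,
#' `disease_id`, `score`, `known_flag`), sorted by score descending with
#' ties broken by `(lncrna_id, disease_id)`; scores are printed with six
#' significant digits.
#'
#' @param fit An `mcgl_fit` object.
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @return The prediction tibble, invisibly.
#' @export
write_predictions <- function(fit, path, delimiter = "\t") {
  preds <- tidy.mcgl_fit(fit) |>
    dplyr::rename(known_flag = "known") |>
    dplyr::mutate(score = signif(.data$score, 6)) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$lncrna_id,
      .data$disease_id)
  readr::write_delim(preds, path, delim = delimiter)
  invisible(preds)
}

#' Export a similarity view as a labeled square matrix
#'
#' @param view A `similarity_view`.
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @export
write_view <- function(view, path, delimiter = "\t") {
  df <- tibble::as_tibble(as.data.frame(unclass(view)), rownames = "id")
  readr::write_delim(df, path, delim = delimiter)
  invisible(path)
}

#' Write a JSON run report for a fitted model
#'
#' @param fit An `mcgl_fit` object.
#' @param path Output path.
#' @export
write_run_report <- function(fit, path) {
  g <- glance.mcgl_fit(fit)
  jsonlite::write_json(
    list(objective = g$objective, outer_iterations = g$outer_iterations,
      converged = g$converged, alpha = g$alpha, beta = g$beta,
      disease_view_weights = as.list(fit$wD),
      lncrna_view_weights = as.list(fit$wL)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
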