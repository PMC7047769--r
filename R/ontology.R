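#' Build a disease ontology from a parent-child edge table
#'
#' The ontology is a rooted directed acyclic graph (DAG) over disease terms,
#' in the style of the MeSH disease hierarchy: edges point from a parent
#' (more general) term to a child (more specific) term. Semantic similarity
#' between diseases is computed from shared ancestors in this DAG.
#'
#' @param edges A data frame whose first two columns are parent and child
#'   term identifiers (`parent_id`, `child_id` are used when present).
#' @param terms Optional character vector of additional (possibly isolated)
#'   terms to include beyond those mentioned in `edges`.
#' @return An object of class `disease_ontology`: a list with `terms` and
#'   named lists `parents` and `children` keyed by term.
#' @examples
#' ont <- disease_ontology(tibble::tibble(
#'   parent_id = c("neoplasms", "neoplasms"),
#'   child_id  = c("breast cancer", "lung cancer")
#' ))
#' semantic_value(ont, "breast cancer")
#' @export
disease_ontology <- function(edges = NULL, terms = NULL) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    parent <- character(0)
    child <- character(0)
  } else {
    edges <- as.data.frame(edges)
    if (ncol(edges) < 2) {
      rlang::abort("`edges` must have at least two columns (parent, child).",
        class = "mcglda_error_input")
    }
    cols <- if (all(c("parent_id", "child_id") %in% names(edges))) {
      c("parent_id", "child_id")
    } else {
      names(edges)[1:2]
    }
    parent <- trimws(as.character(edges[[cols[1]]]))
    child <- trimws(as.character(edges[[cols[2]]]))
    bad <- which(is.na(parent) | is.na(child) | parent == "" | child == "")
    if (length(bad) > 0) {
      rlang::abort(sprintf("Missing term in ontology edge row %d.", bad[1]),
        class = "mcglda_error_parse")
    }
    self <- which(parent == child)
    if (length(self) > 0) {
      rlang::abort(
        sprintf("Self-edge '%s' -> '%s' in ontology edge row %d.",
          parent[self[1]], child[self[1]], self[1]),
        class = "mcglda_error_parse")
    }
  }
  all_terms <- unique(c(parent, child, as.character(terms)))
  keep <- !duplicated(cbind(parent, child))
  parent <- parent[keep]
  child <- child[keep]
  parents <- split(parent, factor(child, levels = all_terms))
  children <- split(child, factor(parent, levels = all_terms))
  ont <- structure(
    list(terms = all_terms, parents = parents, children = children),
    class = "disease_ontology")
  cyc <- find_cycle(ont)
  if (!is.null(cyc)) {
    rlang::abort(
      paste0("Ontology contains a cycle: ", paste(cyc, collapse = " -> ")),
      class = "mcglda_error_ontology")
  }
  ont
}

#' @export
print.disease_ontology <- function(x, ...) {
  n_edges <- sum(lengths(x$children))
  cat(sprintf("<disease_ontology> %d terms, %d edges, %d root(s)\n",
    length(x$terms), n_edges,
    sum(lengths(x$parents[x$terms]) == 0)))
  invisible(x)
}

# Iterative DFS over parent links; returns one offending cycle or NULL.
find_cycle <- function(ont) {
  color <- stats::setNames(rep(0L, length(ont$terms)), ont$terms)
  for (start in ont$terms) {
    if (color[start] != 0L) next
    stack <- list(list(node = start, i = 0L))
    path <- character(0)
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]
      node <- top$node
      if (top$i == 0L) {
        color[node] <- 1L
        path <- c(path, node)
      }
      pars <- ont$parents[[node]]
      if (top$i < length(pars)) {
        stack[[length(stack)]]$i <- top$i + 1L
        nxt <- pars[top$i + 1L]
        if (color[nxt] == 1L) {
          return(c(path[which(path == nxt):length(path)], nxt))
        }
        if (color[nxt] == 0L) {
          stack[[length(stack) + 1L]] <- list(node = nxt, i = 0L)
        }
      } else {
        color[node] <- 2L
        path <- path[-length(path)]
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

check_terms <- function(ont, diseases) {
  missing <- setdiff(diseases, ont$terms)
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("Term(s) not present in the ontology: %s",
        paste(utils::head(missing, 5), collapse = ", ")),
      class = "mcglda_error_identifier")
  }
}

# Ancestor-contribution vector over T(d) (d and all its ancestors).
# The term itself contributes 1; each ancestor t contributes
# max over its children inside T(d) of 0.5 * contribution(child).
semantic_contributions <- function(ont, disease) {
  check_terms(ont, disease)
  anc <- character(0)
  frontier <- disease
  while (length(frontier) > 0) {
    anc <- c(anc, frontier)
    frontier <- setdiff(
      unique(unlist(ont$parents[frontier], use.names = FALSE)), anc)
  }
  contrib <- stats::setNames(rep(NA_real_, length(anc)), anc)
  contrib[disease] <- 1
  resolve <- function(t) {
    if (!is.na(contrib[t])) return(contrib[t])
    kids <- intersect(ont$children[[t]], anc)
    val <- 0.5 * max(vapply(kids, resolve, numeric(1)))
    contrib[t] <<- val
    val
  }
  for (t in anc) resolve(t)
  contrib
}

#' Semantic value of a disease term
#'
#' The semantic value `D(d)` of a disease is the sum of ancestor
#' contributions over `T(d)`, the set containing the disease and all of its
#' ancestors in the ontology DAG. The disease itself contributes 1 and each
#' step up the hierarchy decays the contribution by a factor of 0.5, taking
#' the maximum over a node's children within `T(d)` when several paths lead
#' down towards the disease.
#'
#' @param ontology A [disease_ontology()] object.
#' @param disease A single term identifier present in the ontology.
#' @return A nonnegative scalar; an isolated term has semantic value 1.
#' @export
semantic_value <- function(ontology, disease) {
  stopifnot(length(disease) == 1)
  sum(semantic_contributions(ontology, disease))
}
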