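#' Similarity view constructor and validator
#'
#' A similarity view is a square, symmetric, unit-diagonal matrix with
#' entries in `[0, 1]` describing either the disease side (q x q) or the
#' lncRNA side (p x p) of the bipartite network.
#'
#' @param values Square numeric matrix.
#' @param side `"lncrna"` or `"disease"`.
#' @param name View label, e.g. `"semantic"`, `"functional"`, `"gip"`,
#'   `"cosine"`.
#' @return The matrix with attributes `side` and `view_name`, classed
#'   `similarity_view`.
#' @export
similarity_view <- function(values, side = c("lncrna", "disease"), name) {
  side <- match.arg(side)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    rlang::abort("A similarity view must be square.",
      class = "mcglda_error_shape")
  }
  if (max(abs(values - t(values))) > 1e-10) {
    rlang::abort("A similarity view must be symmetric (tolerance 1e-10).",
      class = "mcglda_error_input")
  }
  if (min(values) < 0 || max(values) > 1 + 1e-12) {
    rlang::abort("Similarity entries must lie in [0, 1].",
      class = "mcglda_error_input")
  }
  if (max(abs(diag(values) - 1)) > 1e-10) {
    rlang::abort("Similarity diagonal entries must equal 1.",
      class = "mcglda_error_input")
  }
  structure(values, side = side, view_name = name,
    class = c("similarity_view", "matrix", "array"))
}

#' @export
print.similarity_view <- function(x, ...) {
  cat(sprintf("<similarity_view '%s' (%s side), %d x %d>\n",
    attr(x, "view_name"), attr(x, "side"), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x)))])
  invisible(x)
}

#' Disease semantic similarity matrix
#'
#' Pairwise semantic similarity over an ordered set of disease terms: the
#' similarity of diseases i and j is the total contribution of their shared
#' ancestors, `sum_t (D_i(t) + D_j(t))` over `t` in `T(i) ∩ T(j)`, divided
#' by the sum of their semantic values `D(i) + D(j)`. Diseases in disjoint
#' rooted components have similarity 0; the diagonal is 1.
#'
#' @param ontology A [disease_ontology()] object.
#' @param diseases Ordered character vector of term identifiers.
#' @return A `similarity_view` of side `"disease"`, name `"semantic"`.
#' @export
disease_semantic_similarity <- function(ontology, diseases) {
  check_terms(ontology, diseases)
  q <- length(diseases)
  # C[t, j] = contribution of ancestor t to disease j (0 if t not in T(j))
  contribs <- lapply(diseases, function(d) semantic_contributions(ontology, d))
  all_anc <- unique(unlist(lapply(contribs, names), use.names = FALSE))
  C <- matrix(0, length(all_anc), q, dimnames = list(all_anc, diseases))
  for (j in seq_len(q)) C[names(contribs[[j]]), j] <- contribs[[j]]
  B <- (C > 0) + 0
  # M[i, j] = sum over shared ancestors of D_i(t); numerator = M + t(M)
  M <- crossprod(C, B)
  D <- colSums(C)
  S <- (M + t(M)) / outer(D, D, "+")
  diag(S) <- 1
  dimnames(S) <- list(diseases, diseases)
  similarity_view(S, "disease", "semantic")
}

#' lncRNA functional similarity from associated disease sets
#'
#' Two lncRNAs are functionally similar when the disease sets they are
#' linked to are semantically similar. For lncRNAs i and j with disease
#' sets `D(i)` (size m) and `D(j)` (size n), the similarity is the sum of
#' best-match semantic similarities of each disease in one set against the
#' other set, in both directions, divided by `m + n`. An lncRNA with an
#' empty disease set (which occurs inside cross-validation folds) gets
#' off-diagonal similarity 0; the diagonal is always 1.
#'
#' @param assoc An `lda_assoc` object (the training association matrix).
#' @param semantic Disease semantic similarity view over
#'   `assoc$disease_ids`, from [disease_semantic_similarity()].
#' @return A `similarity_view` of side `"lncrna"`, name `"functional"`.
#' @export
lncrna_functional_similarity <- function(assoc, semantic) {
  Y <- assoc$Y
  p <- nrow(Y)
  q <- ncol(Y)
  S <- unclass(semantic)
  if (nrow(S) != q) {
    rlang::abort("Semantic view dimension must match the disease count.",
      class = "mcglda_error_shape")
  }
  sets <- lapply(seq_len(p), function(i) which(Y[i, ] == 1))
  sizes <- lengths(sets)
  # best[d, i] = max semantic similarity of disease d to lncRNA i's set
  best <- matrix(0, q, p)
  for (i in seq_len(p)) {
    if (sizes[i] == 1) {
      best[, i] <- S[, sets[[i]]]
    } else if (sizes[i] > 1) {
      best[, i] <- do.call(pmax, as.data.frame(S[, sets[[i]], drop = FALSE]))
    }
  }
  # num[i, j] = sum_{d in D(j)} best[d, i] + sum_{d in D(i)} best[d, j]
  M <- Y %*% best          # M[j, i] = sum over D(j) of best[., i]
  num <- t(M) + M
  denom <- outer(sizes, sizes, "+")
  LFS <- ifelse(denom > 0, num / pmax(denom, 1), 0)
  LFS <- pmin(pmax((LFS + t(LFS)) / 2, 0), 1)  # clip symmetrization round-off
  diag(LFS) <- 1
  dimnames(LFS) <- list(assoc$lncrna_ids, assoc$lncrna_ids)
  similarity_view(LFS, "lncrna", "functional")
}

profiles_for_side <- function(assoc, side) {
  side <- match.arg(side, c("lncrna", "disease"))
  if (side == "lncrna") assoc$Y else t(assoc$Y)
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Gaussian kernel over interaction profiles: rows of Y for lncRNAs,
#' columns of Y for diseases. The kernel bandwidth is
#' `bandwidth_scale / mean(||IP||^2)` over all profiles on the chosen side,
#' so that the kernel adapts to the overall density of the network.
#'
#' @param assoc An `lda_assoc` object.
#' @param side `"lncrna"` or `"disease"`.
#' @param bandwidth_scale Positive scalar scaling the bandwidth (default 1).
#' @return A `similarity_view` named `"gip"`; all entries strictly positive.
#' @export
gip_similarity <- function(assoc, side = c("lncrna", "disease"),
                           bandwidth_scale = 1) {
  side <- match.arg(side)
  stopifnot(bandwidth_scale > 0)
  P <- profiles_for_side(assoc, side)
  norms2 <- rowSums(P^2)
  if (all(norms2 == 0)) {
    rlang::abort(
      "All interaction profiles are zero: GIP bandwidth is undefined.",
      class = "mcglda_error_degenerate")
  }
  beta <- bandwidth_scale / mean(norms2)
  D2 <- outer(norms2, norms2, "+") - 2 * tcrossprod(P)
  D2 <- pmax(D2, 0)
  K <- exp(-beta * D2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dimnames(K) <- list(rownames(P), rownames(P))
  similarity_view(K, side, "gip")
}

#' Cosine similarity of interaction profiles
#'
#' Cosine of the angle between interaction profiles (rows of Y for lncRNAs,
#' columns for diseases). Profiles with zero norm (no known associations)
#' get off-diagonal similarity 0 and diagonal 1.
#'
#' @inheritParams gip_similarity
#' @return A `similarity_view` named `"cosine"`.
#' @export
cosine_similarity_matrix <- function(assoc, side = c("lncrna", "disease")) {
  side <- match.arg(side)
  P <- profiles_for_side(assoc, side)
  nrm <- sqrt(rowSums(P^2))
  C <- tcrossprod(P) / outer(pmax(nrm, 1), pmax(nrm, 1))  # binary: nrm>=1 or 0
  C[nrm == 0, ] <- 0
  C[, nrm == 0] <- 0
  C <- pmin(pmax((C + t(C)) / 2, 0), 1)
  diag(C) <- 1
  dimnames(C) <- list(rownames(P), rownames(P))
  similarity_view(C, side, "cosine")
}

#' Assemble the multiview similarity set
#'
#' Builds the disease-side views (semantic, GIP, cosine) and lncRNA-side
#' views (functional, GIP, cosine) from one association matrix. All
#' Y-derived views are computed from the matrix passed in, so
#' cross-validation folds can rebuild views from a training matrix without
#' leaking held-out associations.
#'
#' @param assoc An `lda_assoc` object.
#' @param ontology A [disease_ontology()] covering `assoc$disease_ids`, or
#'   `NULL` to skip the ontology-based views (with a warning).
#' @param bandwidth_scale GIP bandwidth scale, see [gip_similarity()].
#' @param semantic Optional precomputed disease semantic view (it does not
#'   depend on Y, so it can be shared across cross-validation folds).
#' @param permissive_terms If `TRUE`, diseases absent from the ontology get
#'   zero semantic similarity to everything (diagonal 1) instead of an
#'   error.
#' @return An object of class `view_set`: list with `disease_views` and
#'   `lncrna_views`, each a named list of `similarity_view` matrices.
#' @export
build_views <- function(assoc, ontology = NULL, bandwidth_scale = 1,
                        semantic = NULL, permissive_terms = FALSE) {
  assoc <- as_association_matrix(assoc)
  disease_views <- list()
  lncrna_views <- list()
  if (is.null(semantic) && !is.null(ontology)) {
    present <- assoc$disease_ids %in% ontology$terms
    if (all(present)) {
      semantic <- disease_semantic_similarity(ontology, assoc$disease_ids)
    } else if (permissive_terms) {
      q <- length(assoc$disease_ids)
      S <- matrix(0, q, q,
        dimnames = list(assoc$disease_ids, assoc$disease_ids))
      known <- disease_semantic_similarity(
        ontology, assoc$disease_ids[present])
      S[present, present] <- unclass(known)
      diag(S) <- 1
      semantic <- similarity_view(S, "disease", "semantic")
    } else {
      check_terms(ontology, assoc$disease_ids)  # raises identifier error
    }
  }
  if (!is.null(semantic)) {
    disease_views$semantic <- semantic
    lncrna_views$functional <- lncrna_functional_similarity(assoc, semantic)
  } else {
    rlang::warn(
      "No ontology supplied: building GIP and cosine views only.",
      class = "mcglda_warning_no_ontology")
  }
  disease_views$gip <- gip_similarity(assoc, "disease", bandwidth_scale)
  disease_views$cosine <- cosine_similarity_matrix(assoc, "disease")
  lncrna_views$gip <- gip_similarity(assoc, "lncrna", bandwidth_scale)
  lncrna_views$cosine <- cosine_similarity_matrix(assoc, "lncrna")
  structure(
    list(disease_views = disease_views, lncrna_views = lncrna_views),
    class = "view_set")
}

#' @export
print.view_set <- function(x, ...) {
  cat(sprintf(
    "<view_set> %d disease view(s): %s; %d lncRNA view(s): %s\n",
    length(x$disease_views), paste(names(x$disease_views), collapse = ", "),
    length(x$lncrna_views), paste(names(x$lncrna_views), collapse = ", ")))
  invisible(x)
}
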