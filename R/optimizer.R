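#' Hyperparameters for consensus graph learning
#'
#' @param alpha Nonnegative disease-side smoothness weight: how strongly the
#'   learned disease consensus graph smooths the prediction matrix columns.
#'   Default 1e-4, the value at which five-fold CV performance peaks on
#'   association data at this sparsity.
#' @param beta Nonnegative lncRNA-side smoothness weight; default 1e-4.
#' @param bandwidth_scale GIP kernel bandwidth scale, see [gip_similarity()].
#' @param inner_tol,outer_tol Relative-objective-change convergence
#'   thresholds for the inner (graph/prediction) and outer (view weight)
#'   loops; defaults 1e-4.
#' @param max_inner,max_outer Iteration caps (30, 50).
#' @return A list of class `mcgl_params`.
#' @export
mcgl_params <- function(alpha = 1e-4, beta = 1e-4, bandwidth_scale = 1,
                        inner_tol = 1e-4, outer_tol = 1e-4,
                        max_inner = 30, max_outer = 50) {
  stopifnot(alpha >= 0, beta >= 0, bandwidth_scale > 0,
    inner_tol > 0, outer_tol > 0, max_inner >= 1, max_outer >= 1)
  structure(
    list(alpha = alpha, beta = beta, bandwidth_scale = bandwidth_scale,
      inner_tol = inner_tol, outer_tol = outer_tol,
      max_inner = max_inner, max_outer = max_outer),
    class = "mcgl_params")
}

#' Graph Laplacian of a (possibly asymmetric) similarity matrix
#'
#' `L_S = D_S - (S' + S)/2` where the degree matrix `D_S` is diagonal with
#' entries `sum_j (S_ij + S_ji)/2`. The result is symmetric positive
#' semidefinite with zero row sums.
#'
#' @param S Square nonnegative matrix.
#' @return Symmetric matrix of the same dimension.
#' @export
build_laplacian <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) {
    rlang::abort("Laplacian requires a square matrix.",
      class = "mcglda_error_shape")
  }
  W <- (S + t(S)) / 2
  diag(rowSums(W), nrow(W)) - W
}

#' Euclidean projection onto the probability simplex
#'
#' Returns the closest point (in Euclidean norm) to `v` in
#' `{x : sum(x) = 1, x >= 0}`, via the exact sorting-based closed form.
#'
#' @param v Nonempty numeric vector.
#' @return Vector of the same length on the simplex.
#' @export
simplex_project <- function(v) {
  n <- length(v)
  if (n == 0) {
    rlang::abort("Cannot project an empty vector.",
      class = "mcglda_error_shape")
  }
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_len(n) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# Squared pairwise distances between rows of F
pairwise_sqdist <- function(F) {
  n2 <- rowSums(F^2)
  pmax(outer(n2, n2, "+") - 2 * tcrossprod(F), 0)
}

#' Update a consensus graph given fixed weights and predictions
#'
#' Each row i of the consensus graph solves an independent simplex-
#' constrained least-squares problem: the projection of the weighted
#' average view row minus `(smooth_weight/2) * h_i`, where `h_i[j]` is the
#' squared distance between the prediction-matrix slices for entities i and
#' j (columns of F on the disease side, rows on the lncRNA side).
#'
#' @param views List of `similarity_view` matrices (one side).
#' @param weights Simplex weight vector, one per view.
#' @param F Current p x q prediction matrix.
#' @param smooth_weight `alpha` (disease side) or `beta` (lncRNA side).
#' @param side `"disease"` or `"lncrna"`.
#' @return Row-stochastic nonnegative matrix of the view dimension.
#' @export
update_consensus_graph <- function(views, weights, F,
                                   smooth_weight, side = c("disease", "lncrna")) {
  side <- match.arg(side)
  A <- weighted_view_sum(views, weights)
  slices <- if (side == "disease") t(F) else F
  if (nrow(slices) != nrow(A)) {
    rlang::abort("Prediction matrix dimension does not match the views.",
      class = "mcglda_error_shape")
  }
  H <- pairwise_sqdist(slices)
  Target <- A - (smooth_weight / 2) * H
  S <- t(apply(Target, 1, simplex_project))
  dimnames(S) <- dimnames(A)
  S
}

weighted_view_sum <- function(views, weights) {
  if (length(views) == 0) {
    rlang::abort("At least one view is required.",
      class = "mcglda_error_config")
  }
  stopifnot(length(views) == length(weights))
  Reduce(`+`, Map(function(V, w) unclass(V) * w, views, weights))
}

#' Update view weights on the probability simplex
#'
#' Finds the simplex-constrained weights minimizing the Frobenius distance
#' between the consensus graph and the weighted view combination: with `a`
#' the column-stacked consensus matrix and `G` the matrix of column-stacked
#' views, solves `min_w ||a - G w||^2` on the simplex by projected gradient
#' descent from the uniform initialization, with step size the reciprocal
#' of the spectral norm of `G'G`. Duplicated (indistinguishable) views
#' share weight deterministically because the flat directions are never
#' entered from the uniform start.
#'
#' @param S Consensus matrix.
#' @param views List of views of the same dimension.
#' @param tol Relative-change stopping threshold (1e-8).
#' @param max_iter Iteration cap (10000).
#' @return Weight vector on the simplex, named after the views.
#' @export
update_view_weights <- function(S, views, tol = 1e-8, max_iter = 10000) {
  n <- length(views)
  if (n == 0) {
    rlang::abort("At least one view is required.",
      class = "mcglda_error_config")
  }
  if (n == 1) return(stats::setNames(1, names(views)))
  a <- as.vector(S)
  G <- vapply(views, function(V) as.vector(unclass(V)), numeric(length(a)))
  GtG <- crossprod(G)
  Gta <- crossprod(G, a)
  step <- 1 / max(eigen(GtG, symmetric = TRUE, only.values = TRUE)$values)
  w <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    grad <- GtG %*% w - Gta
    w_new <- simplex_project(as.vector(w - step * grad))
    if (sqrt(sum((w_new - w)^2)) < tol * max(1, sqrt(sum(w^2)))) {
      w <- w_new
      break
    }
    w <- w_new
  }
  stats::setNames(as.vector(w), names(views))
}

#' Solve the prediction-matrix update as a Sylvester equation
#'
#' Solves `(2*beta*L_SL + I) F + 2*alpha * F %*% L_SD = Y` for `F` via
#' symmetric eigendecomposition of both operators and elementwise division
#' in the joint eigenbasis. The solution is unique because every eigenvalue
#' of `2*beta*L_SL + I` is at least 1 and every eigenvalue of `2*alpha*L_SD`
#' is nonnegative.
#'
#' @param L_SL p x p lncRNA-side Laplacian (symmetric PSD).
#' @param L_SD q x q disease-side Laplacian (symmetric PSD).
#' @param Y p x q known association matrix (values).
#' @param alpha,beta Smoothness weights.
#' @return The p x q solution matrix F.
#' @export
solve_label_matrix <- function(L_SL, L_SD, Y, alpha, beta) {
  for (L in list(L_SL, L_SD)) {
    if (max(abs(L - t(L))) > 1e-8) {
      rlang::abort("Laplacian input is asymmetric beyond tolerance 1e-8.",
        class = "mcglda_error_numeric")
    }
  }
  if (alpha == 0 && beta == 0) {
    return(Y)
  }
  eL <- eigen(2 * beta * L_SL + diag(nrow(L_SL)), symmetric = TRUE)
  eD <- eigen(2 * alpha * L_SD, symmetric = TRUE)
  denom <- outer(eL$values, eD$values, "+")
  Ft <- eL$vectors %*% ((crossprod(eL$vectors, Y) %*% eD$vectors) / denom) %*%
    t(eD$vectors)
  dimnames(Ft) <- dimnames(Y)
  Ft
}

#' Value of the joint consensus-learning objective
#'
#' Sum of: the Frobenius misfit of each consensus graph to its weighted
#' view combination, the graph-smoothness penalties
#' `2*alpha*Tr(F L_SD F')` and `2*beta*Tr(F' L_SL F)`, and the label fit
#' `||F - Y||_F^2`.
#'
#' @param SD,SL Consensus graphs (disease q x q, lncRNA p x p).
#' @param wD,wL View weight vectors.
#' @param F Prediction matrix.
#' @param views A `view_set`.
#' @param Y Binary association matrix values.
#' @param alpha,beta Smoothness weights.
#' @return Nonnegative scalar.
#' @export
objective_value <- function(SD, SL, wD, wL, F, views, Y, alpha, beta) {
  if (!all(dim(F) == dim(Y)) || nrow(SD) != ncol(Y) || nrow(SL) != nrow(Y)) {
    rlang::abort("Objective inputs have inconsistent dimensions.",
      class = "mcglda_error_shape")
  }
  AD <- weighted_view_sum(views$disease_views, wD)
  AL <- weighted_view_sum(views$lncrna_views, wL)
  sum((SD - AD)^2) + sum((SL - AL)^2) +
    2 * alpha * sum(F %*% build_laplacian(SD) * F) +
    2 * beta * sum(crossprod(F, build_laplacian(SL)) * t(F)) +
    sum((F - Y)^2)
}

#' Fit the multiview consensus graph model
#'
#' Alternating optimization of the joint objective: view weights start
#' uniform and the prediction matrix starts at Y; an inner loop cycles
#' exact block updates of the disease consensus graph, the lncRNA consensus
#' graph, and the prediction matrix (a Sylvester solve) until the relative
#' objective change drops below `inner_tol`; an outer loop then refreshes
#' the view weights and repeats until the objective stabilizes across outer
#' sweeps. Every block update solves its subproblem exactly, so the
#' objective trace is non-increasing.
#'
#' @param assoc An `lda_assoc` object (or a pair data frame).
#' @param views A `view_set` from [build_views()]; built automatically from
#'   `ontology` when omitted.
#' @param params An [mcgl_params()] object.
#' @param ontology Optional [disease_ontology()], used only when `views` is
#'   missing.
#' @return An object of class `mcgl_fit` with elements `F` (predicted
#'   association scores), `SD`, `SL`, `wD`, `wL`, `objective_trace` (tibble),
#'   `outer_iterations`, `converged`, `params`, and the input `assoc`.
#' @examples
#' sim <- simulate_lda_data(synthetic_config(
#'   n_lncrnas = 20, n_diseases = 15, n_blocks = 3,
#'   density_in = 0.5, density_out = 0.05, seed = 1))
#' fit <- mcgl_fit(sim$assoc, ontology = sim$ontology)
#' glance(fit)
#' @export
mcgl_fit <- function(assoc, views = NULL, params = mcgl_params(),
                     ontology = NULL) {
  assoc <- as_association_matrix(assoc)
  if (is.null(views)) {
    views <- build_views(assoc, ontology,
      bandwidth_scale = params$bandwidth_scale)
  }
  Y <- assoc$Y
  n <- length(views$disease_views)
  m <- length(views$lncrna_views)
  wD <- stats::setNames(rep(1 / n, n), names(views$disease_views))
  wL <- stats::setNames(rep(1 / m, m), names(views$lncrna_views))
  F <- Y
  SD <- update_consensus_graph(views$disease_views, wD, F, params$alpha,
    "disease")
  SL <- update_consensus_graph(views$lncrna_views, wL, F, params$beta,
    "lncrna")
  trace <- list()
  obj <- function() objective_value(SD, SL, wD, wL, F, views, Y,
    params$alpha, params$beta)
  record <- function(outer, inner, block, value) {
    trace[[length(trace) + 1L]] <<- tibble::tibble(
      outer = outer, inner = inner, block = block, objective = value)
  }
  check_finite <- function(x, block) {
    if (!all(is.finite(x))) {
      rlang::abort(
        sprintf("Non-finite values produced in the '%s' update.", block),
        class = "mcglda_error_numeric")
    }
    x
  }
  outer_prev <- Inf
  converged <- FALSE
  outer_used <- 0L
  for (outer in seq_len(params$max_outer)) {
    inner_prev <- Inf
    for (inner in seq_len(params$max_inner)) {
      SD <- check_finite(update_consensus_graph(views$disease_views, wD, F,
        params$alpha, "disease"), "SD")
      record(outer, inner, "SD", obj())
      SL <- check_finite(update_consensus_graph(views$lncrna_views, wL, F,
        params$beta, "lncrna"), "SL")
      record(outer, inner, "SL", obj())
      F <- check_finite(solve_label_matrix(build_laplacian(SL),
        build_laplacian(SD), Y, params$alpha, params$beta), "F")
      cur <- obj()
      record(outer, inner, "F", cur)
      if (abs(inner_prev - cur) < params$inner_tol * max(abs(inner_prev), 1e-12)) {
        break
      }
      inner_prev <- cur
    }
    wD <- check_finite(update_view_weights(SD, views$disease_views), "wD")
    wL <- check_finite(update_view_weights(SL, views$lncrna_views), "wL")
    cur <- obj()
    record(outer, inner, "weights", cur)
    outer_used <- outer
    if (abs(outer_prev - cur) < params$outer_tol * max(abs(outer_prev), 1e-12)) {
      converged <- TRUE
      break
    }
    outer_prev <- cur
  }
  structure(
    list(F = F, SD = SD, SL = SL, wD = wD, wL = wL,
      objective_trace = dplyr::bind_rows(trace),
      outer_iterations = outer_used, converged = converged,
      params = params, assoc = assoc, views = views),
    class = "mcgl_fit")
}

#' @export
print.mcgl_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<mcgl_fit> %d lncRNAs x %d diseases | objective %.6g | ",
      "%d outer iteration(s)%s\n"),
    nrow(x$F), ncol(x$F),
    utils::tail(x$objective_trace$objective, 1), x$outer_iterations,
    if (x$converged) ", converged" else " (cap reached)"))
  cat("disease view weights:",
    paste(sprintf("%s=%.3f", names(x$wD), x$wD), collapse = ", "), "\n")
  cat("lncRNA view weights: ",
    paste(sprintf("%s=%.3f", names(x$wL), x$wL), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy predicted association scores
#'
#' @param x An `mcgl_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `lncrna_id`, `disease_id`, `score`,
#'   `known` (1 for training positives), sorted by score descending with
#'   ties broken by (lncrna_id, disease_id).
#' @method tidy mcgl_fit
#' @export
tidy.mcgl_fit <- function(x, ...) {
  tibble::tibble(
    lncrna_id = rep(x$assoc$lncrna_ids, times = ncol(x$F)),
    disease_id = rep(x$assoc$disease_ids, each = nrow(x$F)),
    score = as.vector(x$F),
    known = as.integer(as.vector(x$assoc$Y))
  ) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$lncrna_id,
      .data$disease_id)
}

#' One-row fit summary
#'
#' @param x An `mcgl_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: final objective, outer iterations, total block
#'   updates, convergence flag, and hyperparameters.
#' @method glance mcgl_fit
#' @export
glance.mcgl_fit <- function(x, ...) {
  tibble::tibble(
    objective = utils::tail(x$objective_trace$objective, 1),
    outer_iterations = x$outer_iterations,
    n_updates = nrow(x$objective_trace),
    converged = x$converged,
    alpha = x$params$alpha,
    beta = x$params$beta
  )
}
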