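#' Rank-based area under the ROC curve
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, computed from midranks (ties count one half).
#'
#' @param scores Numeric vector of prediction scores.
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return Scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("AUC is undefined when only one class is present.",
      class = "mcglda_error_single_class")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return A tibble with columns `threshold`, `fpr`, `tpr`, one row per
#'   distinct score plus the two endpoints.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  n_pos <- sum(l == 1)
  n_neg <- sum(l == 0)
  keep <- c(s[-length(s)] != s[-1], TRUE)
  tibble::tibble(
    threshold = c(Inf, s[keep]),
    tpr = c(0, cumsum(l == 1)[keep] / n_pos),
    fpr = c(0, cumsum(l == 0)[keep] / n_neg)
  )
}

fit_on_training <- function(train_Y, assoc, ontology, params, semantic) {
  train_assoc <- association_matrix(train_Y, assoc$lncrna_ids,
    assoc$disease_ids)
  views <- build_views(train_assoc, ontology,
    bandwidth_scale = params$bandwidth_scale, semantic = semantic)
  mcgl_fit(train_assoc, views, params)
}

precompute_semantic <- function(assoc, ontology) {
  if (is.null(ontology)) return(NULL)
  disease_semantic_similarity(ontology, assoc$disease_ids)
}

new_mcgl_eval <- function(scheme, scores, auc_overall, per_disease_auc,
                          fold_assignments, seed) {
  structure(
    list(scheme = scheme, scores = scores, auc_overall = auc_overall,
      per_disease_auc = per_disease_auc,
      fold_assignments = fold_assignments, seed = seed),
    class = "mcgl_eval")
}

#' @export
print.mcgl_eval <- function(x, ...) {
  cat(sprintf("<mcgl_eval> scheme: %s\n", x$scheme))
  if (!is.null(x$auc_overall)) {
    cat(sprintf("  overall AUC: %.4f\n", x$auc_overall))
  }
  if (!is.null(x$per_disease_auc)) {
    cat(sprintf("  per-disease AUC: n = %d, median = %.4f\n",
      nrow(x$per_disease_auc), stats::median(x$per_disease_auc$auc)))
  }
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' Each known association is held out in turn: it is zeroed in a training
#' copy of Y, all Y-derived views are rebuilt from the training copy (the
#' ontology-based semantic view does not depend on Y and is shared), the
#' model is refit, and the held-out pair is scored under that model. The
#' overall AUC pools the held-out positive scores against all never-known
#' pairs, which are scored once under a single full-data fit.
#'
#' @param assoc An `lda_assoc` object (or pair data frame).
#' @param ontology A [disease_ontology()] or `NULL`.
#' @param params An [mcgl_params()] object.
#' @param fold_hook Optional `function(train_Y, held_out, fold)` called
#'   before each refit with the training matrix and a tibble of held-out
#'   pairs — an instrumentation point for leakage auditing.
#' @return An `mcgl_eval` object (scheme `"loocv"`).
#' @export
run_loocv <- function(assoc, ontology = NULL, params = mcgl_params(),
                      fold_hook = NULL) {
  assoc <- as_association_matrix(assoc)
  pos <- which(assoc$Y == 1, arr.ind = TRUE)
  if (nrow(pos) < 2) {
    rlang::abort("LOOCV needs at least two known associations.",
      class = "mcglda_error_config")
  }
  semantic <- precompute_semantic(assoc, ontology)
  pos_scores <- numeric(nrow(pos))
  for (k in seq_len(nrow(pos))) {
    train_Y <- assoc$Y
    train_Y[pos[k, 1], pos[k, 2]] <- 0
    held <- tibble::tibble(
      lncrna_id = assoc$lncrna_ids[pos[k, 1]],
      disease_id = assoc$disease_ids[pos[k, 2]])
    if (!is.null(fold_hook)) fold_hook(train_Y, held, k)
    fit <- fit_on_training(train_Y, assoc, ontology, params, semantic)
    pos_scores[k] <- fit$F[pos[k, 1], pos[k, 2]]
  }
  full_fit <- mcgl_fit(assoc,
    build_views(assoc, ontology, params$bandwidth_scale, semantic), params)
  neg <- which(assoc$Y == 0, arr.ind = TRUE)
  scores <- tibble::tibble(
    lncrna_id = c(assoc$lncrna_ids[pos[, 1]], assoc$lncrna_ids[neg[, 1]]),
    disease_id = c(assoc$disease_ids[pos[, 2]], assoc$disease_ids[neg[, 2]]),
    score = c(pos_scores, full_fit$F[neg]),
    label = rep(c(1L, 0L), c(nrow(pos), nrow(neg))),
    fold = c(seq_len(nrow(pos)), rep(NA_integer_, nrow(neg)))
  )
  folds <- scores |>
    dplyr::filter(.data$label == 1L) |>
    dplyr::select("lncrna_id", "disease_id", "fold")
  new_mcgl_eval("loocv", scores, roc_auc(scores$score, scores$label),
    NULL, folds, NA_integer_)
}

#' k-fold cross-validation over known associations
#'
#' Known positives are shuffled by `seed` and split into `k` near-equal
#' folds. For each fold, the fold's positives are zeroed in a training copy
#' of Y, the Y-derived views are rebuilt, and the model is refit; the
#' fold's positives and all never-known pairs are scored with that fold's
#' model. The overall AUC pools scores across folds.
#'
#' @inheritParams run_loocv
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold split (default 42).
#' @return An `mcgl_eval` object (scheme `"kfold"`).
#' @export
run_kfold <- function(assoc, ontology = NULL, params = mcgl_params(),
                      k = 5, seed = 42, fold_hook = NULL) {
  assoc <- as_association_matrix(assoc)
  pos <- which(assoc$Y == 1, arr.ind = TRUE)
  n_pos <- nrow(pos)
  if (k < 2 || n_pos < k) {
    rlang::abort("k must be at least 2 and not exceed the positive count.",
      class = "mcglda_error_config")
  }
  perm <- withr::with_seed(seed, sample.int(n_pos))
  fold_of <- integer(n_pos)
  fold_of[perm] <- rep_len(seq_len(k), n_pos)
  semantic <- precompute_semantic(assoc, ontology)
  neg <- which(assoc$Y == 0, arr.ind = TRUE)
  parts <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_of == f)
    train_Y <- assoc$Y
    train_Y[pos[test_idx, , drop = FALSE]] <- 0
    held <- tibble::tibble(
      lncrna_id = assoc$lncrna_ids[pos[test_idx, 1]],
      disease_id = assoc$disease_ids[pos[test_idx, 2]])
    if (!is.null(fold_hook)) fold_hook(train_Y, held, f)
    fit <- fit_on_training(train_Y, assoc, ontology, params, semantic)
    parts[[f]] <- tibble::tibble(
      lncrna_id = c(held$lncrna_id, assoc$lncrna_ids[neg[, 1]]),
      disease_id = c(held$disease_id, assoc$disease_ids[neg[, 2]]),
      score = c(fit$F[pos[test_idx, , drop = FALSE]], fit$F[neg]),
      label = rep(c(1L, 0L), c(length(test_idx), nrow(neg))),
      fold = f)
  }
  scores <- dplyr::bind_rows(parts)
  folds <- tibble::tibble(
    lncrna_id = assoc$lncrna_ids[pos[, 1]],
    disease_id = assoc$disease_ids[pos[, 2]],
    fold = fold_of)
  new_mcgl_eval("kfold", scores, roc_auc(scores$score, scores$label),
    NULL, folds, seed)
}

#' Leave-one-disease-out cross-validation
#'
#' For each disease with at least one known association, its entire Y
#' column is zeroed in a training copy, views are rebuilt, the model is
#' refit, and an AUC is computed over that disease's column (held-out
#' positives versus the disease's non-associated lncRNAs). Diseases whose
#' column is all-positive (no negatives) are skipped with a warning.
#'
#' @inheritParams run_loocv
#' @return An `mcgl_eval` object (scheme `"lodocv"`) with a
#'   `per_disease_auc` tibble.
#' @export
run_lodocv <- function(assoc, ontology = NULL, params = mcgl_params(),
                       fold_hook = NULL) {
  assoc <- as_association_matrix(assoc)
  col_pos <- colSums(assoc$Y)
  eligible <- which(col_pos >= 1)
  if (length(eligible) < 2) {
    rlang::abort("LODOCV needs at least two diseases with associations.",
      class = "mcglda_error_config")
  }
  semantic <- precompute_semantic(assoc, ontology)
  rows <- list()
  score_rows <- list()
  for (j in eligible) {
    if (col_pos[j] == nrow(assoc$Y)) {
      rlang::warn(sprintf(
        "Disease '%s' has no negative lncRNAs; skipped in LODOCV.",
        assoc$disease_ids[j]))
      next
    }
    train_Y <- assoc$Y
    train_Y[, j] <- 0
    held <- tibble::tibble(
      lncrna_id = assoc$lncrna_ids[assoc$Y[, j] == 1],
      disease_id = assoc$disease_ids[j])
    if (!is.null(fold_hook)) fold_hook(train_Y, held, j)
    fit <- fit_on_training(train_Y, assoc, ontology, params, semantic)
    labels <- assoc$Y[, j]
    auc <- roc_auc(fit$F[, j], labels)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      disease_id = assoc$disease_ids[j], n_positive = sum(labels),
      auc = auc)
    score_rows[[length(score_rows) + 1L]] <- tibble::tibble(
      lncrna_id = assoc$lncrna_ids, disease_id = assoc$disease_ids[j],
      score = fit$F[, j], label = as.integer(labels), fold = j)
  }
  per_disease <- dplyr::bind_rows(rows)
  new_mcgl_eval("lodocv", dplyr::bind_rows(score_rows), NULL, per_disease,
    per_disease["disease_id"], NA_integer_)
}

#' Hyperparameter grid evaluation by k-fold CV
#'
#' @inheritParams run_kfold
#' @param alphas,betas Numeric vectors of smoothness weights to evaluate.
#' @return A tibble `(alpha, beta, auc)` with one row per grid point,
#'   sorted by AUC descending.
#' @export
grid_search <- function(assoc, ontology = NULL, alphas, betas,
                        params = mcgl_params(), k = 5, seed = 42) {
  stopifnot(length(alphas) >= 1, length(betas) >= 1)
  grid <- tidyr::expand_grid(alpha = alphas, beta = betas)
  grid$auc <- purrr::pmap_dbl(grid, function(alpha, beta) {
    p <- params
    p$alpha <- alpha
    p$beta <- beta
    run_kfold(assoc, ontology, p, k = k, seed = seed)$auc_overall
  })
  dplyr::arrange(grid, dplyr::desc(.data$auc))
}

#' Compare two per-disease AUC lists
#'
#' Thin wrapper around the paired Wilcoxon signed-rank test for comparing
#' per-disease AUC lists of two methods over the same diseases.
#'
#' @param auc_a,auc_b Data frames with columns `disease_id`, `auc`, or bare
#'   numeric vectors of equal length.
#' @param alternative Passed to [stats::wilcox.test()] (default
#'   `"greater"`: method A better than method B).
#' @return A one-row tibble with the test statistic and p-value.
#' @export
compare_auc_lists <- function(auc_a, auc_b, alternative = "greater") {
  if (is.data.frame(auc_a)) {
    merged <- dplyr::inner_join(auc_a, auc_b, by = "disease_id",
      suffix = c("_a", "_b"))
    a <- merged$auc_a
    b <- merged$auc_b
  } else {
    a <- auc_a
    b <- auc_b
  }
  ht <- stats::wilcox.test(a, b, paired = TRUE, alternative = alternative,
    exact = FALSE)
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
    n = length(a))
}

#' Tidy cross-validation scores
#'
#' @param x An `mcgl_eval` object.
#' @param ... Unused.
#' @return The pooled score tibble (`lncrna_id`, `disease_id`, `score`,
#'   `label`, `fold`).
#' @method tidy mcgl_eval
#' @export
tidy.mcgl_eval <- function(x, ...) x$scores

#' One-row cross-validation summary
#'
#' @param x An `mcgl_eval` object.
#' @param ... Unused.
#' @return A one-row tibble with the scheme, overall or median AUC, and the
#'   number of evaluation units.
#' @method glance mcgl_eval
#' @export
glance.mcgl_eval <- function(x, ...) {
  if (x$scheme == "lodocv") {
    tibble::tibble(scheme = x$scheme,
      auc = stats::median(x$per_disease_auc$auc),
      auc_type = "median_per_disease",
      n = nrow(x$per_disease_auc), seed = x$seed)
  } else {
    tibble::tibble(scheme = x$scheme, auc = x$auc_overall,
      auc_type = "pooled",
      n = nrow(x$fold_assignments), seed = x$seed)
  }
}
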