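# Independent reference implementations used to cross-check the package.
# These are deliberately naive (plain recursion, double loops, exhaustive
# enumeration) and share no code with the implementations they check.

# Semantic value by direct recursion on the definition, no memoization.
oracle_ancestors <- function(ont, d) {
  anc <- d
  repeat {
    more <- setdiff(unique(unlist(ont$parents[anc], use.names = FALSE)), anc)
    if (length(more) == 0) return(anc)
    anc <- c(anc, more)
  }
}

oracle_contrib <- function(ont, d, t) {
  if (t == d) return(1)
  anc <- oracle_ancestors(ont, d)
  kids <- intersect(ont$children[[t]], anc)
  if (length(kids) == 0) return(0)
  0.5 * max(sapply(kids, function(k) oracle_contrib(ont, d, k)))
}

oracle_semantic_value <- function(ont, d) {
  sum(sapply(oracle_ancestors(ont, d), function(t) oracle_contrib(ont, d, t)))
}

oracle_semantic_similarity <- function(ont, diseases) {
  q <- length(diseases)
  S <- matrix(0, q, q)
  for (i in seq_len(q)) for (j in seq_len(q)) {
    if (i == j) { S[i, j] <- 1; next }
    Ti <- oracle_ancestors(ont, diseases[i])
    Tj <- oracle_ancestors(ont, diseases[j])
    shared <- intersect(Ti, Tj)
    num <- sum(sapply(shared, function(t)
      oracle_contrib(ont, diseases[i], t) +
        oracle_contrib(ont, diseases[j], t)))
    den <- oracle_semantic_value(ont, diseases[i]) +
      oracle_semantic_value(ont, diseases[j])
    S[i, j] <- num / den
  }
  S
}

# Functional similarity straight from the best-match definition.
oracle_lfs <- function(Y, S) {
  p <- nrow(Y)
  out <- diag(1, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    Di <- which(Y[i, ] == 1)
    Dj <- which(Y[j, ] == 1)
    if (length(Di) == 0 || length(Dj) == 0) { out[i, j] <- 0; next }
    s1 <- sum(sapply(Dj, function(d) max(S[d, Di])))
    s2 <- sum(sapply(Di, function(d) max(S[d, Dj])))
    out[i, j] <- (s1 + s2) / (length(Di) + length(Dj))
  }
  out
}

oracle_gip <- function(P, scale = 1) {
  n <- nrow(P)
  beta <- scale / mean(rowSums(P^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    K[i, j] <- exp(-beta * sum((P[i, ] - P[j, ])^2))
  }
  K
}

oracle_cosine <- function(P) {
  n <- nrow(P)
  C <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ni <- sqrt(sum(P[i, ]^2))
    nj <- sqrt(sum(P[j, ]^2))
    C[i, j] <- if (ni == 0 || nj == 0) 0 else sum(P[i, ] * P[j, ]) / (ni * nj)
  }
  C
}

# Exact simplex-constrained least squares min ||x - v||^2 by enumerating
# active sets: for each candidate support solve the equality-constrained
# problem in closed form and keep the feasible minimizer.
oracle_simplex_qp <- function(v) {
  n <- length(v)
  best <- NULL
  best_val <- Inf
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    x <- rep(0, n)
    x[S] <- v[S] + (1 - sum(v[S])) / length(S)
    if (any(x[S] < -1e-12)) next
    val <- sum((x - v)^2)
    if (val < best_val - 1e-15) {
      best_val <- val
      best <- pmax(x, 0)
    }
  }
  best
}

# Exhaustive concordant-pair AUC with half-credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# Random rooted DAG over n terms: term k picks parents among terms 1..k-1.
random_ontology <- function(n = 10, p_edge = 0.4) {
  parent <- character(0)
  child <- character(0)
  ids <- paste0("T", seq_len(n))
  for (k in 2:n) {
    np <- max(1, rbinom(1, k - 1, p_edge))
    for (pa in sample(seq_len(k - 1), min(np, k - 1))) {
      parent <- c(parent, ids[pa])
      child <- c(child, ids[k])
    }
  }
  disease_ontology(data.frame(parent_id = parent, child_id = child))
}

random_assoc <- function(p = 8, q = 6, density = 0.3) {
  Y <- matrix(rbinom(p * q, 1, density), p, q)
  association_matrix(Y, paste0("L", seq_len(p)), paste0("D", seq_len(q)))
}

random_view <- function(n, side = "disease", name = "noise") {
  M <- matrix(runif(n * n), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  similarity_view(M, side, name)
}

random_view_set <- function(p, q, n_disease = 3, n_lncrna = 3) {
  structure(list(
    disease_views = stats::setNames(
      lapply(seq_len(n_disease), function(i) random_view(q, "disease")),
      paste0("d", seq_len(n_disease))),
    lncrna_views = stats::setNames(
      lapply(seq_len(n_lncrna), function(i) random_view(p, "lncrna")),
      paste0("l", seq_len(n_lncrna)))), class = "view_set")
}

small_sim <- function(seed = 1) {
  simulate_lda_data(synthetic_config(
    n_lncrnas = 20, n_diseases = 15, n_blocks = 3,
    density_in = 0.5, density_out = 0.05, seed = seed))
}

expect_row_stochastic <- function(S, tol = 1e-8) {
  expect_true(all(S >= 0))
  expect_lt(max(abs(rowSums(S) - 1)), tol)
}
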