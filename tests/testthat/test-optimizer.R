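test_that("graph Laplacian symmetrizes and conserves mass", {
  expect_equal(build_laplacian(diag(3)), matrix(0, 3, 3))
  expect_equal(build_laplacian(matrix(1, 2, 2)),
    rbind(c(1, -1), c(-1, 1)))
  withr::with_seed(3, {
    S <- matrix(runif(49), 7, 7)
    L <- build_laplacian(S)
    expect_equal(L, t(L))
    expect_equal(rowSums(L), rep(0, 7))
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-12)
  })
  expect_error(build_laplacian(matrix(0, 2, 3)),
    class = "mcglda_error_shape")
})

test_that("simplex projection matches the exact QP on enumerated supports", {
  expect_equal(simplex_project(c(0.2, 0.3, 0.5)), c(0.2, 0.3, 0.5))
  expect_equal(simplex_project(c(0.5, 0.5, 0.5)), rep(1 / 3, 3))
  expect_equal(simplex_project(c(2, 0, 0)), c(1, 0, 0))
  expect_error(simplex_project(numeric(0)), class = "mcglda_error_shape")
  withr::with_seed(5, {
    for (rep in 1:50) {
      v <- runif(5, -2, 2)
      expect_equal(simplex_project(v), oracle_simplex_qp(v),
        tolerance = 1e-10)
    }
  })
})

test_that("consensus graph rows solve their per-row simplex QP", {
  withr::with_seed(9, {
    views <- list(a = random_view(3), b = random_view(3))
    w <- c(0.4, 0.6)
    F <- matrix(rnorm(12), 4, 3)  # disease side: 3 columns of F
    S <- update_consensus_graph(views, w, F, smooth_weight = 0.3, "disease")
    expect_row_stochastic(S)
    A <- 0.4 * unclass(views$a) + 0.6 * unclass(views$b)
    for (i in 1:3) {
      h <- colSums((F[, i] - F)^2)
      expect_equal(S[i, ], oracle_simplex_qp(A[i, ] - 0.15 * h),
        tolerance = 1e-6, ignore_attr = TRUE)
    }
    # smooth_weight 0 and a row-stochastic view: projection is a no-op
    V <- similarity_view(diag(3), "disease", "id")
    expect_equal(
      update_consensus_graph(list(V), 1, F, 0, "disease"), diag(3),
      ignore_attr = TRUE)
    # smooth_weight 0, multiple views: row-wise projection of the average
    S0 <- update_consensus_graph(views, w, F, 0, "disease")
    for (i in 1:3) {
      expect_equal(S0[i, ], simplex_project(A[i, ]), ignore_attr = TRUE)
    }
  })
  expect_error(
    update_consensus_graph(list(random_view(3)), 1, matrix(0, 2, 2), 0,
      "disease"),
    class = "mcglda_error_shape")
})

test_that("view weights recover the generating view and break ties evenly", {
  expect_equal(update_view_weights(diag(3), list(v = random_view(3))),
    c(v = 1))
  withr::with_seed(21, {
    views <- list(a = random_view(6), b = random_view(6), c = random_view(6))
    w <- update_view_weights(unclass(views$b), views)
    expect_equal(unname(w), c(0, 1, 0), tolerance = 1e-4)
    # identical views: flat objective, uniform start stays uniform
    same <- list(x = views$a, y = views$a, z = views$a)
    expect_equal(unname(update_view_weights(unclass(views$a), same)),
      rep(1 / 3, 3), tolerance = 1e-10)
  })
  expect_error(update_view_weights(diag(2), list()),
    class = "mcglda_error_config")
})

test_that("Sylvester solve satisfies its defining equation", {
  withr::with_seed(25, {
    Y <- matrix(rbinom(30, 1, 0.3), 6, 5)
    SL <- t(apply(matrix(runif(36), 6, 6), 1, simplex_project))
    SD <- t(apply(matrix(runif(25), 5, 5), 1, simplex_project))
    L_SL <- build_laplacian(SL)
    L_SD <- build_laplacian(SD)
    F <- solve_label_matrix(L_SL, L_SD, Y, 0.1, 0.1)
    resid <- (2 * 0.1 * L_SL + diag(6)) %*% F + 2 * 0.1 * F %*% L_SD - Y
    expect_lt(norm(resid, "F") / norm(Y, "F"), 1e-8)
    # alpha = beta = 0 reduces to F = Y
    expect_identical(solve_label_matrix(L_SL, L_SD, Y, 0, 0), Y)
    # single-node graphs: zero Laplacians, scalar identity
    expect_equal(
      solve_label_matrix(matrix(0, 1, 1), matrix(0, 1, 1),
        matrix(1, 1, 1), 0.5, 0.5),
      matrix(1, 1, 1))
    expect_error(
      solve_label_matrix(matrix(c(0, 1, 0, 0), 2, 2), matrix(0, 2, 2),
        matrix(0, 2, 2), 0.1, 0.1),
      class = "mcglda_error_numeric")
  })
})

test_that("objective matches the pairwise-difference form of the trace terms", {
  withr::with_seed(29, {
    p <- 6; q <- 5
    views <- random_view_set(p, q)
    Y <- matrix(rbinom(p * q, 1, 0.3), p, q)
    F <- matrix(rnorm(p * q), p, q)
    SD <- t(apply(matrix(runif(q * q), q, q), 1, simplex_project))
    SL <- t(apply(matrix(runif(p * p), p, p), 1, simplex_project))
    wD <- simplex_project(runif(3)); wL <- simplex_project(runif(3))
    alpha <- 0.3; beta <- 0.7
    obj <- objective_value(SD, SL, wD, wL, F, views, Y, alpha, beta)
    # trace identity: 2a*Tr(F L_SD F') = a * sum_ij ||F_:i - F_:j||^2 SD_ij
    tr_D <- sum(sapply(seq_len(q), function(i) sum(sapply(seq_len(q),
      function(j) sum((F[, i] - F[, j])^2) * SD[i, j]))))
    tr_L <- sum(sapply(seq_len(p), function(i) sum(sapply(seq_len(p),
      function(j) sum((F[i, ] - F[j, ])^2) * SL[i, j]))))
    AD <- Reduce(`+`, Map(`*`, lapply(views$disease_views, unclass), wD))
    AL <- Reduce(`+`, Map(`*`, lapply(views$lncrna_views, unclass), wL))
    expect_equal(obj,
      sum((SD - AD)^2) + sum((SL - AL)^2) + alpha * tr_D + beta * tr_L +
        sum((F - Y)^2))
    expect_gte(obj, 0)
    # all misfit terms vanish at the weighted averages with F = Y, a = b = 0
    expect_equal(objective_value(AD, AL, wD, wL, Y, views, Y, 0, 0), 0)
  })
})

test_that("alternating fit decouples at zero smoothness and keeps constraints", {
  withr::with_seed(31, {
    p <- 10; q <- 8
    views <- random_view_set(p, q)
    Y <- matrix(rbinom(p * q, 1, 0.3), p, q)
    assoc <- association_matrix(Y)
    fit <- mcgl_fit(assoc, views, mcgl_params(alpha = 0, beta = 0))
    expect_equal(fit$F, assoc$Y)
    expect_row_stochastic(fit$SD)
    expect_row_stochastic(fit$SL)
    expect_equal(sum(fit$wD), 1, tolerance = 1e-10)
    expect_equal(sum(fit$wL), 1, tolerance = 1e-10)
    expect_true(all(fit$wD >= 0) && all(fit$wL >= 0))
    # SD rows are projections of the weighted view average in effect when
    # the graph was last updated (uniform under a single outer sweep)
    fit1 <- mcgl_fit(assoc, views,
      mcgl_params(alpha = 0, beta = 0, max_outer = 1))
    AD <- Reduce(`+`, Map(`*`, lapply(views$disease_views, unclass),
      rep(1 / 3, 3)))
    expect_equal(fit1$SD, t(apply(AD, 1, simplex_project)),
      ignore_attr = TRUE)
  })
})

test_that("objective trace is non-increasing on random instances", {
  withr::with_seed(37, {
    for (rep in 1:5) {
      p <- 20; q <- 15
      views <- random_view_set(p, q)
      Y <- matrix(rbinom(p * q, 1, 0.2), p, q)
      if (sum(Y) == 0) Y[1, 1] <- 1
      fit <- mcgl_fit(association_matrix(Y), views,
        mcgl_params(alpha = 0.05, beta = 0.05))
      tr <- fit$objective_trace$objective
      expect_true(all(diff(tr) <= 1e-8 * pmax(abs(tr[-length(tr)]), 1)))
    }
  })
})

test_that("fit is equivariant under joint lncRNA permutation", {
  withr::with_seed(41, {
    p <- 12; q <- 9
    views <- random_view_set(p, q)
    Y <- matrix(rbinom(p * q, 1, 0.3), p, q)
    fit <- mcgl_fit(association_matrix(Y), views,
      mcgl_params(alpha = 0.01, beta = 0.01))
    perm <- sample(p)
    pviews <- views
    pviews$lncrna_views <- lapply(views$lncrna_views, function(V)
      similarity_view(unclass(V)[perm, perm], "lncrna",
        attr(V, "view_name")))
    pfit <- mcgl_fit(association_matrix(Y[perm, ]), pviews,
      mcgl_params(alpha = 0.01, beta = 0.01))
    expect_equal(pfit$F, fit$F[perm, ], ignore_attr = TRUE,
      tolerance = 1e-8)
  })
})

test_that("predictions converge to the known labels as smoothing vanishes", {
  withr::with_seed(43, {
    p <- 10; q <- 8
    views <- random_view_set(p, q)
    Y <- matrix(rbinom(p * q, 1, 0.3), p, q)
    fit <- mcgl_fit(association_matrix(Y), views,
      mcgl_params(alpha = 1e-12, beta = 1e-12))
    expect_lt(norm(fit$F - Y, "F"), 1e-8)
  })
})

test_that("tidy and glance expose ranked predictions and fit metadata", {
  sim <- small_sim()
  fit <- mcgl_fit(sim$assoc, ontology = sim$ontology)
  td <- tidy(fit)
  expect_equal(nrow(td), 20 * 15)
  expect_true(all(diff(td$score) <= 0))
  expect_equal(sum(td$known), sum(sim$assoc$Y))
  g <- glance(fit)
  expect_true(g$converged)
  expect_equal(g$objective,
    utils::tail(fit$objective_trace$objective, 1))
})
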