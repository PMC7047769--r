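test_that("semantic value follows the 0.5-decay ancestor sum", {
  # isolated term: only itself contributes
  ont <- disease_ontology(terms = "solo")
  expect_equal(semantic_value(ont, "solo"), 1.0)

  # chain root -> a -> d: 1 + 0.5 + 0.25
  chain <- disease_ontology(data.frame(
    parent_id = c("root", "a"), child_id = c("a", "d")))
  expect_equal(semantic_value(chain, "d"), 1.75)

  # diamond: both mid nodes contribute 0.5, the root max(0.25, 0.25)
  diamond <- disease_ontology(data.frame(
    parent_id = c("root", "root", "a", "b"),
    child_id = c("a", "b", "d", "d")))
  expect_equal(semantic_value(diamond, "d"), 2.25)

  expect_error(semantic_value(chain, "nope"),
    class = "mcglda_error_identifier")
})

test_that("cyclic or self-looping edge lists are rejected", {
  expect_error(
    disease_ontology(data.frame(parent_id = c("a", "b"),
      child_id = c("b", "a"))),
    class = "mcglda_error_ontology")
  expect_error(
    disease_ontology(data.frame(parent_id = "a", child_id = "a")),
    class = "mcglda_error_parse")
})

test_that("semantic value is monotone under added ancestors", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      ont <- random_ontology(8)
      d <- sample(ont$terms, 1)
      base <- semantic_value(ont, d)
      # graft a new root above one current root
      roots <- ont$terms[lengths(ont$parents[ont$terms]) == 0]
      edges <- data.frame(
        parent_id = c(rep(names(ont$children), lengths(ont$children)), "NEW"),
        child_id = c(unlist(ont$children, use.names = FALSE), roots[1]))
      grown <- disease_ontology(edges)
      expect_gte(semantic_value(grown, d), base)
    }
  })
})

test_that("disease semantic similarity matches hand values and the naive oracle", {
  sib <- disease_ontology(data.frame(
    parent_id = c("root", "root"), child_id = c("d1", "d2")))
  S <- disease_semantic_similarity(sib, c("d1", "d2"))
  expect_equal(S[1, 1], 1.0)
  expect_equal(S[1, 2], 1 / 3)  # shared root: (0.5+0.5)/(1.5+1.5)

  # disjoint rooted components share no ancestors
  two <- disease_ontology(data.frame(
    parent_id = c("r1", "r2"), child_id = c("d1", "d2")))
  expect_equal(disease_semantic_similarity(two, c("d1", "d2"))[1, 2], 0.0)

  withr::with_seed(11, {
    for (rep in 1:5) {
      ont <- random_ontology(10)
      ds <- sample(ont$terms, 6)
      S <- disease_semantic_similarity(ont, ds)
      expect_equal(unclass(S), oracle_semantic_similarity(ont, ds),
        ignore_attr = TRUE)
    }
  })
})

test_that("functional similarity matches hand values and the naive oracle", {
  sib <- disease_ontology(data.frame(
    parent_id = c("root", "root"), child_id = c("d1", "d2")))
  S <- disease_semantic_similarity(sib, c("d1", "d2"))
  assoc <- association_matrix(diag(2), c("l1", "l2"), c("d1", "d2"))
  LFS <- lncrna_functional_similarity(assoc, S)
  expect_equal(LFS[1, 1], 1.0)
  expect_equal(LFS[1, 2], 1 / 3)  # (S(d1,d2) + S(d2,d1)) / 2

  withr::with_seed(13, {
    for (rep in 1:5) {
      ont <- random_ontology(10)
      ds <- sample(ont$terms, 6)
      S <- disease_semantic_similarity(ont, ds)
      assoc <- random_assoc(8, 6)
      got <- lncrna_functional_similarity(assoc, S)
      expect_equal(unclass(got), oracle_lfs(assoc$Y, unclass(S)),
        ignore_attr = TRUE, tolerance = 1e-12)
    }
  })
})

test_that("GIP kernel matches the bandwidth-normalized Gaussian", {
  assoc <- association_matrix(diag(2))
  K <- gip_similarity(assoc, "lncrna", bandwidth_scale = 1)
  expect_equal(K[1, 2], exp(-2))  # mean profile norm 1, squared distance 2
  expect_equal(K[1, 1], 1.0)

  withr::with_seed(17, {
    assoc <- random_assoc(8, 6)
    for (side in c("lncrna", "disease")) {
      K <- gip_similarity(assoc, side, bandwidth_scale = 1.7)
      P <- if (side == "lncrna") assoc$Y else t(assoc$Y)
      expect_equal(unclass(K), oracle_gip(P, 1.7), ignore_attr = TRUE)
      expect_true(all(K > 0))
    }
  })
  empty <- association_matrix(matrix(0, 2, 2))
  expect_error(gip_similarity(empty, "lncrna"),
    class = "mcglda_error_degenerate")
})

test_that("cosine similarity matches hand values and handles zero profiles", {
  Y <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0))
  assoc <- association_matrix(Y)
  C <- cosine_similarity_matrix(assoc, "lncrna")
  expect_equal(C[1, 2], 1 / sqrt(2))
  expect_equal(C[1, 3], 0)  # zero-norm profile: off-diagonal forced to 0
  expect_equal(diag(unclass(C)), rep(1, 3), ignore_attr = TRUE)

  withr::with_seed(19, {
    assoc <- random_assoc(8, 6)
    expect_equal(unclass(cosine_similarity_matrix(assoc, "disease")),
      oracle_cosine(t(assoc$Y)), ignore_attr = TRUE)
  })
})

test_that("profile-based views are equivariant under entity permutation", {
  withr::with_seed(23, {
    assoc <- random_assoc(8, 6, density = 0.4)
    perm <- sample(8)
    permuted <- association_matrix(assoc$Y[perm, ],
      assoc$lncrna_ids[perm], assoc$disease_ids)
    for (f in list(
      function(a) gip_similarity(a, "lncrna"),
      function(a) cosine_similarity_matrix(a, "lncrna"))) {
      expect_equal(unclass(f(permuted)), unclass(f(assoc))[perm, perm],
        ignore_attr = TRUE)
    }
  })
})

test_that("build_views assembles consistent views and isolates Y dependence", {
  sim <- small_sim()
  vs <- build_views(sim$assoc, sim$ontology)
  expect_named(vs$disease_views, c("semantic", "gip", "cosine"))
  expect_named(vs$lncrna_views, c("functional", "gip", "cosine"))
  for (V in c(vs$disease_views, vs$lncrna_views)) {
    expect_lt(max(abs(V - t(V))), 1e-10)
    expect_true(all(V >= 0 & V <= 1))
    expect_equal(max(abs(diag(unclass(V)) - 1)), 0)
  }
  expect_true(all(vapply(vs$disease_views, nrow, 1L) == 15))
  expect_true(all(vapply(vs$lncrna_views, nrow, 1L) == 20))

  expect_warning(vs2 <- build_views(sim$assoc, ontology = NULL),
    class = "mcglda_warning_no_ontology")
  expect_length(vs2$disease_views, 2)
  expect_length(vs2$lncrna_views, 2)

  # removing one association must change only Y-derived views
  Y2 <- sim$assoc$Y
  Y2[which(Y2 == 1)[1]] <- 0
  vs3 <- build_views(association_matrix(Y2, sim$assoc$lncrna_ids,
    sim$assoc$disease_ids), sim$ontology)
  expect_equal(unclass(vs3$disease_views$semantic),
    unclass(vs$disease_views$semantic))
  expect_false(isTRUE(all.equal(unclass(vs3$lncrna_views$gip),
    unclass(vs$lncrna_views$gip))))
})
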