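#' Configuration for the planted-block synthetic generator
#'
#' The generator emulates curated lncRNA-disease association data at the
#' scale of the largest public catalog snapshot used in this field
#' (hundreds of lncRNAs and diseases, ~600 associations, ~1% density),
#' with planted block structure: lncRNAs and diseases are assigned to
#' latent disease-module blocks and associations are drawn with a higher
#' probability inside matched blocks than across them. Diseases in the
#' same block also share a deep common ancestor in the generated ontology,
#' so the semantic view carries the same block signal.
#'
#' Defaults: 285 lncRNAs x 226 diseases in 5 blocks with `density_in =
#' 0.0442` and `density_out = 0.001` give an expected positive count of
#' about 621. `dag_depth = 4` and `dag_branching = 3` give a shallow
#' MeSH-like hierarchy.
#'
#' @param n_lncrnas,n_diseases Entity counts.
#' @param n_blocks Number of planted blocks; at most
#'   `min(n_lncrnas, n_diseases)`.
#' @param density_in,density_out Association probability for matched /
#'   unmatched block pairs; `0 <= density_out < density_in <= 1`.
#' @param dag_depth Length of each block's ancestor chain in the ontology.
#' @param dag_branching Number of deepest chain levels a disease may attach
#'   to (attachment level is sampled uniformly among them).
#' @param seed Integer master seed. The ontology uses `seed` directly and
#'   the association draws use `seed + 1`, so either part can be
#'   regenerated independently.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_lncrnas = 285, n_diseases = 226,
                             n_blocks = 5, density_in = 0.0442,
                             density_out = 0.001, dag_depth = 4,
                             dag_branching = 3, seed = 42) {
  stopifnot(n_lncrnas >= 1, n_diseases >= 1,
    n_blocks >= 1, n_blocks <= min(n_lncrnas, n_diseases),
    density_out >= 0, density_out < density_in, density_in <= 1,
    dag_depth >= 1, dag_branching >= 1)
  structure(
    list(n_lncrnas = n_lncrnas, n_diseases = n_diseases,
      n_blocks = n_blocks, density_in = density_in,
      density_out = density_out, dag_depth = dag_depth,
      dag_branching = dag_branching, seed = as.integer(seed)),
    class = "synthetic_config")
}

block_of <- function(n, n_blocks) ((seq_len(n) - 1L) %% n_blocks) + 1L

#' Generate a block-structured disease ontology
#'
#' Builds a rooted DAG in which each block has its own chain of
#' `dag_depth` internal ancestor terms hanging off a single root; each
#' disease term attaches as a child of one of the `dag_branching` deepest
#' nodes of its block's chain. Diseases in the same block therefore share
#' deep ancestors while cross-block diseases share only the root, so
#' within-block semantic similarity exceeds cross-block similarity.
#'
#' @param config A [synthetic_config()].
#' @return A [disease_ontology()] whose terms include `D1 ... Dq` plus the
#'   internal block-chain terms and the root.
#' @export
generate_ontology <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  q <- config$n_diseases
  blocks <- block_of(q, config$n_blocks)
  diseases <- paste0("D", seq_len(q))
  depth <- config$dag_depth
  parent <- character(0)
  child <- character(0)
  for (b in seq_len(config$n_blocks)) {
    chain <- paste0("B", b, "_L", seq_len(depth))
    parent <- c(parent, "ROOT", chain[-depth])
    child <- c(child, chain)
  }
  levels_avail <- max(1L, depth - config$dag_branching + 1L):depth
  attach_level <- withr::with_seed(config$seed,
    sample(levels_avail, q, replace = TRUE))
  parent <- c(parent, paste0("B", blocks, "_L", attach_level))
  child <- c(child, diseases)
  disease_ontology(data.frame(parent_id = parent, child_id = child))
}

#' Generate a planted-block association matrix
#'
#' lncRNAs and diseases are assigned to blocks round-robin (so block sizes
#' are reproducible and near-equal); each lncRNA-disease pair is an
#' association with probability `density_in` when their blocks match and
#' `density_out` otherwise. All-zero rows and columns are permitted — they
#' occur in real association catalogs at these densities.
#'
#' @param config A [synthetic_config()].
#' @return A list: `assoc` (an `lda_assoc`), `lncrna_blocks` and
#'   `disease_blocks` (integer ground-truth block labels, for recovery
#'   tests).
#' @export
generate_associations <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- config$n_lncrnas
  q <- config$n_diseases
  lb <- block_of(p, config$n_blocks)
  db <- block_of(q, config$n_blocks)
  prob <- ifelse(outer(lb, db, "=="), config$density_in, config$density_out)
  Y <- withr::with_seed(config$seed + 1L,
    matrix(stats::rbinom(p * q, 1, prob), p, q))
  assoc <- association_matrix(Y, paste0("L", seq_len(p)),
    paste0("D", seq_len(q)))
  list(assoc = assoc, lncrna_blocks = lb, disease_blocks = db)
}

#' Generate a full synthetic dataset (ontology + associations)
#'
#' @param config A [synthetic_config()].
#' @return A list: `assoc`, `ontology`, `lncrna_blocks`, `disease_blocks`,
#'   `config`.
#' @export
simulate_lda_data <- function(config = synthetic_config()) {
  gen <- generate_associations(config)
  list(assoc = gen$assoc, ontology = generate_ontology(config),
    lncrna_blocks = gen$lncrna_blocks, disease_blocks = gen$disease_blocks,
    config = config)
}
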