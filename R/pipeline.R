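#' Assemble a pseudogene-miRNA dataset
#'
#' Bundles the three raw inputs and fixes the canonical node order:
#' pseudogenes sorted lexicographically, then miRNAs sorted
#' lexicographically. Every matrix downstream is indexed by this order, so
#' file loading order never affects results.
#'
#' @param expression Expression tibble (`id` + tissue columns), e.g. from
#'   [read_expression_tsv()].
#' @param sequences Sequence tibble (`id`, `sequence`), e.g. from
#'   [read_fasta()].
#' @param associations Tibble of known pairs (`pseudogene`, `mirna`).
#' @return Object of class `pmgae_dataset` with sorted id universes
#'   `p_ids` and `m_ids`.
#' @export
pma_dataset <- function(expression, sequences, associations) {
  stopifnot(names(expression)[1] == "id",
            all(c("id", "sequence") %in% names(sequences)),
            all(c("pseudogene", "mirna") %in% names(associations)))
  if (anyDuplicated(expression$id)) stop("duplicate pseudogene ids", call. = FALSE)
  if (anyDuplicated(sequences$id)) stop("duplicate miRNA ids", call. = FALSE)
  p_ids <- sort(expression$id)
  m_ids <- sort(sequences$id)
  associations <- dplyr::distinct(associations[c("pseudogene", "mirna")])
  unknown <- setdiff(associations$pseudogene, p_ids)
  if (length(unknown) > 0) stop("association references unknown pseudogene: ",
                                unknown[1], call. = FALSE)
  unknown <- setdiff(associations$mirna, m_ids)
  if (length(unknown) > 0) stop("association references unknown miRNA: ",
                                unknown[1], call. = FALSE)
  structure(
    list(
      expression = dplyr::arrange(expression, .data$id),
      sequences = dplyr::arrange(sequences, .data$id),
      associations = associations,
      p_ids = p_ids, m_ids = m_ids
    ),
    class = "pmgae_dataset"
  )
}

#' @export
print.pmgae_dataset <- function(x, ...) {
  cat("pseudogene-miRNA dataset\n")
  cat("  pseudogenes:", length(x$p_ids),
      "(", ncol(x$expression) - 1, "tissues )\n")
  cat("  miRNAs:", length(x$m_ids), "\n")
  cat("  known associations:", nrow(x$associations), "\n")
  invisible(x)
}

#' Run the feature, fusion and embedding stages
#'
#' The front half of the pipeline: per-node-set similarity matrices
#' (generalized Jaccard, cosine, Pearson on normalized expression / k-mer
#' profiles, zero-filled from the GIP kernel), cross-diffusion fusion,
#' stacked-auto-encoder reduction, dual standardization, feature stacking,
#' and graph-auto-encoder training on the bipartite adjacency. The
#' association pairs used here define both the GIP kernel and the adjacency,
#' so passing a masked pair set keeps held-out edges out of every training
#' structure.
#'
#' @param dataset A `pmgae_dataset`.
#' @param config A `pmgae_config`. `sae_dim` must be smaller than either
#'   node-set size.
#' @param pairs Association pairs to train on; defaults to all of
#'   `dataset$associations`.
#' @return Object of class `pmgae_embedding`: embedding matrix `Z`
#'   (`(n_p + n_m) x gae_hidden[2]`, id rownames), the fitted `gae`, the
#'   stacked feature matrix `X`, fused per-set similarities, and the
#'   association matrix `PMA` actually used.
#' @export
embed_nodes <- function(dataset, config = run_config(), pairs = NULL) {
  stopifnot(inherits(dataset, "pmgae_dataset"))
  validate_config(config)
  pairs <- pairs %||% dataset$associations
  PMA <- association_matrix(pairs, dataset$p_ids, dataset$m_ids)
  expr_mat <- matrix_from_wide(normalize_expression(dataset$expression))
  expr_mat <- expr_mat[dataset$p_ids, , drop = FALSE]
  kmers <- kmer_profile(dataset$sequences, k = config$k)
  p_sims <- node_similarities(expr_mat, PMA, axis = "rows")
  m_sims <- node_similarities(kmers, PMA, axis = "cols")
  fuse_set <- function(sims) {
    snf_fuse(sims, K = min(config$snf_neighbors, nrow(sims[[1]]) - 1),
             t_max = config$snf_iterations)
  }
  fused_p <- fuse_set(p_sims)
  fused_m <- fuse_set(m_sims)
  PSr <- sae_reduce(fused_p, out_dim = config$sae_dim,
                    seed = derive_seed(config$random_seed, 1),
                    hidden = config$sae_hidden, epochs = config$sae_epochs,
                    lr = config$sae_lr)
  MSr <- sae_reduce(fused_m, out_dim = config$sae_dim,
                    seed = derive_seed(config$random_seed, 2),
                    hidden = config$sae_hidden, epochs = config$sae_epochs,
                    lr = config$sae_lr)
  X <- build_node_features(dual_standardize(PSr), dual_standardize(MSr))
  A <- build_adjacency(PMA)
  gae <- train_gae(A, X, hidden = config$gae_hidden, lr = config$gae_lr,
                   epochs = config$gae_epochs,
                   pos_weight = config$gae_pos_weight,
                   seed = derive_seed(config$random_seed, 3))
  structure(
    list(Z = gae$Z, gae = gae, X = X,
         fused = list(pseudogene = fused_p, mirna = fused_m),
         PMA = PMA),
    class = "pmgae_embedding"
  )
}

#' @export
print.pmgae_embedding <- function(x, ...) {
  cat("node embedding\n")
  cat("  nodes:", nrow(x$Z), " dim:", ncol(x$Z), "\n")
  cat("  feature dim:", ncol(x$X), " edges:", sum(x$PMA), "\n")
  invisible(x)
}
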