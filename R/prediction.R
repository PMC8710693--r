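#' Pair feature vectors from node embeddings
#'
#' A pseudogene-miRNA pair is represented by concatenating the two node
#' embeddings, pseudogene half first. Concatenation (rather than Hadamard
#' product or averaging) preserves which side of the bipartite relation each
#' node sits on.
#'
#' @param Z Embedding matrix with id rownames (all nodes).
#' @param pairs Tibble with `pseudogene` and `mirna` columns.
#' @return Numeric matrix `(n_pairs, 2 * ncol(Z))`.
#' @export
pair_features <- function(Z, pairs) {
  stopifnot(is.matrix(Z), !is.null(rownames(Z)),
            all(c("pseudogene", "mirna") %in% names(pairs)))
  missing_id <- setdiff(c(pairs$pseudogene, pairs$mirna), rownames(Z))
  if (length(missing_id) > 0) {
    stop("id not present in embedding: ", missing_id[1], call. = FALSE)
  }
  cbind(Z[pairs$pseudogene, , drop = FALSE], Z[pairs$mirna, , drop = FALSE])
}

#' Train the gradient-boosted tree pair classifier
#'
#' Fits an additive tree ensemble with logistic loss and L2 leaf-weight
#' regularization on labeled pair feature vectors. Single-threaded and
#' seeded, so scores are reproducible bit-for-bit.
#'
#' @param features Numeric matrix of pair features (see [pair_features()]).
#' @param labels 0/1 vector, both classes present.
#' @param seed Integer seed.
#' @param nrounds,max_depth,eta,lambda Ensemble size, tree depth, shrinkage
#'   and L2 penalty (defaults 100, 6, 0.3, 1).
#' @return Object of class `pmgae_classifier`.
#' @export
train_classifier <- function(features, labels, seed = 1, nrounds = 100,
                             max_depth = 6, eta = 0.3, lambda = 1) {
  stopifnot(is.matrix(features), nrow(features) == length(labels),
            all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  dtrain <- xgboost::xgb.DMatrix(features, label = labels, nthread = 1)
  params <- list(
    objective = "binary:logistic",
    max_depth = max_depth, eta = eta, lambda = lambda,
    nthread = 1, seed = as.integer(seed %% 2147483647)
  )
  booster <- withr::with_seed(seed, {
    xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                       verbose = 0)
  })
  structure(
    list(booster = booster, n_features = ncol(features), nrounds = nrounds,
         max_depth = max_depth, eta = eta, lambda = lambda, seed = seed),
    class = "pmgae_classifier"
  )
}

#' Score pairs with a trained classifier
#'
#' @param classifier A `pmgae_classifier` from [train_classifier()].
#' @param features Pair feature matrix with the training feature width.
#' @return Numeric vector of probability-like scores in `[0, 1]`.
#' @export
predict_scores <- function(classifier, features) {
  stopifnot(inherits(classifier, "pmgae_classifier"), is.matrix(features))
  if (ncol(features) != classifier$n_features) {
    stop("feature width mismatch: got ", ncol(features), ", expected ",
         classifier$n_features, call. = FALSE)
  }
  as.numeric(stats::predict(classifier$booster,
                            xgboost::xgb.DMatrix(features, nthread = 1)))
}

#' Rank candidate miRNAs for a query pseudogene
#'
#' Scores every (query, candidate) pair and returns the top of the list,
#' sorted by descending score with ties broken lexicographically by candidate
#' id — so the ranking does not depend on candidate input order.
#'
#' @param classifier A trained `pmgae_classifier`.
#' @param Z Embedding matrix covering the query and all candidates.
#' @param query_pseudogene Single pseudogene id.
#' @param candidate_mirnas Character vector of candidate miRNA ids.
#' @param top_k Rows to return (default 15); all candidates if fewer.
#' @return Tibble with columns `rank`, `id`, `score`.
#' @export
rank_candidates <- function(classifier, Z, query_pseudogene, candidate_mirnas,
                            top_k = 15) {
  if (length(candidate_mirnas) == 0) stop("empty candidate list", call. = FALSE)
  stopifnot(length(query_pseudogene) == 1)
  pairs <- tibble::tibble(pseudogene = query_pseudogene, mirna = candidate_mirnas)
  scores <- predict_scores(classifier, pair_features(Z, pairs))
  out <- tibble::tibble(id = candidate_mirnas, score = scores)
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$id)
  out <- utils::head(out, top_k)
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}
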