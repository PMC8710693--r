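#' Run configuration
#'
#' Bundles every tunable parameter of the pipeline. Defaults follow the
#' published setup: 3-mers, a 64/32-unit GCN encoder trained for 8,000 epochs
#' at learning rate 0.001, 128-dimensional stacked-auto-encoder outputs, and
#' five-fold cross-validation.
#'
#' @param k k-mer size for miRNA sequence profiles (default 3, giving 4^3 =
#'   64 features).
#' @param snf_neighbors Neighborhood size cap for the local affinity matrix of
#'   the fusion step; the effective K is `min(snf_neighbors, n - 1)`.
#' @param snf_iterations Maximum cross-diffusion iterations.
#' @param sae_dim Bottleneck width of the stacked auto-encoder (per node set).
#' @param sae_hidden Width of the stacked auto-encoder's outer hidden layers.
#' @param sae_epochs,sae_lr Training length and Adam step size for the
#'   stacked auto-encoder.
#' @param gae_hidden Integer vector of length 2: GCN encoder layer widths.
#' @param gae_lr,gae_epochs Adam step size and training length for the graph
#'   auto-encoder.
#' @param gae_pos_weight Positive-class weight in the reconstruction loss;
#'   `NULL` (default) uses #zeros / #ones of the adjacency, 1 recovers the
#'   unweighted cross-entropy.
#' @param xgb_nrounds,xgb_max_depth,xgb_eta,xgb_lambda Gradient-boosted tree
#'   ensemble hyperparameters (trees, depth, shrinkage, L2 leaf penalty).
#' @param neg_ratio Sampled negatives per known positive (>= 1).
#' @param cv_folds Number of cross-validation folds.
#' @param cv_repeats Independent cross-validation repetitions.
#' @param mask_test_edges If `TRUE` (default) test-fold positives are removed
#'   from the association matrix before the feature/embedding stages of each
#'   fold, so no test edge leaks into training structures.
#' @param random_seed Master seed; every randomized stage derives its own
#'   sub-seed from it.
#'
#' @return A list of class `pmgae_config`.
#' @examples
#' cfg <- run_config(gae_epochs = 500, random_seed = 7)
#' cfg$gae_hidden
#' @export
run_config <- function(k = 3,
                       snf_neighbors = 20,
                       snf_iterations = 20,
                       sae_dim = 128,
                       sae_hidden = 256,
                       sae_epochs = 200,
                       sae_lr = 0.01,
                       gae_hidden = c(64, 32),
                       gae_lr = 0.001,
                       gae_epochs = 8000,
                       gae_pos_weight = NULL,
                       xgb_nrounds = 100,
                       xgb_max_depth = 6,
                       xgb_eta = 0.3,
                       xgb_lambda = 1,
                       neg_ratio = 1,
                       cv_folds = 5,
                       cv_repeats = 5,
                       mask_test_edges = TRUE,
                       random_seed = 1) {
  cfg <- list(
    k = k, snf_neighbors = snf_neighbors, snf_iterations = snf_iterations,
    sae_dim = sae_dim, sae_hidden = sae_hidden, sae_epochs = sae_epochs,
    sae_lr = sae_lr, gae_hidden = gae_hidden, gae_lr = gae_lr,
    gae_epochs = gae_epochs, gae_pos_weight = gae_pos_weight,
    xgb_nrounds = xgb_nrounds, xgb_max_depth = xgb_max_depth,
    xgb_eta = xgb_eta, xgb_lambda = xgb_lambda,
    neg_ratio = neg_ratio, cv_folds = cv_folds, cv_repeats = cv_repeats,
    mask_test_edges = isTRUE(mask_test_edges),
    random_seed = random_seed
  )
  validate_config(cfg)
  structure(cfg, class = "pmgae_config")
}

validate_config <- function(cfg) {
  int_fields <- c(
    "k", "snf_neighbors", "snf_iterations", "sae_dim", "sae_hidden",
    "sae_epochs", "gae_epochs", "xgb_nrounds", "xgb_max_depth",
    "cv_folds", "cv_repeats"
  )
  for (f in int_fields) {
    v <- cfg[[f]]
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != round(v)) {
      stop("config field '", f, "' must be a positive integer", call. = FALSE)
    }
  }
  if (length(cfg$gae_hidden) != 2 || any(cfg$gae_hidden < 1) ||
      any(cfg$gae_hidden != round(cfg$gae_hidden))) {
    stop("gae_hidden must be two positive integers", call. = FALSE)
  }
  for (f in c("sae_lr", "gae_lr", "xgb_eta")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("config field '", f, "' must be > 0", call. = FALSE)
    }
  }
  if (!is.numeric(cfg$neg_ratio) || cfg$neg_ratio < 1) {
    stop("neg_ratio must be >= 1", call. = FALSE)
  }
  if (!is.null(cfg$gae_pos_weight) && cfg$gae_pos_weight <= 0) {
    stop("gae_pos_weight must be > 0 or NULL", call. = FALSE)
  }
  invisible(cfg)
}
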