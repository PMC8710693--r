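#' Sample negative (non-associated) pairs
#'
#' Uniform sample without replacement from the zero cells of the association
#' matrix; unknown pairs are treated as potential negatives.
#'
#' @param PMA Binary association matrix with dimnames.
#' @param ratio Negatives per positive (>= 1); the sample size is
#'   `round(ratio * sum(PMA))`.
#' @param seed Integer seed; the same seed reproduces the same sample.
#' @param exclude_rows Optional pseudogene ids whose cells are excluded from
#'   sampling (used by the case-study protocol).
#' @return Tibble with `pseudogene` and `mirna` columns, disjoint from the
#'   positives.
#' @export
sample_negatives <- function(PMA, ratio = 1, seed = 1, exclude_rows = NULL) {
  stopifnot(is.matrix(PMA), all(PMA %in% c(0, 1)), ratio >= 1)
  zeros <- which(PMA == 0, arr.ind = TRUE)
  if (!is.null(exclude_rows)) {
    zeros <- zeros[!(rownames(PMA)[zeros[, 1]] %in% exclude_rows), , drop = FALSE]
  }
  need <- round(ratio * sum(PMA))
  if (need > nrow(zeros)) {
    if (ratio > 1) {
      stop("requested ", need, " negatives but only ", nrow(zeros),
           " non-associated cells available", call. = FALSE)
    }
    warning("only ", nrow(zeros), " non-associated cells available; ",
            "using all of them", call. = FALSE)
    need <- nrow(zeros)
  }
  take <- withr::with_seed(seed, sample.int(nrow(zeros), need))
  picked <- zeros[take, , drop = FALSE]
  tibble::tibble(
    pseudogene = rownames(PMA)[picked[, 1]],
    mirna = colnames(PMA)[picked[, 2]]
  )
}

#' Stratified k-fold assignment
#'
#' Positives and negatives are each shuffled and dealt into k near-equal
#' parts, so every fold keeps the global class ratio up to rounding.
#'
#' @param labels 0/1 vector.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector in `1..k`, one test-fold assignment per element.
#' @export
kfold_split <- function(labels, k = 5, seed = 1) {
  stopifnot(k >= 2, all(labels %in% c(0, 1)))
  if (sum(labels == 1) < k || sum(labels == 0) < k) {
    stop("need at least k = ", k, " samples of each class", call. = FALSE)
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in c(0, 1)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Thresholded confusion-matrix metrics
#'
#' Accuracy, sensitivity, specificity, precision and the Matthews
#' correlation coefficient at a fixed score threshold. A metric whose
#' denominator is zero is reported as 0 with a warning.
#'
#' @param labels 0/1 vector.
#' @param scores Scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5; scores >= threshold are
#'   called positive).
#' @return One-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `mcc`.
#' @export
confusion_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores), length(labels) > 0,
            all(labels %in% c(0, 1)))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " has zero denominator; reported as 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  tibble::tibble(
    accuracy = (tp + tn) / length(labels),
    sensitivity = safe_div(tp, tp + fn, "sensitivity"),
    specificity = safe_div(tn, tn + fp, "specificity"),
    precision = safe_div(tp, tp + fp, "precision"),
    mcc = safe_div(tp * tn - fp * fn, mcc_den, "MCC")
  )
}

#' Area under the ROC and precision-recall curves
#'
#' AUC via the Mann-Whitney rank statistic (midranks, so ties count one
#' half); AUPR by step integration of the precision-recall curve over
#' descending unique score thresholds.
#'
#' @param labels 0/1 vector containing both classes.
#' @param scores Numeric scores.
#' @return Named numeric vector `c(auc = ..., aupr = ...)`.
#' @export
auc_aupr <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes required for AUC/AUPR", call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # PR step integration: one point per unique threshold, descending
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  keep <- c(diff(sc) != 0, TRUE) # last index of each tie group
  tp <- cumsum(lab)[keep]
  fp <- cumsum(1 - lab)[keep]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  aupr <- sum(diff(c(0, recall)) * precision)
  c(auc = auc, aupr = aupr)
}

#' Run repeated k-fold cross-validation over the whole pipeline
#'
#' For every repetition, negatives are sampled once (`config$neg_ratio` per
#' positive) and positives and negatives are dealt into `config$cv_folds`
#' stratified folds. Each fold then reruns the full pipeline from scratch on
#' the training data only: with `config$mask_test_edges = TRUE` (default) the
#' test-fold positives are removed from the association matrix before the
#' GIP-filling, fusion and graph-auto-encoder stages, so no test edge leaks
#' into any training structure. The classifier is trained on training pairs
#' and scored on the held-out fold.
#'
#' @param dataset A `pmgae_dataset` (see [pma_dataset()]).
#' @param config A `pmgae_config`; `cv_repeats` controls the number of
#'   independent repetitions.
#' @return Object of class `pmgae_cv`: `per_fold` metrics tibble,
#'   `predictions` (per-pair labels and scores for ROC/PR plotting), mean
#'   and sd rows, the config and the master seed.
#' @export
run_cv <- function(dataset, config = run_config()) {
  stopifnot(inherits(dataset, "pmgae_dataset"))
  validate_config(config)
  PMA_full <- association_matrix(dataset$associations, dataset$p_ids, dataset$m_ids)
  per_fold <- list()
  predictions <- list()
  for (r in seq_len(config$cv_repeats)) {
    rep_seed <- derive_seed(config$random_seed, 100 + r)
    negatives <- sample_negatives(PMA_full, config$neg_ratio, seed = rep_seed)
    pairs <- dplyr::bind_rows(
      dplyr::mutate(dataset$associations, label = 1),
      dplyr::mutate(negatives, label = 0)
    )
    fold <- kfold_split(pairs$label, k = config$cv_folds, seed = rep_seed + 1L)
    for (f in seq_len(config$cv_folds)) {
      test <- pairs[fold == f, ]
      train <- pairs[fold != f, ]
      graph_pairs <- if (config$mask_test_edges) {
        train[train$label == 1, c("pseudogene", "mirna")]
      } else {
        dataset$associations
      }
      fold_cfg <- config
      fold_cfg$random_seed <- derive_seed(rep_seed, f)
      emb <- embed_nodes(dataset, fold_cfg, pairs = graph_pairs)
      clf <- train_classifier(
        pair_features(emb$Z, train), train$label,
        seed = derive_seed(fold_cfg$random_seed, 9),
        nrounds = config$xgb_nrounds, max_depth = config$xgb_max_depth,
        eta = config$xgb_eta, lambda = config$xgb_lambda
      )
      scores <- predict_scores(clf, pair_features(emb$Z, test))
      cm <- suppressWarnings(confusion_metrics(test$label, scores))
      aa <- auc_aupr(test$label, scores)
      per_fold[[length(per_fold) + 1]] <- dplyr::bind_cols(
        tibble::tibble(repeat_id = r, fold = f), cm,
        tibble::tibble(auc = aa[["auc"]], aupr = aa[["aupr"]])
      )
      predictions[[length(predictions) + 1]] <- dplyr::mutate(
        test, score = scores, repeat_id = r, fold = f
      )
    }
  }
  per_fold <- dplyr::bind_rows(per_fold)
  metric_cols <- setdiff(names(per_fold), c("repeat_id", "fold"))
  structure(
    list(
      per_fold = per_fold,
      predictions = dplyr::bind_rows(predictions),
      mean = dplyr::summarise(per_fold, dplyr::across(dplyr::all_of(metric_cols), mean)),
      sd = dplyr::summarise(per_fold, dplyr::across(dplyr::all_of(metric_cols), stats::sd)),
      config = config,
      seed = config$random_seed
    ),
    class = "pmgae_cv"
  )
}

#' Leave-pseudogene-out case study
#'
#' Every association involving a held-out pseudogene is dropped from
#' training (including the graph fed to the embedding stages); the model is
#' trained once on the remainder and all miRNAs are ranked for each held-out
#' pseudogene.
#'
#' @param dataset A `pmgae_dataset`.
#' @param holdout_pseudogenes Character vector of pseudogene ids to hold out.
#' @param top_k Ranking length per pseudogene (default 15).
#' @param config A `pmgae_config`.
#' @return Tibble with columns `pseudogene`, `rank`, `mirna`, `score`.
#' @export
case_study <- function(dataset, holdout_pseudogenes, top_k = 15,
                       config = run_config()) {
  stopifnot(inherits(dataset, "pmgae_dataset"))
  missing_id <- setdiff(holdout_pseudogenes, dataset$p_ids)
  if (length(missing_id) > 0) {
    stop("holdout pseudogene not in dataset: ", missing_id[1], call. = FALSE)
  }
  train_pos <- dplyr::filter(dataset$associations,
                             !(.data$pseudogene %in% holdout_pseudogenes))
  emb <- embed_nodes(dataset, config, pairs = train_pos)
  negatives <- sample_negatives(
    emb$PMA, config$neg_ratio, seed = derive_seed(config$random_seed, 41),
    exclude_rows = holdout_pseudogenes
  )
  train <- dplyr::bind_rows(
    dplyr::mutate(train_pos, label = 1),
    dplyr::mutate(negatives, label = 0)
  )
  clf <- train_classifier(
    pair_features(emb$Z, train), train$label,
    seed = derive_seed(config$random_seed, 42),
    nrounds = config$xgb_nrounds, max_depth = config$xgb_max_depth,
    eta = config$xgb_eta, lambda = config$xgb_lambda
  )
  purrr::map_dfr(holdout_pseudogenes, function(pg) {
    rk <- rank_candidates(clf, emb$Z, pg, dataset$m_ids, top_k = top_k)
    tibble::tibble(pseudogene = pg, rank = rk$rank, mirna = rk$id, score = rk$score)
  })
}
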