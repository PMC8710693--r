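test_that("negative sampling is sized, disjoint from positives, and seeded", {
  ds <- tiny_dataset()
  PMA <- association_matrix(ds$associations, ds$p_ids, ds$m_ids)
  neg <- sample_negatives(PMA, ratio = 1, seed = 3)
  expect_equal(nrow(neg), sum(PMA))
  expect_equal(nrow(dplyr::inner_join(neg, ds$associations,
                                      by = c("pseudogene", "mirna"))), 0)
  expect_identical(neg, sample_negatives(PMA, ratio = 1, seed = 3))
  expect_false(identical(neg, sample_negatives(PMA, ratio = 1, seed = 4)))

  tiny <- matrix(c(1, 1, 1, 0), 2, 2,
                 dimnames = list(c("p1", "p2"), c("m1", "m2")))
  expect_warning(one <- sample_negatives(tiny, ratio = 1, seed = 1),
                 "using all")
  expect_equal(nrow(one), 1)               # the single zero cell
  expect_equal(tiny[cbind(one$pseudogene, one$mirna)], 0, ignore_attr = TRUE)
  expect_error(sample_negatives(tiny, ratio = 2, seed = 1), "available")
})

test_that("k-fold split is stratified, disjoint, and exhaustive", {
  labels <- rep(c(1, 0), each = 10)
  fold <- kfold_split(labels, k = 5, seed = 2)
  for (f in 1:5) {
    expect_equal(sum(fold == f & labels == 1), 2)
    expect_equal(sum(fold == f & labels == 0), 2)
  }
  expect_equal(sort(unique(fold)), 1:5)
  expect_length(fold, 20)

  withr::with_seed(6, {
    lab <- rbinom(83, 1, 0.45)
    fr <- kfold_split(lab, k = 5, seed = 9)
    glob <- mean(lab)
    for (f in 1:5) {
      expect_lt(abs(mean(lab[fr == f]) - glob), 1 / 5 + 0.05)
    }
  })
  expect_error(kfold_split(c(1, 1, 0, 0), k = 5), "at least k")
})

test_that("confusion metrics match hand-computed confusion tables", {
  perfect <- confusion_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_equal(unname(unlist(perfect)), rep(1, 5))
  # TP=1, FP=1, TN=1, FN=1
  m <- confusion_metrics(c(1, 0, 0, 1), c(0.9, 0.9, 0.1, 0.1))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$mcc, 0)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$precision, 0.5)
  expect_warning(
    allpos <- confusion_metrics(c(1, 1, 0, 0), c(0.9, 0.9, 0.9, 0.9)),
    "zero denominator"
  )
  expect_equal(allpos$specificity, 0)
})

test_that("AUC and AUPR match closed forms and the ordered-pair oracle", {
  expect_equal(unname(auc_aupr(c(1, 1, 0), c(0.9, 0.8, 0.1))["auc"]), 1)
  expect_equal(unname(auc_aupr(c(1, 0, 1, 0), rep(0.5, 4))["auc"]), 0.5)
  ex <- auc_aupr(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))
  expect_equal(unname(ex["auc"]), oracle_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)))
  expect_equal(unname(ex["auc"]), 3 / 4)
  expect_error(auc_aupr(c(1, 1), c(0.3, 0.4)), "both classes")

  # perfect separation puts AUPR at 1 as well
  expect_equal(unname(auc_aupr(c(0, 1), c(0.2, 0.9))["aupr"]), 1)

  withr::with_seed(31, {
    for (rep in 1:40) {
      n <- sample(4:8, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      scores <- round(runif(n), 2)   # rounding forces occasional ties
      expect_equal(unname(auc_aupr(labels, scores)["auc"]),
                   oracle_auc(labels, scores), tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(37, {
    labels <- rbinom(60, 1, 0.4)
    labels[1:2] <- c(0, 1)
    scores <- runif(60)
    ours <- unname(auc_aupr(labels, scores)["auc"])
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("cross-validation reports are complete, consistent and reproducible", {
  ds <- tiny_dataset()
  cfg <- fast_config(sae_epochs = 15, gae_epochs = 50)
  cv <- run_cv(ds, cfg)
  expect_s3_class(cv, "pmgae_cv")
  expect_equal(nrow(cv$per_fold), cfg$cv_folds)
  expect_equal(glance(cv)$auc, mean(cv$per_fold$auc), tolerance = 1e-12)
  expect_true(all(cv$per_fold$auc >= 0 & cv$per_fold$auc <= 1))
  expect_true(all(cv$per_fold$mcc >= -1 & cv$per_fold$mcc <= 1))
  # every labeled pair is scored exactly once per repeat
  expect_equal(nrow(cv$predictions), 2 * nrow(ds$associations))
  expect_equal(sum(cv$predictions$label), nrow(ds$associations))
  cv2 <- run_cv(ds, cfg)
  expect_equal(cv$per_fold, cv2$per_fold, tolerance = 1e-12)
})

test_that("case study masks holdout pseudogenes and returns seeded rankings", {
  ds <- tiny_dataset(seed = 13, n_p = 24, n_m = 16, n_edges = 80)
  holdout <- unique(ds$associations$pseudogene)[1:2]
  cfg <- fast_config(sae_epochs = 15, gae_epochs = 50)
  rk <- case_study(ds, holdout, top_k = 5, config = cfg)
  expect_equal(nrow(rk), 2 * 5)
  expect_equal(unique(rk$pseudogene), holdout)
  expect_equal(rk$rank[rk$pseudogene == holdout[1]], 1:5)
  expect_true(all(rk$score >= 0 & rk$score <= 1))
  rk2 <- case_study(ds, holdout, top_k = 5, config = cfg)
  expect_identical(rk, rk2)
  expect_error(case_study(ds, "nope", config = cfg), "not in dataset")
})

test_that("fold-masked adjacency never contains test positives", {
  ds <- tiny_dataset()
  PMA <- association_matrix(ds$associations, ds$p_ids, ds$m_ids)
  neg <- sample_negatives(PMA, 1, seed = 5)
  pairs <- dplyr::bind_rows(dplyr::mutate(ds$associations, label = 1),
                            dplyr::mutate(neg, label = 0))
  fold <- kfold_split(pairs$label, 5, seed = 5)
  for (f in 1:5) {
    train_pos <- pairs[fold != f & pairs$label == 1, c("pseudogene", "mirna")]
    test_pos <- pairs[fold == f & pairs$label == 1, c("pseudogene", "mirna")]
    A <- association_matrix(train_pos, ds$p_ids, ds$m_ids)
    hits <- A[cbind(test_pos$pseudogene, test_pos$mirna)]
    expect_equal(sum(hits), 0)
    expect_equal(nrow(dplyr::inner_join(train_pos, test_pos,
                                        by = c("pseudogene", "mirna"))), 0)
  }
})
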