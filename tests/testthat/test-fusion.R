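test_that("weight matrix has half diagonal and unit row sums", {
  S <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  P <- snf_weight_matrix(S)
  expect_equal(unname(P), matrix(0.5, 2, 2))
  S2 <- random_similarity(9, seed = 4)
  P2 <- snf_weight_matrix(S2)
  expect_equal(unname(diag(P2)), rep(0.5, 9))
  expect_equal(unname(rowSums(P2)), rep(1, 9), tolerance = 1e-12)
  S3 <- diag(3); dimnames(S3) <- list(letters[1:3], letters[1:3])
  expect_error(snf_weight_matrix(S3), "'a' has all-zero off-diagonal")
})

test_that("local affinity keeps the top-K neighbors renormalized to one", {
  n <- 6
  S <- matrix(1, n, n); diag(S) <- 1
  rownames(S) <- colnames(S) <- paste0("x", 1:n)
  L <- snf_local_affinity(S, K = n - 1)
  expect_equal(unname(L[1, -1]), rep(1 / (n - 1), n - 1))
  expect_equal(L[1, 1], 0)

  S3 <- matrix(c(1, 0.6, 0.2,
                 0.6, 1, 0.3,
                 0.2, 0.3, 1), 3, 3, byrow = TRUE,
               dimnames = list(letters[1:3], letters[1:3]))
  L1 <- snf_local_affinity(S3, K = 1)
  expect_equal(unname(L1[1, ]), c(0, 1, 0))   # top-1 neighbor of a is b

  Sr <- random_similarity(8, seed = 2)
  for (K in c(1, 3, 7)) {
    expect_equal(unname(rowSums(snf_local_affinity(Sr, K))), rep(1, 8),
                 tolerance = 1e-12)
  }
  expect_error(snf_local_affinity(Sr, 0), "K must be")
  expect_error(snf_local_affinity(Sr, 8), "K must be")
})

test_that("fusing identical views with no iterations returns the rescaled weight matrix", {
  S <- random_similarity(5, seed = 6)
  out <- snf_fuse(list(S, S, S), K = 4, t_max = 0)
  P <- snf_weight_matrix(S)
  d <- diag(P)
  expected <- P / sqrt(outer(d, d))
  expected <- (expected + t(expected)) / 2
  diag(expected) <- 1
  expect_equal(out, expected, tolerance = 1e-12)
})

test_that("one fusion iteration matches the long-hand cross-diffusion oracle", {
  withr::with_seed(13, {
    S1 <- random_similarity(4, seed = 21)
    S2 <- random_similarity(4, seed = 22)
    out <- snf_fuse(list(S1, S2), K = 2, t_max = 1)
    expect_equal(unname(out), oracle_snf_one_iter(list(S1, S2), K = 2),
                 tolerance = 1e-12)
  })
})

test_that("fused output is symmetric, non-negative, unit-diagonal and permutation-equivariant", {
  S1 <- random_similarity(7, seed = 31)
  S2 <- random_similarity(7, seed = 32)
  S3 <- random_similarity(7, seed = 33)
  out <- snf_fuse(list(S1, S2, S3), K = 3, t_max = 15)
  expect_equal(out, t(out))
  expect_true(all(out >= 0))
  expect_equal(unname(diag(out)), rep(1, 7))

  perm <- withr::with_seed(5, sample(7))
  outp <- snf_fuse(list(S1[perm, perm], S2[perm, perm], S3[perm, perm]),
                   K = 3, t_max = 15)
  expect_equal(unname(outp), unname(out[perm, perm]), tolerance = 1e-9)

  S2b <- S2; rownames(S2b) <- colnames(S2b) <- paste0("z", 1:7)
  expect_error(snf_fuse(list(S1, S2b)), "id mismatch")
})

test_that("auto-encoder reduction is deterministic, shaped, and learns", {
  S <- random_similarity(50, seed = 44)
  codes <- sae_reduce(S, out_dim = 12, seed = 3, hidden = 32, epochs = 80)
  expect_equal(dim(codes), c(50, 12))
  expect_equal(rownames(codes), rownames(S))
  codes2 <- sae_reduce(S, out_dim = 12, seed = 3, hidden = 32, epochs = 80)
  expect_identical(unclass(codes), unclass(codes2))
  lh <- attr(codes, "loss_history")
  expect_lt(lh[length(lh)], lh[1])
  expect_error(sae_reduce(S, out_dim = 50), "out_dim")
})

test_that("full-width linear auto-encoder reaches near-zero reconstruction", {
  S <- random_similarity(12, seed = 45)
  codes <- sae_reduce(S, out_dim = 11, seed = 1, hidden = 24, epochs = 1500,
                      lr = 0.01, activation = "linear")
  lh <- attr(codes, "loss_history")
  expect_lt(lh[length(lh)], 1e-4)
})

test_that("dual standardization averages z-scores and robust scores per column", {
  M <- matrix(c(-1, 1), 2, 1)
  # mean 0, population sd 1, median 0, IQR 1 -> both scalers are identity
  expect_equal(dual_standardize(M), M)
  # re-standardizing a symmetric column changes nothing
  expect_equal(dual_standardize(dual_standardize(M)), M)
  Mc <- matrix(3, 4, 2)
  expect_equal(dual_standardize(Mc), Mc * 0)
  expect_error(dual_standardize(matrix(1, 1, 3)), ">= 2 rows")

  withr::with_seed(19, {
    X <- matrix(rnorm(40), 8, 5)
    perm <- sample(8)
    expect_equal(dual_standardize(X[perm, ]), dual_standardize(X)[perm, ],
                 tolerance = 1e-12)
    # hand-check one column against the stated conventions
    x <- X[, 2]
    z <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
    r <- (x - median(x)) / diff(quantile(x, c(0.25, 0.75), names = FALSE))
    expect_equal(dual_standardize(X)[, 2], (z + r) / 2, tolerance = 1e-12)
  })
})

test_that("node feature stacking keeps order and validates widths", {
  PS <- matrix(1:6, 2, 3, dimnames = list(c("p1", "p2"), NULL))
  MS <- matrix(7:9, 1, 3, dimnames = list("m1", NULL))
  X <- build_node_features(PS, MS)
  expect_equal(dim(X), c(3, 3))
  expect_equal(rownames(X), c("p1", "p2", "m1"))
  expect_equal(X["m1", ], c(7, 8, 9))
  expect_error(build_node_features(PS, matrix(0, 1, 4)), "column mismatch")
})
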