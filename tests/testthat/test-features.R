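test_that("k-mer frequencies follow the sliding-window definition", {
  v <- kmer_frequencies("AGGUUCCAGG", k = 3)
  expect_length(v, 64)
  expect_equal(names(v)[1:3], c("AAA", "AAC", "AAG"))
  expect_equal(v[["AGG"]], 2 / 8)   # two AGG windows of eight
  expect_equal(sum(v), 1)
  single <- kmer_frequencies("AAA", k = 3)
  expect_equal(single[["AAA"]], 1)
  expect_equal(sum(single != 0), 1)
  expect_error(kmer_frequencies("AG", k = 3), "shorter")
})

test_that("k-mer rows sum to one for random sequences of any length >= k", {
  withr::with_seed(42, {
    for (i in 1:20) {
      len <- sample(3:40, 1)
      s <- paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
      expect_equal(sum(kmer_frequencies(s, 3)), 1, tolerance = 1e-9)
    }
  })
})

test_that("expression normalization is per-column min-max with degenerate guard", {
  tbl <- tibble::tibble(id = c("p1", "p2", "p3"),
                        a = c(0, 5, 10), b = c(3, 3, 3), c = c(2, 4, 2))
  out <- normalize_expression(tbl)
  expect_equal(out$a, c(0, 0.5, 1))
  expect_equal(out$b, c(0, 0, 0))
  expect_equal(out$c, c(0, 1, 0))
  expect_error(normalize_expression(tibble::tibble(id = "p", a = -1)),
               "non-negative")
})

test_that("generalized Jaccard handles identity, disjoint support and zero rows", {
  M <- rbind(a = c(1, 2), b = c(2, 1), c = c(1, 2), d = c(0, 0), e = c(0, 0))
  S <- jaccard_similarity(M)
  expect_equal(S["a", "c"], 1)            # identical rows
  expect_equal(S["a", "b"], 0.5)          # sum min 2 / sum max 4
  expect_equal(S["d", "e"], 1)            # both all-zero
  S2 <- jaccard_similarity(rbind(a = c(1, 0), b = c(0, 1)))
  expect_equal(S2["a", "b"], 0)           # disjoint supports
  expect_error(jaccard_similarity(rbind(c(-1, 2), c(1, 1))), "negative")
})

test_that("cosine and Pearson similarities match their rescaled raw forms", {
  S <- cosine_similarity(rbind(a = c(1, 1), b = c(2, 2), c = c(1, 0), d = c(0, 1)))
  expect_equal(S["a", "b"], 1)                       # parallel: raw 1
  expect_equal(S["c", "d"], 0.5)                     # orthogonal: raw 0
  expect_equal(S["a", "c"], (1 / sqrt(2) + 1) / 2)   # raw 1/sqrt(2)

  P <- pearson_similarity(rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2, 4)))
  expect_equal(P["a", "a"], 1)
  expect_equal(P["a", "b"], 0)                       # raw -1, rescaled 0
  expect_equal(P["a", "c"], (cor(c(1, 2, 3), c(1, 2, 4)) + 1) / 2)
})

test_that("similarity operations agree with brute-force double loops", {
  withr::with_seed(11, {
    for (rep in 1:3) {
      M <- matrix(runif(36), 6, 6)
      rownames(M) <- paste0("r", 1:6)
      J <- jaccard_similarity(M)
      expect_equal(unname(J), oracle_jaccard(M), tolerance = 1e-12)
      Cs <- cosine_similarity(M)
      expect_equal(unname(Cs)[lower.tri(Cs)],
                   ((oracle_cosine_raw(M) + 1) / 2)[lower.tri(Cs)],
                   tolerance = 1e-12)
      Pr <- pearson_similarity(M)
      expect_equal(unname(Pr)[lower.tri(Pr)],
                   ((oracle_pearson_raw(M) + 1) / 2)[lower.tri(Pr)],
                   tolerance = 1e-12)
    }
  })
})

test_that("finalized similarity matrices are symmetric, unit-diagonal, in [0,1]", {
  withr::with_seed(3, {
    M <- matrix(runif(60), 10, 6)
    rownames(M) <- paste0("r", 1:10)
    for (S in list(jaccard_similarity(M), cosine_similarity(M),
                   pearson_similarity(M))) {
      expect_equal(S, t(S))
      expect_equal(unname(diag(S)), rep(1, 10))
      expect_true(all(S >= 0 & S <= 1))
    }
  })
})

test_that("GIP kernel matches the interaction-profile definition", {
  A <- diag(2)
  dimnames(A) <- list(c("p1", "p2"), c("m1", "m2"))
  G <- gip_kernel(A, "rows")
  expect_equal(G["p1", "p2"], exp(-2))   # |IP|^2 = 1 each, gamma = 1
  expect_equal(unname(diag(G)), c(1, 1))

  withr::with_seed(8, {
    B <- matrix(rbinom(35, 1, 0.3), 7, 5,
                dimnames = list(paste0("p", 1:7), paste0("m", 1:5)))
    G2 <- gip_kernel(B, "rows")
    expect_equal(unname(G2), oracle_gip(B), tolerance = 1e-12)
    expect_equal(G2, t(G2))
    Gc <- gip_kernel(B, "cols")
    expect_equal(unname(Gc), oracle_gip(B, "cols"), tolerance = 1e-12)
    # identical profiles give similarity exactly 1
    B2 <- B; B2[2, ] <- B2[1, ]
    expect_equal(gip_kernel(B2, "rows")[1, 2], 1)
  })
})

test_that("GIP kernel commutes with simultaneous row permutations", {
  withr::with_seed(9, {
    A <- matrix(rbinom(40, 1, 0.4), 8, 5,
                dimnames = list(paste0("p", 1:8), paste0("m", 1:5)))
    perm <- sample(8)
    G <- gip_kernel(A, "rows")
    Gp <- gip_kernel(A[perm, ], "rows")
    expect_equal(unname(Gp), unname(G[perm, perm]), tolerance = 1e-12)
  })
})

test_that("zero filling takes the GIP value exactly where similarity is zero", {
  ids <- c("a", "b", "c")
  S <- matrix(c(1, 0, 0.4, 0, 1, 0, 0.4, 0, 1), 3, 3, dimnames = list(ids, ids))
  G <- matrix(0.3, 3, 3, dimnames = list(ids, ids)); diag(G) <- 1
  out <- fill_zeros(S, G)
  expect_equal(out["a", "b"], 0.3)
  expect_equal(out["a", "c"], 0.4)
  expect_equal(out, t(out))
  expect_equal(fill_zeros(G, S * 0 + 0.9), G)   # no zeros -> unchanged
  allz <- S * 0
  expect_equal(fill_zeros(allz, G), G)          # all zeros -> G
  G2 <- G; rownames(G2) <- c("a", "b", "z"); colnames(G2) <- rownames(G2)
  expect_error(fill_zeros(S, G2), "id mismatch")
})

test_that("association matrix is indexed by sorted universes", {
  pairs <- tibble::tibble(pseudogene = c("pb", "pa"), mirna = c("m2", "m1"))
  A <- association_matrix(pairs, c("pb", "pa"), c("m2", "m1"))
  expect_equal(rownames(A), c("pa", "pb"))
  expect_equal(colnames(A), c("m1", "m2"))
  expect_equal(sum(A), 2)
  expect_equal(A["pa", "m1"], 1)
  expect_equal(A["pa", "m2"], 0)
})
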