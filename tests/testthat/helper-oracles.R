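# Independent brute-force oracles. These deliberately re-derive each quantity
# with plain double loops / exhaustive enumeration, never by calling the
# package's own implementation path.

oracle_jaccard <- function(M) {
  n <- nrow(M)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (k in seq_len(ncol(M))) {
      num <- num + min(M[i, k], M[j, k])
      den <- den + max(M[i, k], M[j, k])
    }
    S[i, j] <- if (den == 0) 1 else num / den
  }
  S
}

oracle_cosine_raw <- function(M) {
  n <- nrow(M)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    na <- sqrt(sum(M[i, ]^2)); nb <- sqrt(sum(M[j, ]^2))
    S[i, j] <- if (na == 0 || nb == 0) 0 else sum(M[i, ] * M[j, ]) / (na * nb)
  }
  S
}

oracle_pearson_raw <- function(M) {
  n <- nrow(M)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- M[i, ]; y <- M[j, ]
    sx <- sd(x) * sqrt((length(x) - 1) / length(x))
    sy <- sd(y) * sqrt((length(y) - 1) / length(y))
    S[i, j] <- if (sx == 0 || sy == 0) 0 else {
      mean(x * y) - mean(x) * mean(y)
    } / (sx * sy)
  }
  S
}

oracle_gip <- function(A, axis = "rows") {
  P <- if (axis == "rows") A else t(A)
  n <- nrow(P)
  sq <- numeric(n)
  for (i in seq_len(n)) sq[i] <- sum(P[i, ]^2)
  gamma <- if (mean(sq) == 0) 1 else 1 / mean(sq)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    G[i, j] <- exp(-gamma * sum((P[i, ] - P[j, ])^2))
  }
  G
}

# dense re-statement of the two-layer graph convolution
oracle_encode <- function(X, An, W0, W1) {
  H <- An %*% X %*% W0
  H[H < 0] <- 0
  An %*% H %*% W1
}

# AUC as the fraction of correctly ordered positive/negative pairs
# (ties count one half)
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# one cross-diffusion pass written out long-hand from the update equations
oracle_snf_one_iter <- function(S_list, K) {
  n <- nrow(S_list[[1]])
  nv <- length(S_list)
  weight <- function(S) {
    P <- matrix(0, n, n)
    for (i in seq_len(n)) {
      off <- sum(S[i, ]) - S[i, i]
      for (j in seq_len(n)) P[i, j] <- if (i == j) 0.5 else S[i, j] / (2 * off)
    }
    P
  }
  local_aff <- function(S) {
    L <- matrix(0, n, n)
    for (i in seq_len(n)) {
      s <- S[i, ]; s[i] <- -Inf
      nb <- order(s, decreasing = TRUE)[seq_len(K)]
      for (j in nb) L[i, j] <- S[i, j] / sum(S[i, nb])
    }
    L
  }
  renorm <- function(P) {
    Q <- matrix(0, n, n)
    for (i in seq_len(n)) {
      off <- sum(P[i, ]) - P[i, i]
      for (j in seq_len(n)) Q[i, j] <- if (i == j) 0.5 else P[i, j] / (2 * off)
    }
    Q
  }
  P <- lapply(S_list, weight)
  L <- lapply(S_list, local_aff)
  Pn <- vector("list", nv)
  for (v in seq_len(nv)) {
    others <- Reduce(`+`, P[-v]) / (nv - 1)
    Pv <- L[[v]] %*% others %*% t(L[[v]])
    Pn[[v]] <- renorm((Pv + t(Pv)) / 2)
  }
  fused <- Reduce(`+`, Pn) / nv
  d <- diag(fused)
  fused <- fused / sqrt(outer(d, d))
  fused <- (fused + t(fused)) / 2
  diag(fused) <- 1
  fused
}

random_similarity <- function(n, seed = 1) {
  withr::with_seed(seed, {
    S <- matrix(runif(n * n, 0.05, 1), n, n)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    rownames(S) <- colnames(S) <- sprintf("n%02d", seq_len(n))
    S
  })
}
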