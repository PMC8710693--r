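#' Cross-diffusion weight matrix
#'
#' Full-kernel transition matrix of the fusion step:
#' `P(i, j) = S(i, j) / (2 * sum_{k != i} S(i, k))` off-diagonal and
#' `P(i, i) = 1/2`, so every row sums to exactly 1 and half of each node's
#' mass stays on itself.
#'
#' @param S Symmetric non-negative similarity matrix with id rownames.
#' @return Row-stochastic matrix of the same shape.
#' @export
snf_weight_matrix <- function(S) {
  assert_named_square(S)
  assert_symmetric(S)
  off <- rowSums(S) - diag(S)
  if (any(off <= 0)) {
    stop("node '", rownames(S)[which(off <= 0)[1]],
         "' has all-zero off-diagonal similarities", call. = FALSE)
  }
  P <- S / (2 * off)
  diag(P) <- 0.5
  P
}

#' Local (KNN-restricted) affinity matrix
#'
#' Keeps, per row, only the K most similar neighbors (self excluded) and
#' renormalizes them to sum to 1; everything else is zero. Restricting
#' diffusion to local neighborhoods is what makes the fusion robust to the
#' noisy long-range entries of each similarity measure.
#'
#' @param S Symmetric similarity matrix with id rownames.
#' @param K Neighborhood size, `1 <= K <= n - 1`. Ties at the cutoff are
#'   broken by row order (deterministic).
#' @return Matrix with rows summing to 1 over each node's neighbor set.
#' @export
snf_local_affinity <- function(S, K) {
  assert_named_square(S)
  n <- nrow(S)
  if (K < 1 || K > n - 1) stop("K must be in [1, n-1]", call. = FALSE)
  L <- matrix(0, n, n, dimnames = dimnames(S))
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- -Inf
    nb <- order(s, decreasing = TRUE)[seq_len(K)]
    tot <- sum(S[i, nb])
    if (tot <= 0) stop("node '", rownames(S)[i], "' has no positive neighbor mass",
                       call. = FALSE)
    L[i, nb] <- S[i, nb] / tot
  }
  L
}

#' Fuse similarity matrices by non-linear cross-diffusion
#'
#' Each view v starts from its weight matrix `P^(v)` ([snf_weight_matrix()])
#' and local affinity `L^(v)` ([snf_local_affinity()]); the update
#' `P_{t+1}^(v) = L^(v) %*% mean_{k != v}(P_t^(k)) %*% t(L^(v))` diffuses each
#' view across the average of the others. After each update the matrix is
#' symmetrized (`(P + t(P)) / 2`) and renormalized to the weight-matrix form
#' (off-diagonal mass 1/2, diagonal 1/2), which keeps every view
#' row-stochastic across iterations and makes the diffusion converge instead
#' of flattening. The fused result is the mean of the final views, rescaled
#' to unit diagonal (`s_ij / sqrt(d_i d_j)`).
#'
#' @param S_list List of >= 2 similarity matrices over identical ids.
#' @param K Neighborhood size; default `min(20, n - 1)`.
#' @param t_max Maximum iterations (default 20).
#' @param tol Early-stopping threshold on `max |P_{t+1} - P_t|` across views.
#' @return Fused similarity matrix: symmetric, non-negative, unit diagonal.
#' @export
snf_fuse <- function(S_list, K = NULL, t_max = 20, tol = 1e-6) {
  stopifnot(is.list(S_list), length(S_list) >= 2)
  ids <- rownames(S_list[[1]])
  for (S in S_list) {
    assert_named_square(S)
    if (!identical(rownames(S), ids)) {
      stop("id mismatch between similarity views", call. = FALSE)
    }
  }
  n <- length(ids)
  nv <- length(S_list)
  K <- K %||% min(20, n - 1)
  P <- lapply(S_list, snf_weight_matrix)
  L <- lapply(S_list, snf_local_affinity, K = K)
  renorm <- function(P) {
    off <- rowSums(P) - diag(P)
    Q <- P / (2 * off)
    diag(Q) <- 0.5
    Q
  }
  if (t_max > 0) {
    for (t in seq_len(t_max)) {
      totP <- Reduce(`+`, P)
      Pnew <- vector("list", nv)
      for (v in seq_len(nv)) {
        others <- (totP - P[[v]]) / (nv - 1)
        Pv <- L[[v]] %*% others %*% t(L[[v]])
        Pnew[[v]] <- renorm((Pv + t(Pv)) / 2)
      }
      delta <- max(vapply(seq_len(nv), function(v) max(abs(Pnew[[v]] - P[[v]])),
                          numeric(1)))
      P <- Pnew
      if (delta < tol) break
    }
  }
  fused <- Reduce(`+`, P) / nv
  d <- diag(fused)
  fused <- fused / sqrt(outer(d, d))
  finalize_similarity(fused)
}

#' Reduce a fused similarity matrix with a stacked auto-encoder
#'
#' Trains a symmetric auto-encoder `n -> hidden -> out_dim -> hidden -> n`
#' (tanh hidden units, linear output, squared-error reconstruction loss,
#' full-batch Adam) on the rows of the fused matrix and returns the
#' bottleneck activations — a denoised `out_dim`-dimensional representation
#' of each node's similarity profile.
#'
#' @param S_fused Square similarity matrix with id rownames.
#' @param out_dim Bottleneck width; must be `< n` (default 128).
#' @param seed Integer seed controlling weight initialization.
#' @param hidden Outer hidden-layer width (default 256).
#' @param epochs Training epochs (default 200).
#' @param lr Adam step size (default 0.01).
#' @param activation `"tanh"` (default) or `"linear"` (diagnostic sanity
#'   mode).
#' @return `(n, out_dim)` matrix of bottleneck codes with id rownames and an
#'   attribute `loss_history` (per-epoch reconstruction loss, the value at
#'   index 1 being the pre-update loss at initialization).
#' @export
sae_reduce <- function(S_fused, out_dim = 128, seed = 1, hidden = 256,
                       epochs = 200, lr = 0.01, activation = c("tanh", "linear")) {
  assert_named_square(S_fused, "fused matrix")
  activation <- match.arg(activation)
  n <- nrow(S_fused)
  if (out_dim >= n) stop("out_dim must be < n = ", n, call. = FALSE)
  X <- S_fused
  dims <- c(n, hidden, out_dim, hidden, n)
  act <- if (activation == "tanh") tanh else identity
  dact <- if (activation == "tanh") function(a) 1 - a^2 else function(a) 1
  W <- withr::with_seed(seed, lapply(seq_len(4), function(l) {
    glorot(dims[l], dims[l + 1])
  }))
  b <- lapply(seq_len(4), function(l) numeric(dims[l + 1]))
  opt <- adam_state(c(W, b), lr)
  loss_history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    A1 <- act(sweep(X %*% W[[1]], 2, b[[1]], `+`))
    A2 <- act(sweep(A1 %*% W[[2]], 2, b[[2]], `+`))
    A3 <- act(sweep(A2 %*% W[[3]], 2, b[[3]], `+`))
    Xhat <- sweep(A3 %*% W[[4]], 2, b[[4]], `+`)
    R <- Xhat - X
    loss_history[e] <- mean(R^2)
    G4 <- 2 * R / length(R)
    dW4 <- crossprod(A3, G4); db4 <- colSums(G4)
    G3 <- (G4 %*% t(W[[4]])) * dact(A3)
    dW3 <- crossprod(A2, G3); db3 <- colSums(G3)
    G2 <- (G3 %*% t(W[[3]])) * dact(A2)
    dW2 <- crossprod(A1, G2); db2 <- colSums(G2)
    G1 <- (G2 %*% t(W[[2]])) * dact(A1)
    dW1 <- crossprod(X, G1); db1 <- colSums(G1)
    upd <- adam_step(opt, list(dW1, dW2, dW3, dW4, db1, db2, db3, db4))
    opt <- upd$state
    W <- upd$params[1:4]
    b <- upd$params[5:8]
  }
  A1 <- act(sweep(X %*% W[[1]], 2, b[[1]], `+`))
  codes <- act(sweep(A1 %*% W[[2]], 2, b[[2]], `+`))
  rownames(codes) <- rownames(S_fused)
  attr(codes, "loss_history") <- loss_history
  codes
}

glorot <- function(fan_in, fan_out) {
  r <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -r, r), fan_in, fan_out)
}

# Minimal full-batch Adam over a flat list of parameter arrays.
adam_state <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       params = params)
}

adam_step <- function(state, grads) {
  state$t <- state$t + 1
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (i in seq_along(grads)) {
    state$m[[i]] <- state$beta1 * state$m[[i]] + (1 - state$beta1) * grads[[i]]
    state$v[[i]] <- state$beta2 * state$v[[i]] + (1 - state$beta2) * grads[[i]]^2
    step <- state$lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + state$eps)
    state$params[[i]] <- state$params[[i]] - step
  }
  list(state = state, params = state$params)
}

#' Dual standardization (z-score and robust scaling averaged)
#'
#' Per column computes the z-score `(x - mean) / sd` (population sd) and the
#' robust score `(x - median) / IQR` (linear-interpolation quartiles) and
#' returns their mean. A column with zero sd (or zero IQR) contributes 0 for
#' that component.
#'
#' @param M Numeric matrix with >= 2 rows.
#' @return Matrix of the same shape.
#' @export
dual_standardize <- function(M) {
  stopifnot(is.matrix(M))
  if (nrow(M) < 2) stop("dual_standardize needs >= 2 rows", call. = FALSE)
  mu <- colMeans(M)
  sigma <- sqrt(colMeans(sweep(M, 2, mu)^2))
  med <- apply(M, 2, stats::median)
  iqr <- apply(M, 2, function(x) diff(stats::quantile(x, c(0.25, 0.75), names = FALSE)))
  Z <- sweep(M, 2, mu)
  Z <- sweep(Z, 2, ifelse(sigma == 0, 1, sigma), `/`)
  Z[, sigma == 0] <- 0
  R <- sweep(M, 2, med)
  R <- sweep(R, 2, ifelse(iqr == 0, 1, iqr), `/`)
  R[, iqr == 0] <- 0
  out <- (Z + R) / 2
  dimnames(out) <- dimnames(M)
  out
}

#' Stack per-set node features into the full node feature matrix
#'
#' @param PS Pseudogene feature matrix (rows = pseudogenes).
#' @param MS miRNA feature matrix with the same number of columns.
#' @return Row-bound matrix, pseudogene rows first.
#' @export
build_node_features <- function(PS, MS) {
  stopifnot(is.matrix(PS), is.matrix(MS))
  if (ncol(PS) != ncol(MS)) {
    stop("feature column mismatch: ", ncol(PS), " vs ", ncol(MS), call. = FALSE)
  }
  rbind(PS, MS)
}
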