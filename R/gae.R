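#' Bipartite block adjacency matrix
#'
#' Lays the binary association matrix into the symmetric block form
#' `A = rbind(cbind(0, PMA), cbind(t(PMA), 0))`, pseudogene nodes first, so
#' the bipartite graph can be fed to a (uni-partite) graph convolution.
#'
#' @param PMA Binary association matrix with dimnames
#'   (see [association_matrix()]).
#' @return `(n_p + n_m)` square symmetric 0/1 matrix with zero diagonal and
#'   zero within-set blocks.
#' @export
build_adjacency <- function(PMA) {
  stopifnot(is.matrix(PMA), all(PMA %in% c(0, 1)))
  n_p <- nrow(PMA); n_m <- ncol(PMA)
  A <- rbind(
    cbind(matrix(0, n_p, n_p), PMA),
    cbind(t(PMA), matrix(0, n_m, n_m))
  )
  ids <- c(rownames(PMA), colnames(PMA))
  dimnames(A) <- list(ids, ids)
  A
}

#' Symmetric normalization of an adjacency matrix
#'
#' Renormalization-trick form: self-loops are added before computing
#' `D^(-1/2) (A + I) D^(-1/2)`. Without self-loops the normalization is
#' undefined for isolated nodes and a node's own features never enter its
#' convolution; with them, an isolated node's row reduces to the self-loop
#' term.
#'
#' @param A Symmetric binary adjacency matrix.
#' @return Symmetric normalized adjacency, same dimnames.
#' @export
normalize_adjacency <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  assert_symmetric(A, what = "adjacency")
  Ahat <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(Ahat))
  An <- Ahat * outer(dinv, dinv)
  dimnames(An) <- dimnames(A)
  An
}

#' Two-layer GCN encoder
#'
#' `Z = A_norm %*% ReLU(A_norm %*% X %*% W0) %*% W1`, computed exactly as
#' written (dense).
#'
#' @param X Node feature matrix `(n, d_in)`.
#' @param A_norm Normalized adjacency from [normalize_adjacency()].
#' @param W0 `(d_in, h1)` weight matrix.
#' @param W1 `(h1, h2)` weight matrix.
#' @return Embedding matrix `Z` of shape `(n, h2)`.
#' @export
gcn_encode <- function(X, A_norm, W0, W1) {
  stopifnot(ncol(X) == nrow(W0), ncol(W0) == nrow(W1),
            nrow(X) == nrow(A_norm))
  Z <- A_norm %*% pmax(A_norm %*% X %*% W0, 0) %*% W1
  rownames(Z) <- rownames(X)
  Z
}

#' Inner-product decoder
#'
#' Edge probabilities `A_hat = sigmoid(Z %*% t(Z))`. Used only for the
#' training loss; prediction goes through the pair classifier instead.
#'
#' @param Z Embedding matrix.
#' @return Symmetric matrix of probabilities in `(0, 1)`.
#' @export
gae_decode <- function(Z) {
  stopifnot(all(is.finite(Z)))
  stats::plogis(tcrossprod(Z))
}

#' Weighted cross-entropy reconstruction loss
#'
#' `L = -(1/N) * sum(w * y * log(y_hat) + (1 - y) * log(1 - y_hat))` over all
#' `N` adjacency entries, with `w` the positive-class weight (`w = 1` gives
#' the plain cross-entropy). Predictions are clamped to `[eps, 1 - eps]`,
#' `eps = 1e-15`.
#'
#' @param A Binary adjacency matrix.
#' @param A_hat Decoded probability matrix of the same shape.
#' @param pos_weight Positive-class weight (default 1).
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(A, A_hat, pos_weight = 1) {
  stopifnot(identical(dim(A), dim(A_hat)))
  eps <- 1e-15
  P <- pmin(pmax(A_hat, eps), 1 - eps)
  -mean(pos_weight * A * log(P) + (1 - A) * log(1 - P))
}

#' Train the graph auto-encoder
#'
#' Full-batch Adam minimization of [reconstruction_loss()] over the GCN
#' encoder weights, with Glorot-uniform seed-controlled initialization. The
#' adjacency should contain only training edges when embeddings feed a
#' downstream evaluation (see [run_cv()]).
#'
#' @param A Symmetric binary adjacency (from [build_adjacency()]).
#' @param X Node feature matrix aligned with `A`.
#' @param hidden Two encoder widths, default `c(64, 32)`.
#' @param lr Adam step size (default 0.001).
#' @param epochs Training epochs (default 8000; desk-scale runs use a few
#'   hundred).
#' @param pos_weight Positive-class weight; `NULL` uses `#zeros / #ones` of
#'   `A` (1 if `A` has no ones).
#' @param seed Integer seed for weight initialization.
#' @return Object of class `pmgae_gae`: list with embedding matrix `Z`
#'   (`n x hidden[2]`, id rownames), weights `W0`, `W1`, per-epoch
#'   `loss_history`, and the resolved `pos_weight`.
#' @export
train_gae <- function(A, X, hidden = c(64, 32), lr = 0.001, epochs = 8000,
                      pos_weight = NULL, seed = 1) {
  stopifnot(is.matrix(A), is.matrix(X), nrow(A) == nrow(X))
  assert_symmetric(A, what = "adjacency")
  n_pos <- sum(A)
  pos_weight <- pos_weight %||% if (n_pos == 0) 1 else (length(A) - n_pos) / n_pos
  An <- normalize_adjacency(A)
  AX <- An %*% X
  W <- withr::with_seed(seed, list(glorot(ncol(X), hidden[1]),
                                   glorot(hidden[1], hidden[2])))
  opt <- adam_state(W, lr)
  N <- length(A)
  loss_history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    Pre <- AX %*% W[[1]]
    H <- pmax(Pre, 0)
    AH <- An %*% H
    Z <- AH %*% W[[2]]
    S <- tcrossprod(Z)
    Phat <- stats::plogis(S)
    Pc <- pmin(pmax(Phat, 1e-15), 1 - 1e-15)
    loss_history[e] <- -mean(pos_weight * A * log(Pc) + (1 - A) * log(1 - Pc))
    if (!is.finite(loss_history[e])) {
      stop("non-finite loss at epoch ", e, "; reduce the learning rate",
           call. = FALSE)
    }
    # d loss / d S for the weighted sigmoid cross-entropy
    G <- (Phat * ((1 - A) + pos_weight * A) - pos_weight * A) / N
    dZ <- (G + t(G)) %*% Z
    dW1 <- crossprod(AH, dZ)
    dH <- (An %*% (dZ %*% t(W[[2]]))) * (Pre > 0)
    dW0 <- crossprod(AX, dH)
    upd <- adam_step(opt, list(dW0, dW1))
    opt <- upd$state
    W <- upd$params
  }
  Z <- gcn_encode(X, An, W[[1]], W[[2]])
  structure(
    list(Z = Z, W0 = W[[1]], W1 = W[[2]], loss_history = loss_history,
         pos_weight = pos_weight, hidden = hidden, lr = lr, epochs = epochs,
         seed = seed),
    class = "pmgae_gae"
  )
}

#' @export
print.pmgae_gae <- function(x, ...) {
  cat("Graph auto-encoder fit\n")
  cat("  nodes:", nrow(x$Z), " embedding dim:", ncol(x$Z), "\n")
  cat("  epochs:", x$epochs, " lr:", x$lr, " pos_weight:",
      signif(x$pos_weight, 4), "\n")
  cat("  loss: ", signif(x$loss_history[1], 4), " -> ",
      signif(x$loss_history[length(x$loss_history)], 4), "\n", sep = "")
  invisible(x)
}
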