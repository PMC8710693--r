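# internal helpers shared across modules

# Derive a per-stage seed from the master seed so that every randomized stage
# is reproducible independently. Offsets are fixed per stage; result stays
# below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97L + offset * 7919) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_named_square <- function(S, what = "similarity matrix") {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (is.null(rownames(S))) stop(what, " must carry id rownames", call. = FALSE)
  invisible(S)
}

assert_symmetric <- function(S, tol = 1e-9, what = "matrix") {
  if (max(abs(S - t(S))) > tol) stop(what, " is not symmetric", call. = FALSE)
  invisible(S)
}

# Enforce the finalized similarity-matrix invariants: symmetry, unit
# diagonal, entries in [0, 1] (clipping only numerical spill).
finalize_similarity <- function(S) {
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S[S < 0] <- 0
  S[S > 1] <- 1
  S
}

matrix_from_wide <- function(tbl, id_col = "id") {
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  rownames(m) <- tbl[[id_col]]
  storage.mode(m) <- "double"
  m
}
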