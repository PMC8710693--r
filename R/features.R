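#' k-mer frequency vector of a single RNA sequence
#'
#' Each k-mer `w` gets frequency `count(w) / (L - k + 1)`, the fraction of
#' sliding windows equal to `w`, so entries sum to 1. Columns are all 4^k
#' k-mers over `{A, C, G, U}` in lexicographic order (`AAA`, `AAC`, ...).
#'
#' @param sequence RNA string over `{A, C, G, U}` of length >= `k`.
#' @param k k-mer size (default 3).
#' @return Named numeric vector of length `4^k`.
#' @examples
#' kmer_frequencies("AGGUUCCAGG")[["AGG"]]  # 2 of 8 windows
#' @export
kmer_frequencies <- function(sequence, k = 3) {
  stopifnot(length(sequence) == 1, is.character(sequence))
  if (nchar(sequence) < k) {
    stop("sequence shorter than k = ", k, call. = FALSE)
  }
  s <- Biostrings::RNAStringSet(sequence)
  v <- Biostrings::oligonucleotideFrequency(s, width = k, as.prob = TRUE)
  stats::setNames(as.numeric(v[1, ]), colnames(v))
}

#' k-mer profile matrix for a set of sequences
#'
#' @param records Tibble with `id` and `sequence` columns, e.g. from
#'   [read_fasta()].
#' @inheritParams kmer_frequencies
#' @return Numeric matrix of shape `(n, 4^k)`, rows named by `id`, each row
#'   summing to 1; rows ordered lexicographically by id (the package-wide
#'   node order).
#' @export
kmer_profile <- function(records, k = 3) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  short <- nchar(records$sequence) < k
  if (any(short)) {
    stop("sequence shorter than k = ", k, ": ", records$id[short][1], call. = FALSE)
  }
  ord <- order(records$id)
  s <- Biostrings::RNAStringSet(stats::setNames(records$sequence[ord], records$id[ord]))
  m <- Biostrings::oligonucleotideFrequency(s, width = k, as.prob = TRUE)
  m <- as.matrix(m)
  rownames(m) <- records$id[ord]
  m
}

#' Min-max normalize an expression table
#'
#' Per tissue (column), values are rescaled to `[0, 1]`; a constant column
#' maps to all zeros. Min-max (rather than z-scoring) keeps values
#' non-negative, which the generalized Jaccard similarity requires.
#'
#' @param table Expression tibble with an `id` first column (see
#'   [read_expression_tsv()]).
#' @return A tibble of the same shape with normalized values.
#' @export
normalize_expression <- function(table) {
  stopifnot(names(table)[1] == "id")
  vals <- table[-1]
  if (any(vapply(vals, function(x) any(x < 0), logical(1)))) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  scaled <- lapply(vals, function(x) {
    rng <- max(x) - min(x)
    if (rng == 0) rep(0, length(x)) else (x - min(x)) / rng
  })
  dplyr::bind_cols(table[1], tibble::as_tibble(scaled))
}

#' Generalized (Ruzicka) Jaccard similarity between matrix rows
#'
#' `S(i, j) = sum_k min(x_ik, x_jk) / sum_k max(x_ik, x_jk)`, which reduces to
#' set Jaccard on binary input. Two all-zero rows are defined as similarity 1.
#'
#' @param M Non-negative numeric matrix, rows = samples, with rownames.
#' @return Square symmetric similarity matrix with unit diagonal, entries in
#'   `[0, 1]`.
#' @export
jaccard_similarity <- function(M) {
  M <- as_feature_matrix(M)
  if (any(M < 0)) stop("Jaccard similarity undefined for negative input", call. = FALSE)
  n <- nrow(M)
  tM <- t(M)
  rs <- rowSums(M)
  S <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n)) {
    mins <- colSums(pmin(tM, M[i, ]))
    # sum max = sum x + sum y - sum min
    maxs <- rs + rs[i] - mins
    S[i, ] <- ifelse(maxs == 0, 1, mins / maxs)
  }
  finalize_similarity(S)
}

#' Cosine similarity between matrix rows
#'
#' Raw cosine `sum x_k y_k / (|x| |y|)` can be negative on general input, so
#' the result is rescaled by `s -> (s + 1) / 2` to the `[0, 1]` range shared
#' by all similarity measures in the pipeline. A zero row has raw similarity
#' 0 to every other row.
#'
#' @inheritParams jaccard_similarity
#' @return Square symmetric similarity matrix with unit diagonal, entries in
#'   `[0, 1]`.
#' @export
cosine_similarity <- function(M) {
  M <- as_feature_matrix(M)
  nrm <- sqrt(rowSums(M^2))
  S <- tcrossprod(M)
  denom <- outer(nrm, nrm)
  S <- ifelse(denom == 0, 0, S / ifelse(denom == 0, 1, denom))
  finalize_similarity((S + 1) / 2)
}

#' Pearson similarity between matrix rows
#'
#' Raw value is the Pearson correlation of the two rows; zero-variance rows
#' get raw correlation 0 off-diagonal. As for [cosine_similarity()], the raw
#' value is rescaled by `s -> (s + 1) / 2`.
#'
#' @inheritParams jaccard_similarity
#' @return Square symmetric similarity matrix with unit diagonal, entries in
#'   `[0, 1]`.
#' @export
pearson_similarity <- function(M) {
  M <- as_feature_matrix(M)
  S <- suppressWarnings(stats::cor(t(M)))
  S[!is.finite(S)] <- 0
  finalize_similarity((S + 1) / 2)
}

as_feature_matrix <- function(M) {
  if (is.data.frame(M)) M <- matrix_from_wide(M)
  stopifnot(is.matrix(M))
  if (is.null(rownames(M))) rownames(M) <- paste0("row", seq_len(nrow(M)))
  storage.mode(M) <- "double"
  M
}

#' Gaussian interaction-profile (GIP) kernel similarity
#'
#' Treats each node's binary association profile `IP(i)` (a row or column of
#' the association matrix) as its feature vector and applies a Gaussian
#' kernel: `G(i, j) = exp(-gamma * |IP(i) - IP(j)|^2)` with bandwidth
#' `gamma = 1 / mean_i |IP(i)|^2` (1 if all profiles are empty).
#'
#' @param A Binary association matrix (pseudogenes x miRNAs) with dimnames.
#' @param axis `"rows"` for pseudogene similarity, `"cols"` for miRNA
#'   similarity.
#' @return Square symmetric similarity matrix with unit diagonal.
#' @export
gip_kernel <- function(A, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(A), all(A %in% c(0, 1)))
  P <- if (axis == "rows") A else t(A)
  sq <- rowSums(P^2)
  gamma <- if (mean(sq) == 0) 1 else 1 / mean(sq)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0 # numerical guard
  G <- exp(-gamma * d2)
  dimnames(G) <- list(rownames(P), rownames(P))
  finalize_similarity(G)
}

#' Replace zero similarities with GIP kernel values
#'
#' Attribute-based similarity matrices can contain exact zeros (e.g. disjoint
#' k-mer supports); those entries are filled from the interaction-profile
#' kernel so every node pair carries some signal into the fusion step.
#'
#' @param S Attribute similarity matrix.
#' @param G GIP kernel matrix over the same ids in the same order.
#' @return Matrix with `S` where `S > 0` and `G` elsewhere.
#' @export
fill_zeros <- function(S, G) {
  assert_named_square(S); assert_named_square(G, "GIP matrix")
  if (!identical(rownames(S), rownames(G))) {
    stop("id mismatch between similarity and GIP matrices", call. = FALSE)
  }
  out <- ifelse(S > 0, S, G)
  dimnames(out) <- dimnames(S)
  out
}

#' All three zero-filled similarity matrices for one node set
#'
#' Convenience wrapper: computes generalized Jaccard, cosine and Pearson
#' similarities of the feature rows and fills exact zeros from the GIP
#' kernel of the association matrix.
#'
#' @param features Numeric matrix, rows = nodes (k-mer profile or normalized
#'   expression), rownames = ids in the canonical sorted order.
#' @param A Binary association matrix whose rows (or columns) correspond to
#'   the same nodes.
#' @param axis Passed to [gip_kernel()].
#' @return Named list of three similarity matrices
#'   (`jaccard`, `cosine`, `pearson`).
#' @export
node_similarities <- function(features, A, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  G <- gip_kernel(A, axis)
  sims <- list(
    jaccard = jaccard_similarity(features),
    cosine = cosine_similarity(features),
    pearson = pearson_similarity(features)
  )
  lapply(sims, fill_zeros, G = G)
}

#' Build the binary association (PMA) matrix
#'
#' @param pairs Tibble with `pseudogene` and `mirna` columns.
#' @param row_universe,col_universe Full id sets; the matrix is indexed by
#'   the sorted universes regardless of pair order.
#' @return Binary matrix with `PMA(i, j) = 1` iff the pair is present.
#' @export
association_matrix <- function(pairs, row_universe, col_universe) {
  rows <- sort(unique(row_universe))
  cols <- sort(unique(col_universe))
  A <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  if (nrow(pairs) > 0) {
    unknown <- setdiff(pairs$pseudogene, rows)
    if (length(unknown)) stop("unknown pseudogene id: ", unknown[1], call. = FALSE)
    unknown <- setdiff(pairs$mirna, cols)
    if (length(unknown)) stop("unknown miRNA id: ", unknown[1], call. = FALSE)
    A[cbind(match(pairs$pseudogene, rows), match(pairs$mirna, cols))] <- 1
  }
  A
}
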