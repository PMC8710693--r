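#' Specification for a synthetic pseudogene-miRNA dataset
#'
#' The generator plants a shared latent structure: pseudogene latent vectors
#' drive both the expression profile and the edge probabilities; miRNA latent
#' vectors drive both the 3-mer composition of the sequence and the edge
#' probabilities. Every pipeline stage therefore has a recoverable signal.
#' Default scale (120 x 60 nodes, 500 edges, ~7% density) keeps a full
#' cross-validation run desk-sized while staying close to the density of the
#' real curated network this emulates (444 x 173 nodes, 1,884 edges, ~2.5%);
#' `paper_scale = TRUE` switches to that full scale.
#'
#' @param n_pseudogenes,n_mirnas,n_tissues,n_edges Problem size (defaults
#'   120, 60, 20, 500).
#' @param latent_dim Shared latent dimension (default 8).
#' @param edge_noise Fraction of planted edges rewired to random non-edges
#'   (in `[0, 0.5)`, default 0.05); the expected edge count is preserved.
#' @param motif_strength Probability that a sequence 3-mer slot is drawn from
#'   the latent-weighted motif set rather than uniformly (in `[0, 1]`,
#'   default 0.8).
#' @param decouple_edges If `TRUE`, edges are drawn independently and
#'   uniformly at the calibrated density, with no latent structure at all —
#'   a null control in which neither node features nor the graph topology
#'   carry information about held-out edges, so end-to-end recovery should
#'   sit at chance.
#' @param paper_scale If `TRUE`, use 444 x 173 nodes and 1,884 edges.
#' @param seed Integer seed.
#' @return A list of class `pmgae_synthetic_spec`.
#' @export
synthetic_spec <- function(n_pseudogenes = 120, n_mirnas = 60, n_tissues = 20,
                           latent_dim = 8, n_edges = 500, edge_noise = 0.05,
                           motif_strength = 0.8, decouple_edges = FALSE,
                           paper_scale = FALSE, seed = 1) {
  if (paper_scale) {
    n_pseudogenes <- 444; n_mirnas <- 173; n_edges <- 1884
  }
  spec <- list(
    n_pseudogenes = n_pseudogenes, n_mirnas = n_mirnas, n_tissues = n_tissues,
    latent_dim = latent_dim, n_edges = n_edges, edge_noise = edge_noise,
    motif_strength = motif_strength, decouple_edges = isTRUE(decouple_edges),
    seed = seed
  )
  for (f in c("n_pseudogenes", "n_mirnas", "n_tissues", "latent_dim", "n_edges")) {
    if (spec[[f]] < 1 || spec[[f]] != round(spec[[f]])) {
      stop("spec field '", f, "' must be a positive integer", call. = FALSE)
    }
  }
  if (n_edges > n_pseudogenes * n_mirnas) {
    stop("n_edges exceeds the number of cells", call. = FALSE)
  }
  if (edge_noise < 0 || edge_noise >= 0.5) stop("edge_noise must be in [0, 0.5)",
                                                call. = FALSE)
  if (motif_strength < 0 || motif_strength > 1) {
    stop("motif_strength must be in [0, 1]", call. = FALSE)
  }
  structure(spec, class = "pmgae_synthetic_spec")
}

all_kmers <- function(k = 3) {
  sort(apply(expand.grid(rep(list(c("A", "C", "G", "U")), k)), 1, paste, collapse = ""))
}

#' Generate a synthetic dataset with planted latent structure
#'
#' Latent vectors `u_i` (pseudogenes) and `v_j` (miRNAs) are drawn so that
#' `u_i . v_j` has unit scale. Expression row i is
#' `softplus(u_i %*% B) + noise` (non-negative); sequence j is 60 nt of
#' 3-mer slots drawn, with probability `motif_strength`, from a fixed motif
#' set weighted by `softmax(2 v_j)` and uniformly otherwise; edge `(i, j)`
#' occurs with probability `sigmoid(a + 3 u_i . v_j)`, the intercept `a`
#' calibrated by root finding so the expected edge count equals `n_edges`.
#' A fraction `edge_noise` of realized edges is then rewired to random
#' non-edges.
#'
#' @param spec A `pmgae_synthetic_spec`.
#' @return List with `expression` (tibble), `sequences` (tibble),
#'   `associations` (tibble) and `truth` (latent factors and edge
#'   probabilities, for diagnostics).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "pmgae_synthetic_spec"))
  withr::with_seed(spec$seed, {
    n_p <- spec$n_pseudogenes; n_m <- spec$n_mirnas; d <- spec$latent_dim
    p_ids <- sprintf("PG%04d", seq_len(n_p))
    m_ids <- sprintf("MIR%04d", seq_len(n_m))
    sdl <- d^(-1 / 4) # entry scale making u . v unit-variance
    U <- matrix(stats::rnorm(n_p * d, sd = sdl), n_p, d, dimnames = list(p_ids, NULL))
    V <- matrix(stats::rnorm(n_m * d, sd = sdl), n_m, d, dimnames = list(m_ids, NULL))

    # expression: softplus of a random linear map of u, plus mild noise
    B <- matrix(stats::rnorm(d * spec$n_tissues), d, spec$n_tissues)
    E <- log1p(exp(U %*% B)) + matrix(abs(stats::rnorm(n_p * spec$n_tissues, sd = 0.1)),
                                      n_p, spec$n_tissues)
    expression <- dplyr::bind_cols(
      tibble::tibble(id = p_ids),
      tibble::as_tibble(stats::setNames(as.data.frame(E),
                                        sprintf("tissue%02d", seq_len(spec$n_tissues))))
    )

    # sequences: 20 slots of 3-mers, motif slots weighted by softmax(2 v_j)
    kmers <- all_kmers(3)
    motif_idx <- round(seq(1, length(kmers), length.out = d))
    motifs <- kmers[motif_idx]
    sequences <- tibble::tibble(
      id = m_ids,
      sequence = vapply(seq_len(n_m), function(j) {
        w <- exp(2 * V[j, ]); w <- w / sum(w)
        slots <- vapply(seq_len(20), function(s) {
          if (stats::runif(1) < spec$motif_strength) {
            sample(motifs, 1, prob = w)
          } else {
            sample(kmers, 1)
          }
        }, character(1))
        paste(slots, collapse = "")
      }, character(1))
    )

    # edges: Bernoulli with logistic link, intercept calibrated to n_edges;
    # the null control uses a structureless uniform edge probability instead
    if (spec$decouple_edges) {
      prob <- matrix(spec$n_edges / (n_p * n_m), n_p, n_m,
                     dimnames = list(p_ids, m_ids))
      a <- NA_real_
    } else {
      S <- 3 * tcrossprod(U, V)
      a <- stats::uniroot(function(a) sum(stats::plogis(a + S)) - spec$n_edges,
                          c(-40, 40))$root
      prob <- stats::plogis(a + S)
    }
    A <- matrix(stats::rbinom(length(prob), 1, prob), n_p, n_m,
                dimnames = list(p_ids, m_ids))
    # rewire a fraction of realized edges to random non-edges
    if (spec$edge_noise > 0 && sum(A) > 0) {
      ones <- which(A == 1)
      move <- ones[stats::runif(length(ones)) < spec$edge_noise]
      if (length(move) > 0) {
        A[move] <- 0
        zeros <- which(A == 0)
        A[sample(zeros, length(move))] <- 1
      }
    }
    idx <- which(A == 1, arr.ind = TRUE)
    associations <- tibble::tibble(
      pseudogene = p_ids[idx[, 1]],
      mirna = m_ids[idx[, 2]]
    )
    associations <- dplyr::arrange(associations, .data$pseudogene, .data$mirna)

    list(
      expression = expression,
      sequences = sequences,
      associations = associations,
      truth = list(u = U, v = V, edge_prob = prob, intercept = a,
                   spec = unclass(spec))
    )
  })
}

#' Write a synthetic dataset to plain-text fixture files
#'
#' Produces `sequences.fasta`, `expression.tsv`, `edges.tsv` and
#' `truth.json` in `dir`, loadable unchanged by [read_fasta()],
#' [read_expression_tsv()] and [read_edge_list()].
#'
#' @param outputs Result of [generate_synthetic()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture <- function(outputs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "sequences.fasta"),
    expression = file.path(dir, "expression.tsv"),
    edges = file.path(dir, "edges.tsv"),
    truth = file.path(dir, "truth.json")
  )
  writeLines(
    as.vector(rbind(paste0(">", outputs$sequences$id), outputs$sequences$sequence)),
    paths[["fasta"]]
  )
  readr::write_tsv(outputs$expression, paths[["expression"]], progress = FALSE)
  readr::write_tsv(outputs$associations, paths[["edges"]], col_names = FALSE,
                   progress = FALSE)
  truth <- outputs$truth
  truth$u <- unname(as.data.frame(truth$u))
  truth$v <- unname(as.data.frame(truth$v))
  truth$edge_prob <- unname(as.data.frame(truth$edge_prob))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Load a fixture directory written by [write_fixture()]
#'
#' @param dir Directory containing the fixture files.
#' @return A `pmgae_dataset`.
#' @export
read_fixture <- function(dir) {
  sequences <- read_fasta(file.path(dir, "sequences.fasta"))
  expression <- read_expression_tsv(file.path(dir, "expression.tsv"))
  associations <- read_edge_list(file.path(dir, "edges.tsv"),
                                 row_universe = expression$id,
                                 col_universe = sequences$id)
  pma_dataset(expression, sequences, associations)
}
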