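#' Read RNA sequences from a FASTA file
#'
#' Reads a FASTA file into a tibble of sequence records. DNA-style `T`/`t`
#' is mapped to `U`; any character outside `{A, C, G, U}` after mapping is a
#' parse error reported with its line number, as are empty headers, duplicate
#' ids and records without sequence.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence` (uppercase RNA
#'   alphabet), rows in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">m1", "AGGT"), fa)
#' read_fasta(fa)   # T normalized to U
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  ids <- character()
  seqs <- character()
  header_line <- integer()
  cur <- NULL
  flush_record <- function() {
    if (is.null(cur)) return(invisible())
    if (!nzchar(cur$seq)) {
      stop("FASTA parse error at line ", cur$line, ": record '", cur$id,
           "' has an empty sequence", call. = FALSE)
    }
    ids <<- c(ids, cur$id)
    seqs <<- c(seqs, cur$seq)
    header_line <<- c(header_line, cur$line)
    invisible()
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      flush_record()
      id <- trimws(sub("^>", "", ln))
      # keep only the first whitespace-delimited token, the FASTA convention
      id <- sub("\\s.*$", "", id)
      if (!nzchar(id)) {
        stop("FASTA parse error at line ", i, ": empty header", call. = FALSE)
      }
      cur <- list(id = id, seq = "", line = i)
    } else {
      if (is.null(cur)) {
        stop("FASTA parse error at line ", i,
             ": sequence data before any header", call. = FALSE)
      }
      chunk <- chartr("acgut", "ACGUT", ln)
      chunk <- gsub("T", "U", chunk, fixed = TRUE)
      bad <- regmatches(chunk, regexpr("[^ACGU]", chunk))
      if (length(bad) > 0 && nzchar(bad)) {
        stop("FASTA parse error at line ", i, ": illegal character '",
             bad, "' in record '", cur$id, "'", call. = FALSE)
      }
      cur$seq <- paste0(cur$seq, chunk)
    }
  }
  flush_record()
  if (length(ids) == 0) stop("no FASTA records in ", path, call. = FALSE)
  if (anyDuplicated(ids)) {
    di <- which(duplicated(ids))[1]
    stop("FASTA parse error at line ", header_line[di], ": duplicate id '",
         ids[di], "'", call. = FALSE)
  }
  tibble::tibble(id = ids, sequence = seqs)
}

#' Read a pseudogene expression table
#'
#' Expects a TSV with a header row of tissue/condition names, the first
#' column holding pseudogene ids. Missing or non-numeric cells and duplicate
#' row ids are errors: filtering and imputation are upstream concerns.
#'
#' @param path Path to a TSV file.
#' @return A tibble whose first column is `id` and remaining columns are
#'   numeric expression values per tissue.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  if (ncol(tbl) < 2) stop("expression table needs an id column plus >= 1 tissue column",
                          call. = FALSE)
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    stop("malformed expression table (row ", prob$row[1], "): ",
         prob$expected[1], " vs ", prob$actual[1], call. = FALSE)
  }
  names(tbl)[1] <- "id"
  tbl$id <- as.character(tbl$id)
  if (anyDuplicated(tbl$id)) {
    stop("duplicate pseudogene id: ", tbl$id[duplicated(tbl$id)][1], call. = FALSE)
  }
  vals <- tbl[-1]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    bad <- names(vals)[!vapply(vals, is.numeric, logical(1))][1]
    stop("non-numeric expression values in column '", bad, "'", call. = FALSE)
  }
  if (anyNA(vals)) stop("missing expression values are not supported", call. = FALSE)
  tbl
}

#' Read a pseudogene-miRNA edge list
#'
#' Two-column TSV (no header required; a `pseudogene<TAB>mirna` header line is
#' tolerated). Duplicate pairs are dropped with a warning; ids outside the
#' supplied universes are errors.
#'
#' @param path Path to a two-column TSV.
#' @param row_universe Character vector of valid pseudogene ids.
#' @param col_universe Character vector of valid miRNA ids.
#' @return A tibble with columns `pseudogene` and `mirna`, deduplicated.
#' @export
read_edge_list <- function(path, row_universe, col_universe) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_names = c("pseudogene", "mirna"),
                         col_types = "cc", progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) > 0 && identical(unname(unlist(raw[1, ])), c("pseudogene", "mirna"))) {
    raw <- raw[-1, ]
  }
  if (nrow(raw) == 0) stop("empty edge list: ", path, call. = FALSE)
  dup <- duplicated(raw)
  if (any(dup)) {
    warning(sum(dup), " duplicate pair(s) dropped from ", path, call. = FALSE)
    raw <- raw[!dup, ]
  }
  unknown_p <- setdiff(raw$pseudogene, row_universe)
  if (length(unknown_p) > 0) {
    stop("unknown pseudogene id in edge list: ", unknown_p[1], call. = FALSE)
  }
  unknown_m <- setdiff(raw$mirna, col_universe)
  if (length(unknown_m) > 0) {
    stop("unknown miRNA id in edge list: ", unknown_m[1], call. = FALSE)
  }
  raw
}

#' Write a cross-validation report to JSON
#'
#' Serializes per-fold metrics plus their mean (and sd) so a run can be
#' archived and compared.
#'
#' @param report A `pmgae_cv` object from [run_cv()].
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "pmgae_cv"))
  out <- list(
    folds = report$per_fold,
    mean = as.list(glance(report)),
    sd = as.list(report$sd),
    seed = report$seed,
    config = unclass(report$config)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a candidate ranking to TSV
#'
#' @param ranking A tibble with at least `id` and `score` columns (e.g. from
#'   [rank_candidates()]); written sorted by descending score with an
#'   explicit `rank` column. An empty ranking yields a header-only file.
#' @param path Output path for the TSV file.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(is.data.frame(ranking), all(c("id", "score") %in% names(ranking)))
  out <- dplyr::arrange(ranking, dplyr::desc(.data$score), .data$id)
  out <- tibble::tibble(rank = seq_len(nrow(out)), id = out$id, score = out$score)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a similarity or feature matrix as TSV with id headers
#'
#' @param m Numeric matrix with id rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  tbl <- tibble::as_tibble(m, .name_repair = "minimal")
  tbl <- dplyr::bind_cols(tibble::tibble(id = rownames(m)), tbl)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with id rownames.
#' @export
read_matrix_tsv <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  matrix_from_wide(tbl, id_col = names(tbl)[1])
}
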