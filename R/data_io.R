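# Reading and writing the external artifacts: count matrices (TSV or
# per-sample HTSeq-count files), clinical tables and gene rankings.

#' Load a count dataset with its sample metadata
#'
#' Reads raw gene-level counts either from a single genes-by-samples TSV
#' (header row of sample identifiers, first column of gene identifiers) or
#' from a directory of per-sample two-column HTSeq-count files
#' (`<sample_id>.tsv`, tab-separated `gene<TAB>count`). HTSeq special
#' counter rows (identifiers starting with `"__"`, e.g. `__no_feature`)
#' are dropped. Every sample in the counts must be described in the
#' metadata table.
#'
#' @param counts_source path to a counts TSV, or a directory of
#'   HTSeq-count files.
#' @param metadata_path path to a TSV with columns `sample_id`,
#'   `condition` and optionally `survival_time`, `event`.
#' @return A list with elements `matrix` (an [expression_matrix()], raw
#'   counts) and `metadata` (validated data frame restricted to the
#'   matrix samples, in matrix order).
#' @export
load_dataset <- function(counts_source, metadata_path) {
  metadata <- validate_metadata(
    read.delim(metadata_path, sep = "\t", stringsAsFactors = FALSE))
  values <- if (dir.exists(counts_source)) {
    read_htseq_dir(counts_source)
  } else {
    read_counts_tsv(counts_source)
  }
  missing <- setdiff(colnames(values), metadata$sample_id)
  if (length(missing))
    stop("samples present in counts but absent from metadata: ",
         paste(missing, collapse = ", "))
  metadata <- metadata[match(colnames(values), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  list(matrix = expression_matrix(values, normalized = FALSE),
       metadata = metadata)
}

read_counts_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene row(s) in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  if (anyNA(values) || any(values != round(values)))
    stop("non-integer raw count value in ", path)
  values
}

read_htseq_dir <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no HTSeq-count files found in ", dir)
  cols <- lapply(files, function(f) {
    df <- read.delim(f, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) != 2L)
      stop("HTSeq-count file must have two columns: ", f)
    keep <- !startsWith(as.character(df[[1L]]), "__")
    setNames(df[[2L]][keep], as.character(df[[1L]])[keep])
  })
  genes <- names(cols[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene in HTSeq-count file: ", files[[1L]])
  for (i in seq_along(cols)) {
    if (!identical(names(cols[[i]]), genes))
      stop("inconsistent gene set across HTSeq files: ", files[[i]])
  }
  values <- do.call(cbind, cols)
  colnames(values) <- tools::file_path_sans_ext(basename(files))
  storage.mode(values) <- "double"
  if (anyNA(values) || any(values != round(values)))
    stop("non-integer raw count value among HTSeq files in ", dir)
  values
}

#' Write a count matrix to TSV
#'
#' Genes as rows, samples as columns, header row of sample identifiers;
#' the first column (`gene_id`) carries gene identifiers. The on-disk
#' layout round-trips through [load_dataset()].
#'
#' @param matrix an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "expression_matrix"))
  df <- data.frame(gene_id = gene_ids(matrix), matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample metadata to TSV
#'
#' @param metadata validated metadata data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metadata_tsv <- function(metadata, path) {
  metadata <- validate_metadata(metadata)
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read gene rankings
#'
#' Rankings are stored as a TSV with columns `rank`, `gene_id`, `score`,
#' `method`. Scores are written with 15 significant digits so a write /
#' read cycle preserves rank order, scores (well beyond 12 significant
#' digits) and the method tag. Reading
#' verifies that ranks form the gap-free sequence `1..G`.
#'
#' @param ranking a [gene_ranking()].
#' @param path file path.
#' @return `write_ranking_tsv` returns `path` invisibly;
#'   `read_ranking_tsv` returns a [gene_ranking()].
#' @export
write_ranking_tsv <- function(ranking, path) {
  stopifnot(inherits(ranking, "gene_ranking"))
  df <- data.frame(rank = ranking$rank, gene_id = ranking$gene_id,
                   score = formatC(ranking$score, digits = 15,
                                   format = "g"),
                   method = ranking_method(ranking),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking_tsv
#' @export
read_ranking_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("rank", "gene_id")
  if (!all(req %in% names(df)))
    stop("ranking file must contain columns rank and gene_id: ", path)
  df <- df[order(df$rank), , drop = FALSE]
  if (!identical(as.integer(df$rank), seq_len(nrow(df))))
    stop("ranks are not the gap-free sequence 1..G in ", path)
  method <- if ("method" %in% names(df)) unique(df$method) else "imported"
  if (length(method) != 1L)
    stop("ranking file mixes method tags: ", path)
  score <- if ("score" %in% names(df)) {
    suppressWarnings(as.numeric(df$score))
  } else {
    rep(NA_real_, nrow(df))
  }
  gene_ranking(as.character(df$gene_id), score, method)
}
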