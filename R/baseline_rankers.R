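# Comparator rankings: absolute fold change, a univariate-test ranking
# standing in for an external differential-expression tool, and import of
# rankings computed elsewhere.

#' Rank genes by absolute fold change
#'
#' Using training samples only, scores each gene as
#' `|log2((mean_case + 0.5) / (mean_control + 0.5))|` of its normalized
#' counts; a pseudocount of 0.5 keeps genes with zero counts in one class
#' finite. Genes are ordered by decreasing score, ties broken
#' lexicographically by gene id.
#'
#' @param matrix a normalized [expression_matrix()].
#' @param metadata validated metadata with `condition`.
#' @param split a [split_spec()]; only `split$training_ids` are used.
#' @return A [gene_ranking()] with method `"FC"`.
#' @export
rank_by_fold_change <- function(matrix, metadata, split) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(split, "split_spec"))
  if (!matrix$normalized)
    stop("fold-change ranking expects a normalized matrix")
  metadata <- validate_metadata(metadata)
  cond <- setNames(metadata$condition, metadata$sample_id)[split$training_ids]
  x <- matrix$values[, split$training_ids, drop = FALSE]
  m_case <- rowMeans(x[, cond == "case", drop = FALSE])
  m_ctrl <- rowMeans(x[, cond == "control", drop = FALSE])
  score <- abs(log2((m_case + 0.5) / (m_ctrl + 0.5)))
  rank_descending(setNames(score, gene_ids(matrix)), "FC")
}

#' Rank genes by a univariate test with BH adjustment
#'
#' A stand-in for a differential-expression ranking: a two-sided Welch
#' t-test per gene on transformed expression of the training samples,
#' Benjamini-Hochberg adjustment, and ordering by ascending adjusted
#' p-value with ties broken by ascending raw p-value then gene id. Genes
#' constant across the training samples are assigned p = 1 (last tier);
#' genes whose two class means differ with zero within-class variance get
#' p = 0 (the test statistic diverges). The reported score is
#' `-log10(adjusted p)`, so scores are non-increasing in rank.
#'
#' @param features a `feature_matrix` from [transform_features()].
#' @param metadata validated metadata with `condition`.
#' @param split a [split_spec()]; only training samples are used.
#' @return A [gene_ranking()] with method `"DE"`, carrying the per-gene
#'   raw and adjusted p-values as attribute `"pvalues"`.
#' @export
rank_by_univariate_test <- function(features, metadata, split) {
  blk <- training_block(features, metadata, split)
  if (min(table(blk$y)) < 2L)
    stop("each class needs at least 2 training samples for the t-test")
  a <- blk$x[blk$y == "case", , drop = FALSE]
  b <- blk$x[blk$y == "control", , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(sweep(a, 2L, ma)^2) / (na - 1)
  vb <- colSums(sweep(b, 2L, mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  zero_se <- se2 == 0
  p[zero_se & (ma == mb)] <- 1       # constant genes: defined degenerate rule
  p[zero_se & (ma != mb)] <- 0
  p[!is.finite(p)] <- 1
  padj <- p.adjust(p, method = "BH")
  genes <- colnames(blk$x)
  ord <- order(padj, p, genes, method = "radix")
  ranking <- gene_ranking(genes[ord], -log10(pmax(padj[ord], 1e-300)), "DE")
  attr(ranking, "pvalues") <- data.frame(gene_id = genes, p = p, padj = padj,
                                         stringsAsFactors = FALSE)
  ranking
}

#' Import an externally computed gene ranking
#'
#' Reads a TSV holding either an explicit `rank` column or an adjusted
#' p-value column (`padj`, `p_adj`, `pvalue` or `p`) next to `gene_id`.
#' With p-values, genes are ordered by ascending p with ties broken by
#' gene id; with ranks the file order is preserved. When the gene
#' universe of the study is supplied, rows for unknown genes are dropped
#' with a warning listing them.
#'
#' @param path TSV file path.
#' @param universe optional character vector of valid gene ids.
#' @return A [gene_ranking()] with method `"imported"`; the score column
#'   is `-log10(p)` when p-values were supplied, `NA` otherwise.
#' @export
import_external_ranking <- function(path, universe = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df))
    stop("imported ranking needs a gene_id column: ", path)
  df$gene_id <- as.character(df$gene_id)
  if (!is.null(universe)) {
    unknown <- setdiff(df$gene_id, universe)
    if (length(unknown)) {
      warning("dropping ", length(unknown),
              " gene(s) absent from the study matrix: ",
              paste(unknown, collapse = ", "))
      df <- df[df$gene_id %in% universe, , drop = FALSE]
    }
  }
  pcol <- intersect(c("padj", "p_adj", "pvalue", "p"), names(df))
  if (length(pcol)) {
    pv <- as.numeric(df[[pcol[[1L]]]])
    ord <- order(pv, df$gene_id, method = "radix")
    gene_ranking(df$gene_id[ord], -log10(pmax(pv[ord], 1e-300)), "imported")
  } else if ("rank" %in% names(df)) {
    df <- df[order(df$rank), , drop = FALSE]
    gene_ranking(df$gene_id, rep(NA_real_, nrow(df)), "imported")
  } else {
    stop("imported ranking needs a rank or p-value column: ", path)
  }
}
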