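# Core S3 containers shared by every stage of the pipeline.

#' Construct an expression matrix
#'
#' Wraps a genes-by-samples numeric matrix together with a flag recording
#' whether the values are raw integer counts or size-factor-normalized
#' counts. Gene and sample identifiers live in the dimnames and must be
#' unique; all values must be non-negative, and raw matrices must contain
#' only whole numbers.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   complete and unique dimnames.
#' @param normalized logical; `TRUE` once counts have been divided by
#'   per-sample size factors.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the matrix) and `normalized`.
#' @seealso [load_dataset()], [normalize_counts()]
#' @export
expression_matrix <- function(values, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("'values' must carry gene rownames and sample colnames")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(values) || any(values < 0))
    stop("expression values must be non-negative and non-missing")
  if (!normalized && any(values != round(values)))
    stop("raw count matrices must contain only integers")
  structure(list(values = values, normalized = isTRUE(normalized)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `expression_matrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Validate sample metadata
#'
#' Sample metadata is a plain data frame with columns `sample_id`,
#' `condition` (`"case"` or `"control"`), and optional `survival_time`
#' (days) and `event` (0/1). Survival fields may be missing for samples
#' used only for training; wherever `survival_time` is present, `event`
#' must be present too.
#'
#' @param metadata data frame as described above.
#' @return The metadata, with `condition` as character, invisibly checked.
#' @export
validate_metadata <- function(metadata) {
  if (!is.data.frame(metadata))
    stop("metadata must be a data frame")
  req <- c("sample_id", "condition")
  miss <- setdiff(req, names(metadata))
  if (length(miss))
    stop("metadata lacks required columns: ", paste(miss, collapse = ", "))
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$condition <- as.character(metadata$condition)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
               collapse = ", "))
  bad <- setdiff(unique(metadata$condition), c("case", "control"))
  if (length(bad))
    stop("condition must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  if (!"survival_time" %in% names(metadata)) metadata$survival_time <- NA_real_
  if (!"event" %in% names(metadata)) metadata$event <- NA_integer_
  has_t <- !is.na(metadata$survival_time)
  if (any(has_t & is.na(metadata$event)))
    stop("event must be present wherever survival_time is present")
  if (any(metadata$survival_time[has_t] < 0))
    stop("survival_time must be non-negative")
  ev <- metadata$event[!is.na(metadata$event)]
  if (length(ev) && !all(ev %in% c(0, 1)))
    stop("event must be 0 or 1")
  metadata
}

#' Construct a gene ranking
#'
#' A gene ranking is an ordered table of all genes of a study with a
#' per-gene score and a method tag (`RF`, `EPS`, `DE`, `FC` or
#' `imported`). Ranks are the gap-free permutation `1..G`; for
#' score-based methods scores are non-increasing in rank.
#'
#' @param gene_id character vector of unique gene identifiers, already in
#'   rank order.
#' @param score numeric scores aligned with `gene_id` (may be `NA` for
#'   imported rankings that carry no score).
#' @param method one of `"RF"`, `"EPS"`, `"DE"`, `"FC"`, `"imported"`.
#' @return A data frame of class `gene_ranking` with columns `rank`,
#'   `gene_id`, `score` and attribute `method`.
#' @export
gene_ranking <- function(gene_id, score, method) {
  method <- match.arg(method, c("RF", "EPS", "DE", "FC", "imported"))
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("gene ranking contains duplicate gene_ids")
  if (length(score) != length(gene_id))
    stop("score and gene_id lengths differ")
  out <- data.frame(rank = seq_along(gene_id), gene_id = gene_id,
                    score = as.numeric(score), stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' @rdname gene_ranking
#' @param x a `gene_ranking`.
#' @export
ranking_method <- function(x) attr(x, "method")

# Order genes by decreasing score, ties broken lexicographically by gene id;
# the shared tie rule of the FC, RF and EPS rankers.
rank_descending <- function(scores, method) {
  stopifnot(!is.null(names(scores)))
  ord <- order(-scores, names(scores), method = "radix")
  gene_ranking(names(scores)[ord], unname(scores[ord]), method)
}

#' Top genes of a ranking
#'
#' @param ranking a [gene_ranking()].
#' @param k number of leading genes to return.
#' @return Character vector of the first `k` gene identifiers.
#' @export
top_genes <- function(ranking, k) {
  stopifnot(inherits(ranking, "gene_ranking"), k >= 1, k <= nrow(ranking))
  ranking$gene_id[seq_len(k)]
}
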