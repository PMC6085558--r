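# One-call orchestration of the per-dataset methodology: normalize,
# split, rank with every method, evaluate nested survival signatures and
# compare methods pairwise, with optional on-disk artifacts and manifest.

#' Run the full multi-method comparison on one dataset
#'
#' Executes the complete per-dataset methodology: median-of-ratios
#' normalization, the balanced train / case-only validation split,
#' gene rankings by each requested method (absolute fold change `FC`,
#' univariate-test `DE` or an imported external ranking, random-forest
#' permutation importance `RF`, and the `EPS` pipeline), nested survival
#' signatures of sizes `1..i_max` per ranking, one median-split log-rank
#' test per signature on the validation cohort, and pairwise win counts
#' between methods. With three methods and `i_max = 20` this performs 60
#' log-rank tests. Rerunning with the same inputs and seeds reproduces
#' every ranking bit-identically.
#'
#' @param matrix a raw-count [expression_matrix()].
#' @param metadata validated metadata with `condition` and survival
#'   fields for the validation samples.
#' @param methods subset of `c("FC", "DE", "RF", "EPS")`.
#' @param i_max largest signature size (default 20).
#' @param seeds named list of per-stage seeds (`split`, `rf`, `eps`);
#'   missing entries are filled from `base_seed` and recorded.
#' @param base_seed integer used to derive unspecified stage seeds.
#' @param rf_config a [forest_config()] for the `RF` method.
#' @param eps_epochs,eps_q,eps_n_per_class,eps_arch EPS stage controls
#'   (see [rank_by_eps_pipeline()]).
#' @param de_ranking_path optional TSV of an externally computed
#'   differential-expression ranking; when given it replaces the
#'   univariate-test ranking as the `DE` method.
#' @param out_dir optional directory; when given, rankings, per-signature
#'   p-values, the comparison table and a manifest (package version,
#'   seeds, md5 checksums of every artifact) are written there.
#' @return List: `rankings` (named list of [gene_ranking()]),
#'   `evaluations` (named list of [evaluate_ranking()] frames),
#'   `comparison` (a [compare_methods()] table), `split`, `size_factors`,
#'   `seeds`, `n_logrank_tests`, and `manifest` when `out_dir` was given.
#' @export
run_full_comparison <- function(matrix, metadata,
                                methods = c("FC", "DE", "RF", "EPS"),
                                i_max = 20, seeds = list(), base_seed = 1,
                                rf_config = NULL,
                                eps_epochs = 200, eps_q = 0.1,
                                eps_n_per_class = 400, eps_arch = NULL,
                                de_ranking_path = NULL, out_dir = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  methods <- match.arg(methods, c("FC", "DE", "RF", "EPS"),
                       several.ok = TRUE)
  metadata <- validate_metadata(metadata)
  for (stage in c("split", "rf", "eps"))
    if (is.null(seeds[[stage]]))
      seeds[[stage]] <- sub_seed(base_seed, match(stage, c("split", "rf",
                                                          "eps")))
  if (is.null(rf_config)) rf_config <- forest_config(seed = seeds$rf)

  size_factors <- estimate_size_factors(matrix)
  normalized <- normalize_counts(matrix, size_factors)
  split <- make_split(metadata, seed = seeds$split)
  features <- transform_features(normalized, split)

  rankings <- list()
  if ("FC" %in% methods)
    rankings$FC <- rank_by_fold_change(normalized, metadata, split)
  if ("DE" %in% methods) {
    rankings$DE <- if (is.null(de_ranking_path)) {
      rank_by_univariate_test(features, metadata, split)
    } else {
      import_external_ranking(de_ranking_path, universe = gene_ids(matrix))
    }
  }
  if ("RF" %in% methods)
    rankings$RF <- rank_by_random_forest(features, metadata, split,
                                         config = rf_config)$ranking
  if ("EPS" %in% methods)
    rankings$EPS <- rank_by_eps_pipeline(
      features, metadata, split, arch = eps_arch, epochs = eps_epochs,
      q = eps_q, n_per_class = eps_n_per_class, seed = seeds$eps)$ranking

  evaluations <- lapply(rankings, evaluate_ranking, matrix = normalized,
                        metadata = metadata, split = split, i_max = i_max)
  comparison <- if (length(evaluations) >= 2L) {
    compare_methods(evaluations)
  } else {
    NULL
  }

  result <- list(rankings = rankings, evaluations = evaluations,
                 comparison = comparison, split = split,
                 size_factors = size_factors, seeds = seeds,
                 n_logrank_tests = as.integer(length(evaluations) * i_max))
  if (!is.null(out_dir))
    result$manifest <- write_run_artifacts(result, out_dir)
  result
}

# Serialize every artifact of a run and return the manifest.
write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (m in names(result$rankings)) {
    p <- file.path(out_dir, paste0("ranking_", m, ".tsv"))
    write_ranking_tsv(result$rankings[[m]], p)
    paths <- c(paths, p)
  }
  pvals <- do.call(rbind, result$evaluations)
  p <- file.path(out_dir, "signature_pvalues.tsv")
  write.table(pvals, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(result$comparison)) {
    p <- file.path(out_dir, "comparison.json")
    jsonlite::write_json(result$comparison, p, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "epsrank",
    version = as.character(utils::packageVersion("epsrank")),
    seeds = result$seeds,
    n_logrank_tests = result$n_logrank_tests,
    files = data.frame(path = basename(paths),
                       md5 = unname(tools::md5sum(paths)),
                       stringsAsFactors = FALSE))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  manifest
}

#' Run a comparison from a YAML configuration
#'
#' The configuration either points at a dataset (`counts`, `metadata`
#' paths accepted by [load_dataset()]) or requests a simulation
#' (`simulate:` block with [simulate_dataset()] /
#' [simulate_survival()] parameters). Remaining keys mirror the
#' arguments of [run_full_comparison()]; unspecified stage seeds are
#' derived from `base_seed` and recorded in the manifest.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return A [run_full_comparison()] result.
#' @export
run_from_config <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    surv_args <- sim_args[intersect(names(sim_args),
                                    c("baseline_hazard", "censor_rate"))]
    sim_args <- sim_args[setdiff(names(sim_args),
                                 c("baseline_hazard", "censor_rate"))]
    sim <- do.call(simulate_dataset, sim_args)
    normalized <- normalize_counts(sim$matrix)
    metadata <- do.call(add_simulated_survival,
                        c(list(metadata = sim$metadata,
                               matrix = normalized, truth = sim$truth,
                               seed = sub_seed(config$base_seed %||% 1, 9L)),
                          surv_args))
    matrix <- sim$matrix
  } else {
    ds <- load_dataset(config$counts, config$metadata)
    matrix <- ds$matrix
    metadata <- ds$metadata
  }
  args <- config[intersect(names(config),
                           setdiff(names(formals(run_full_comparison)),
                                   c("matrix", "metadata", "out_dir")))]
  do.call(run_full_comparison,
          c(list(matrix = matrix, metadata = metadata,
                 out_dir = out_dir %||% config$out_dir), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
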