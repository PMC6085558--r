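# epsrank

Supervised gene selection for case-control RNA-Seq studies, with a
survival-signature benchmark.

Differential-expression analysis tests each gene univariately and can
miss genes whose discriminative power only shows in concert with
others. `epsrank` ranks the genes of a tumor/normal cohort with two
multivariate, supervised methods and measures every ranking by how well
its top genes stratify survival in a held-out validation cohort:

- **RF** — a random-forest classifier on the training samples, genes
  ranked by out-of-bag *permutation importance* (mean increase in a
  tree's out-of-bag misclassification error when the gene's values are
  permuted).
- **EPS (Extreme Pseudo-Samples)** — a variational autoencoder learns a
  latent representation of expression profiles; a ridge-logistic
  separator is fitted between classes in latent space; balanced
  *pseudo-samples* are decoded from the furthest region of each class's
  side of the separator; genes are ranked by the absolute coefficients
  of a ridge-logistic model fitted on the standardized pseudo-samples.
- Baselines: absolute fold change
  `|log2((mean_case + 0.5) / (mean_control + 0.5))|`, a Welch-t /
  Benjamini-Hochberg univariate ranking, and import of externally
  computed differential-expression rankings.

Evaluation follows the survival-signature design: nested signatures
`sig_i = {top 1, ..., top i}` for `i = 1..20`, a ridge-penalized Cox
model per signature on the validation cohort, a median split of the Cox
risk score, a two-group log-rank test per signature (60 tests for three
methods), and pairwise win counts across methods. Ranking stability
across repeated seeded runs and a stratified subsample experiment
(20% of samples, at least 20 controls) round out the harness.

A negative-binomial simulator with planted signal genes, planted size
factors, correlated gene blocks and expression-linked exponential
survival makes the entire pipeline testable with known ground truth.

## Worked example

```r
library(epsrank)

# a synthetic cohort: 500 genes (10 discriminative at |log2FC| = 2),
# 150 tumors, 50 healthy samples, survival linked to the signal genes
sim  <- simulate_dataset(n_genes = 500, n_case = 150, n_control = 50,
                         n_signal = 10, effect_log2fc = 2, seed = 1)
norm <- normalize_counts(sim$matrix)
md   <- add_simulated_survival(sim$metadata, norm, sim$truth,
                               censor_rate = 0.3, seed = 1)

run <- run_full_comparison(sim$matrix, md, methods = c("DE", "RF", "EPS"),
                           i_max = 20, base_seed = 1, eps_epochs = 100)

run$n_logrank_tests
#> [1] 60

# how many of the 10 planted genes does each method put in its top 20?
sapply(run$rankings, function(r)
  length(intersect(top_genes(r, 20), sim$truth$signal_genes)))
#>  DE  RF EPS
#>  10  10  10

run$comparison
#>   method_a method_b wins_a wins_b ties n_compared
#> 1       DE       RF     11      4    5         20
#> 2       DE      EPS     13      4    3         20
#> 3       RF      EPS      6     11    3         20
```

All three methods recover every planted gene here — with only ten
strongly shifted genes this synthetic cohort is easy for a univariate
test too, so the planted-truth recovery mainly validates the machinery.
The comparison table counts, for each pair, the signature sizes at
which each method's log-rank p-value was strictly smaller; that win
count is the per-dataset score used to compare methods.

Individual stages are exposed as plain functions
(`estimate_size_factors()`, `make_split()`, `rank_by_fold_change()`,
`rank_by_random_forest()`, `train_vae()`, `fit_separator()`,
`draw_pseudo_samples()`, `rank_by_eps()`, `evaluate_signature()`,
`stability_analysis()`, `subsample_experiment()`, ...), and
`inst/cli/epsrank.R` is a thin command-line wrapper
(`Rscript inst/cli/epsrank.R run --config run.yaml --out dir/`).
See the methods vignette (`vignettes/epsrank-methods.Rmd`) for the
models, parameter meanings and design choices.

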