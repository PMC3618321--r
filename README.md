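# pathvar

Single-sample pathway activity scoring for transcriptomics, with the
simulation benchmarks that characterise it.

Given a normalized genes × samples expression matrix (continuous log2
microarray values or RNA-seq counts) and a collection of gene sets (GMT),
`pathvar` produces a gene sets × samples matrix of per-sample enrichment
scores — pathway-level features usable in any downstream analysis
(differential activity, survival models, clustering) without phenotype
labels.

## The method

The core scorer is a non-parametric gene set variation approach:

1. **Expression-level statistic.** Per gene, a kernel estimate of the
   cumulative density of its expression across samples, evaluated at each
   sample's value: Gaussian kernel
   `z_ij = (1/n) Σ_k Φ((x_ij − x_ik)/h_i)` with bandwidth `h_i = s_i/4`
   for continuous data, or a discrete Poisson kernel
   `z_ij = (1/n) Σ_k P(Y ≤ x_ij), Y ~ Pois(x_ik + 0.5)` for counts. This
   puts genes with different dynamic ranges on a common scale.
2. **Symmetric ranks.** Per sample, `z` is ranked and folded:
   `r_ij = |p/2 − rank|`, up-weighting both tails.
3. **KS-like random walk.** Per (sample, gene set), traversing genes by
   decreasing `z`, the difference between the cumulative `τ`-weighted
   in-set rank mass (normalized to 1) and the cumulative out-of-set
   fraction.
4. **Enrichment score.** Either the walk's signed maximum deviation
   (`es_mode = "max"`; bimodal under the null) or, by default, the sum of
   the largest positive and largest negative excursions
   (`es_mode = "diff"`; unimodal, approximately normal null — two-sided
   excursions cancel).

Three comparator single-sample methods are included behind the same
interface: `plage()` (first right-singular vector of the standardized set
submatrix), `combined_zscore()` (Stouffer sum `Σ z_ij / sqrt(|γ|)`), and
`ssgsea()` (integrated weighted rank-ECDF difference, globally
range-normalized). A simulation module generates two-group expression data
from a linear additive model `y_ij = α_i + β_j + ε_ij` and runs the
power/type-I, differential-pathway AUC, and survival-time benchmark
harnesses; `dip_statistic()`/`dip_test()` provide Hartigan's dip test of
unimodality used to characterise the null score distributions.

## Worked example

```r
library(pathvar)
set.seed(42)
x <- matrix(rnorm(200 * 20), 200, 20,
            dimnames = list(paste0("g", 1:200), paste0("s", 1:20)))
x[1:15, 11:20] <- x[1:15, 11:20] + 1.5   # pathway 1 up in samples 11-20
expr <- expression_matrix(x, "continuous")
gsc <- gene_set_collection(list(active = paste0("g", 1:15),
                                background = paste0("g", 101:130)))
gsc <- apply_size_filter(gsc, expr)
#> size filter [10, 500]: kept 2 of 2 gene sets (0 too small, 0 too large)
es <- gsva_scores(expr, gsc)
round(es[, c(1:3, 11:13)], 2)
#>               s1    s2    s3   s11   s12  s13
#> active     -0.31 -0.54 -0.61  0.04  0.45 0.43
#> background -0.23 -0.09  0.23 -0.20 -0.01 0.23
apply(es, 1, function(s) t.test(s[1:10], s[11:20])$p.value)
#>     active background
#>    1.6e-10    4.0e-01
```

The `active` pathway's scores separate the two sample groups (t-test
p ≈ 2e-10); the random `background` set does not (p ≈ 0.4). Scores lie in
[−1, 1]; positive means the set's genes sit concordantly in the upper tail
of that sample's expression ranking.

File-based workflows use `read_expression()` / `read_gmt()` /
`write_scores()`, or the command-line wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "pathvar.R", package = "pathvar"))')" \
  score -i expr.tsv -g sets.gmt -o scores.tsv --method gsva --es diff
```

with `simulate`, `benchmark` and `fixture` subcommands for the simulation
harnesses (see `--help` of each).

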