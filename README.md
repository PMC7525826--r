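# xintro

Tools for asking whether the X chromosome resists interspecific gene flow,
starting from nothing but a fragmented draft assembly and a hybrid zone.

In XY species, females carry two X copies and males one. `xintro` exploits
this twice:

1. **Sex-linkage screen.** Contigs of a draft assembly are classified from
   male/female whole-genome coverage: an X-linked contig shows a
   male:female log2 fold-change of −1 (one copy vs two), an autosomal contig
   0. Each contig gets an exact conditional count test (conditional on the
   total count *T*, the male sum is Binomial(*T*, π) under the null, with π
   the male share of the library sizes; a negative-binomial convolution mode
   handles between-individual overdispersion), Benjamini–Hochberg correction,
   and a three-way call. Candidates are validated by homology to an annotated
   reference karyotype (≥ 50% per-block query coverage, best-match
   chromosome) and by qPCR relative quantification (ΔΔCt, fold-change
   2^ΔΔCt = 2 expected for X targets).
2. **Genomic cline analysis.** Per-locus Bayesian genomic clines are fitted
   to hybrid-zone SNPs: the probability that a gene copy in an individual of
   hybrid index *h* derives from parental population 1 is
   φ = h + 2h(1−h)(α + β(2h−1)), with α the direction and β the amount of
   introgression (β > 0 = reduced introgression, the barrier-locus
   signature). Hybrid indices, cline parameters and parental allele
   frequencies are sampled jointly by MCMC (optionally with a
   genotype-uncertainty likelihood over allele-specific read counts);
   outliers are loci whose 95% credible interval excludes zero. A
   permutation test then compares the mean cline parameters of the X-linked
   SNP set against size-matched autosomal draws.

Simulators for every input (count matrices, PAF homology records,
hybrid-zone VCFs, qPCR plates) make the whole pipeline testable without
external data.

## Worked example

```r
library(xintro)

# --- stage 1: which contigs are X-linked? -----------------------------------
sim <- simulate_count_matrix(n_contigs = 4000, frac_x = 0.05, seed = 7)
cls <- classify_contigs(sim$counts, sim$samples)
summarize_classes(cls)
#>   class             n    pct mean_log2fc sd_log2fc
#> 1 female-biased   205  5.12    -0.980      0.145
#> 2 male-biased       5  0.125    0.196      0.00691
#> 3 unbiased       3790 94.8     -0.000730   0.0576
```

The 5% of contigs simulated as X-linked are recovered as female-biased with a
mean log2FC(M:F) of −0.98 — the expected −1 for one male copy versus two
female copies — while unbiased (autosomal) contigs sit at 0.

```r
# --- qPCR validation of candidate X contigs ---------------------------------
summarize_folds(fold_change(c(0.92, 1.55, 1.14, 1.17, 0.73)))
#>       n  mean    sd
#> 1     5  2.19 0.480
```

Five validation assays with those ΔΔCt values give a mean fold-change of
2.19 ± 0.48, consistent with the 2-fold female amplification expected of
X-linked sequence.

```r
# --- stage 2: do X-linked SNPs introgress differently? ----------------------
hz <- simulate_hybrid_zone(
  n_loci_autosomal = 150, n_loci_x = 25, n_parental0 = 16, n_parental1 = 16,
  n_admixed = 60, allele_freq_divergence = 0.9,
  true_beta = c(rep(0.8, 25), rep(0, 150)),   # X loci: reduced introgression
  seed = 7, out_dir = tempfile()
)
panel <- load_variants(hz$paths[["vcf"]], hz$paths[["samples"]]) |>
  filter_variants() |>
  thin_and_annotate(
    validated_x = grep("^xcontig", unique(hz$loci$contig), value = TRUE),
    unbiased    = grep("^acontig", unique(hz$loci$contig), value = TRUE),
    seed = 1
  )
fit <- fit_clines(panel, config = cline_config(n_chains = 2, n_steps = 4000,
                                               burn_in = 1500, thin = 10,
                                               seed = 7))
est <- tidy(fit)   # per-locus alpha/beta medians, CIs, outlier calls, R-hat

permutation_test(est$beta_med[est$linkage == "X"],
                 est$beta_med[est$linkage == "autosomal"],
                 n_perm = 10000, direction = "greater", seed = 7,
                 parameter = "beta")
#> <perm_test> beta observed mean(X) = 0.1808 vs 10000 null means (direction greater)
#>   empirical p = 9.999e-05  [distinct at the >95% rule]
```

The planted reduced-introgression signal on the X-like loci is recovered: the
observed mean β of the X set exceeds every one of 10,000 size-matched
autosomal permutation means. `hybrid_index(fit)` returns the per-individual
hybrid-index posteriors, `tabulate_outliers(est)` the linkage × outlier
cross-table, and `autoplot()` methods draw the fitted clines, the null-mean
histogram and the log2FC distributions. `run_pipeline()` chains all stages
from files to a report; `simulate_inputs()` writes a complete demo input set.

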