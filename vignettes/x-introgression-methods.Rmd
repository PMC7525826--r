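---
title: "Detecting X-linked contigs and testing X-chromosome introgression with xintro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting X-linked contigs and testing X-chromosome introgression with xintro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xintro)
```

## The problem

In XY species that hybridize, theory predicts the X chromosome resists
introgression more than autosomes: X-linked incompatibilities are exposed in
hemizygous males, and several classic reproductive-isolation rules (Haldane's
rule, the large-X effect) concentrate on it. Testing this in a non-model
species with a fragmented draft assembly requires two inferences that this
package implements end to end:

1. **Which assembly contigs are X-linked?** Females carry two X copies and
   males one, so X-linked contigs show a male:female coverage ratio of 1/2
   (log2FC(M:F) of −1) in whole-genome resequencing, while autosomal contigs
   sit at 0. Candidates are then validated by homology to an annotated
   reference karyotype (the X is highly conserved across mammals) and,
   optionally, by qPCR relative quantification.
2. **Do X-linked SNPs introgress differently?** Per-locus Bayesian genomic
   clines are fitted to hybrid-zone genotypes, and the X-linked SNP set is
   compared against the autosomal background with a permutation test on the
   mean cline parameters.

Every input format has a simulator in the package, so the full pipeline is
testable without any external data; the simulators' defaults are the study
conditions the analysis assumes, not tuning knobs.

## Stage 1: coverage-ratio detection of X-linked contigs

`classify_contigs()` screens an idxstats-style count matrix from a small,
sexed panel (two males, two females by default). Contigs with CPM > 0.2 in
fewer than two individuals are set aside as `filtered` — near-zero counts
carry no power. For each remaining contig an exact conditional test compares
the male and female count sums: conditional on the total $T$, the male sum is
$\mathrm{Binomial}(T, \pi)$ under the null of a shared per-read rate, with
$\pi$ the male share of the summed library sizes, and the two-sided $p$ sums
all outcomes no more probable than the observed one. Benjamini–Hochberg
correction at $\alpha = 0.05$ and the sign of
$\log_2((\overline{\mathrm{CPM}}_M + c)/(\overline{\mathrm{CPM}}_F + c))$
give the three-way call (female-biased / male-biased / unbiased). The
pseudo-count $c$ (0.5 reads, rescaled to CPM) only matters for near-empty
contigs.

Two modelling points deserve emphasis:

* **What the overdispersion is.** Coverage varies enormously *between
  contigs* (mappability, repeat content), and `simulate_count_matrix()`
  models this as a Gamma-distributed contig effect shared by all individuals:
  marginally each count is negative-binomial with dispersion $d$
  (variance $\mu + d\mu^2$; $d = 0$ is Poisson), but the male:female contrast
  at a fixed contig remains conditionally Poisson. That conditional behaviour
  is what makes a coverage screen with $n = 2$ per sex work at all: if the
  same overdispersion acted independently *between individuals*, the log2FC
  standard error would saturate at $\sqrt{d}/\ln 2$ (≈ 0.32 at $d = 0.05$)
  and a 2-fold effect could never be called at high sensitivity with a
  calibrated test, at any depth. The package still offers an `"nb"` test mode
  (exact convolution of per-individual negative binomials at a
  moment-estimated common dispersion) for data where between-individual
  overdispersion is real; on the shared-effect simulations its estimated
  dispersion is ≈ 0 and it reproduces the Poisson mode.
* **Library sizes.** The simulator emits a common `library_size` for every
  individual, mirroring a design in which libraries are subsampled to equal
  input before mapping. Using raw column sums instead would bias the null:
  male totals are depressed by the half-covered X contigs, which shifts the
  expected male share at *autosomal* contigs away from the truth (measured as
  a ~9% false-positive rate at 10% X content versus ~0.5% with equal library
  sizes). `classify_contigs()` therefore prefers an explicit library-size
  column and falls back to column sums.

Homology validation (`read_paf()`, `assign_contigs()`, `crosstab_linkage()`)
assigns each contig to the reference chromosome of its best alignment block,
requiring the block to cover ≥ 50% of the contig; coverage is per block, not
summed, matching the aligner-level filter such screens use (a summed mode is
available). Ties on matched bases across chromosomes are reported as
`ambiguous`, never resolved silently. The validated X set is the intersection
of coverage evidence (female-biased) and synteny evidence (assigned to the
reference X). The pseudoautosomal region, which escapes hemizygosity, is
invisible to this design by construction.

qPCR validation (`delta_delta_ct()`, `fold_change()`) assumes amplification
efficiency 2 exactly; replicates are averaged on the Ct scale and ΔΔCt is
signed so that the one extra template doubling in females gives +1, i.e. a
fold-change of 2 for true X targets.

## Stage 2: Bayesian genomic clines

For an admixed individual with hybrid index $h$ (the fraction of its genome
from parental population 1), the probability that a gene copy at locus $j$
derives from population 1 is

$$\phi_j(h) = h + 2h(1-h)\,\big(\alpha_j + \beta_j(2h - 1)\big),$$

truncated into $[10^{-6}, 1 - 10^{-6}]$. $\alpha_j$ shifts the cline centre
(direction of introgression; $\alpha > 0$ = excess population-1 ancestry) and
$\beta_j$ its rate ($\beta > 0$ = reduced introgression, the signature of a
barrier locus). A genotype is $\mathrm{Binomial}(2, q)$ with
$q = \phi p_1 + (1 - \phi) p_0$; in the genotype-uncertainty mode the
genotype is latent and the likelihood sums over it with a binomial read layer
(per-read alternate probability $(g/2)(1-e) + (1 - g/2)e$).

`fit_clines()` samples $\{h_i\}$, $\{\alpha_j, \beta_j\}$ and the parental
allele frequencies jointly by Metropolis-within-Gibbs: $p_{0j}, p_{1j}$ carry
Beta(1,1) priors updated by the parental allele counts and are Gibbs-refreshed
each sweep; $h_i$ is Uniform(0,1); $\alpha_j, \beta_j$ have independent
zero-mean normal priors. Random-walk scales adapt toward ~35% acceptance
during burn-in only, so the post-burn-in kernel is fixed. The default run is
5 chains × 50,000 iterations, 30,000 burn-in, thinned by 20 (5,000 merged
draws); `tidy()` reports posterior medians, equal-tailed 95% intervals, the
CI outlier call (interval excluding zero), split-R̂ and effective sample
sizes. Loci with R̂ > 1.1 are flagged, never dropped. "Burn-in of 30,000 for
50,000 steps" is read as 50,000 total with the first 30,000 discarded; both
readings are expressible through the config.

### Why the cline priors default to sd 0.3

The cline family is nearly closed under composition: applying a common shift
$(a_0, b_0)$ to every locus while reparameterizing each hybrid index with the
inverse warp changes the likelihood only at second order. Marginalizing the
uniform-prior hybrid indices along this soft ridge favours flattened clines
(each $h_i$ integral widens as $|d\phi/dh|$ falls), so with diffuse
$\mathcal N(0,1)$ priors a few-hundred-locus panel drifts: on null
simulations (200 loci, 60 admixed) we measured a median $\alpha$ of −0.4, a
hybrid-index bias of +0.09 and 20% of null 95% intervals excluding zero. The
prior is the only term that pins this warp at moderate locus counts (at
genome scale, 10⁴ loci, the cost $L a_0^2 / 2\sigma^2$ pins it for any
reasonable $\sigma$). With $\sigma = 0.3$ the same null simulations give
≈ 2–5% interval exclusion and hybrid-index RMSE ≈ 0.05, while per-locus
effects of the size that matters (|α| ≈ 1, β ≈ 0.8) remain clearly separated
because 200 admixed individuals dominate the prior at a single locus.
$\sigma = 0.3$ also keeps three prior standard deviations inside the range
where $\phi$ is not pinned at its truncation over most of $h$ — values far
outside it are not distinguishable anyway. Both sds are exposed in
`cline_config()`.

Other numerical choices: the point estimate is the posterior median (robust
to the skew that truncation induces at extreme parameters; means are also
reported); parental frequencies can be held fixed (`fix_parental`) which is
also how the sampler is validated against a dense-grid integration oracle;
chains are initialized from a moment estimate of $h$ (mean aligned allele
dosage at informative loci) and differ only by a seed offset, so runs are
exactly reproducible.

## Stage 3: X versus autosome comparison

`permutation_test()` draws, 10,000 times, an autosomal subset the size of the
X-linked set (97 loci at panel scale) without replacement and records its
mean point estimate. The X set is called distinct when its observed mean is
more extreme than the permuted mean in > 95% of draws, in a direction chosen
a priori (`"greater"` for β — reduced introgression; `"less"` for α — excess
parental-0 ancestry). The add-one-corrected empirical $p$
$(1 + \#\{\text{as or more extreme}\})/(n_{\mathrm{perm}} + 1)$ is reported
alongside, so the decision rule and a non-zero $p$ both survive.
`tabulate_outliers()` crosses linkage class with the CI outlier categories
for each parameter.

`expand_and_merge()` turns the alignment blocks of outlier-bearing contigs
into candidate regions: 500 kb flanks on both sides, clamped to the
chromosome, with overlapping or bookended intervals merged (members unioned)
via `IRanges::reduce()`. Coordinates are 0-based half-open internally and
rendered 1-based inclusive by `format_region()`.

## What the simulators do and do not emulate

`simulate_hybrid_zone()` draws parental genotypes from their population
frequencies, admixed genotypes through the cline model itself (so generator
and likelihood are exact inverses), allele depths as Poisson totals with
binomial error-perturbed allele counts, and writes standard VCF 4.2 + TSV
that round-trip through the package's own readers. Parental allele-frequency
divergence is controlled by drawing $p_0 \sim U(0,1)$ and clipping
$p_0 \pm \delta$; hybrid indices default to Beta(0.8, 0.8), a
multigeneration hybrid swarm with both backcross directions. All simulated
cline individuals are female, mirroring the female-only analysis set that
avoids hemizygosity bias.

Not emulated: linkage disequilibrium along chromosomes (loci are exchangeable
given $h$), recombination maps, genotype-calling artefacts beyond symmetric
per-read error, reference bias, or population structure within parental
ranges. Passing recovery tests on these simulations therefore demonstrates
correctness of the inference machinery under the model's own assumptions, not
robustness to real-data violations of them.

## Problem sizes used in the checks

The packaged checks run a screen of 10,000 contigs (10% X, negative-binomial
dispersion 0.05, ~637 expected reads per contig — a 50M-read library over
~78,500 contigs), and a cline panel of 300 loci (50 X-like carrying planted
effects β = 0.8 or α = −0.9, 250 null) × 200 admixed + 16 + 16 parental
females with chains scaled to 5,000 steps / 2,000 burn-in. These sizes were
chosen so the whole suite exercises every stage at meaningful power on a
single CPU; the full-scale defaults (10,353 SNPs, 50,000-step chains) are a
config change, not a code change.

## Known limitations

* The exact NB convolution test assumes a common dispersion across contigs;
  contig-specific dispersions with $n = 2$ per sex are not estimable.
* The cut-style Gibbs update of parental frequencies (parental data only)
  slightly understates their posterior coupling with the admixed data; a
  `--fix-parental` style flag exposes the fixed-frequency alternative.
* Outlier calling is per-locus CI-based only; genome-wide quantile flags and
  linkage-aware (CAR) priors are out of scope.
* Y-linked sequence cannot be separated from other male-biased coverage, and
  the male-biased class is deliberately left unvalidated.
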