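---
title: "Comparing sorted cell population transcriptomes with popmarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing sorted cell population transcriptomes with popmarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

Studies that FACS-sort several immune cell populations from the same donors —
for example tissue-resident macrophages such as vitreous hyalocytes, retinal
microglia, and the classical / intermediate / non-classical monocyte subsets —
end with a gene × sample matrix of read counts and three recurring questions:

1. **How similar are two populations' transcriptomes as a whole?**
2. **Which genes mark one population against all the others?**
3. **Are any samples contaminated by a different population?**

`popmarkers` implements this count-matrix-to-conclusions pipeline:
normalization, patient (batch) adjustment, differential expression, a
percentile-rank similarity statistic, two-step marker discovery, panel-based
contamination QC, and over-representation analysis — together with a
negative-binomial simulator that provides planted ground truth for every
stage, so the whole pipeline is validated end to end.

```{r, eval = FALSE}
library(popmarkers)
design <- default_design(n_markers = 20, marker_log2fc = 8, seed = 1)
cfg <- pipeline_config(focal = "hyalocyte", design = design, seed = 1)
summary <- run_pipeline(cfg, out_dir = "run1")
```

## Normalization

Two scales are produced. **TPM** divides each count by its feature length in
bp, then rescales each sample so the column sums to $10^6$; it is used for
"top expressed gene" style summaries where length bias matters. **Size-factor
normalization** uses the median-of-ratios estimator: for sample $j$,
$s_j = \mathrm{median}_g \, k_{gj} / (\prod_{j'} k_{gj'})^{1/n}$ over genes
with a strictly positive geometric mean. The median is taken on the log
scale, so an even number of usable genes averages the two central ratios
geometrically. All testing and marker statistics run on
size-factor-normalized counts; genes with zero counts in every sample are
removed first.

## Patient adjustment

Paired designs — every population sorted from the same donors — allow
donor-level expression shifts to be removed before visualization. Per gene,
`adjust_for_patient()` fits least squares of $\log_2(\text{normalized} + 1)$
on population indicators plus sum-to-zero patient indicators (via
`limma::removeBatchEffect`) and subtracts the patient contribution. Two
properties matter and are tested:

* the adjustment is a projection, hence idempotent;
* planted patient offsets are removed *exactly* on balanced designs — but
  only their donor-contrast component. A shift shared by all donors is
  absorbed by the intercept and is not identifiable by any batch method, so
  the simulator centres its per-gene patient effects across donors.

Differential testing never uses the adjusted matrix; the patient enters the
count model directly (below). The pseudo-count (default 1) is configurable.

## Differential expression

`nb_wald_test()` fits, per gene, a log-linear negative-binomial model of
counts on a population indicator — plus patient indicators when donors are
shared — with log size factors as offsets and a fixed dispersion
$\alpha_g$ (variance $\mu + \alpha\mu^2$). The Wald statistic
$\hat\beta / \mathrm{SE}$ gets a two-sided normal p-value,
Benjamini–Hochberg adjustment across all converged genes, and the DEG rule
$|\log_2 FC| > 2$ and adjusted $p < 0.05$ (both thresholds configurable).

Dispersions come from `estimate_dispersions()`: a method-of-moments
gene-wise estimate pooled within populations, a robust mean–dispersion trend
$\alpha(\mu) = a_0 + a_1/\mu$, and a log-scale average of the two (trend
weight 0.5 by default). Genes whose moment estimate is non-positive carry no
evidence of overdispersion; they take the trend value rather than a
log-average against the $10^{-8}$ floor, which would otherwise drag their
dispersion orders of magnitude below the trend and make the test
anti-conservative.

This is intentionally a *simplified* DE engine: no Cox–Reid adjusted
dispersion likelihood, no independent filtering, no outlier handling, no
fold-change shrinkage. Its contract is statistical calibration at desk
scale, verified by simulation: under a null design (2,000 genes, 6 vs 6
samples) the suite checks that the empirical type-I error at nominal 0.05
stays within [0.03, 0.07] and that the DEG rule's false positive rate stays
below $10^{-3}$. Two numerical details: the linear predictor is clipped at
±30, so a gene with all-zero counts in one group (separation) ends with a
huge fold change but a diverging SE and a non-significant Wald p — the known
Wald artifact, accepted as a documented limitation; and genes whose IRLS
does not converge are reported with `NA` p-values and excluded from the BH
universe.

## Percentile-rank similarity

For each population, genes are ranked by mean normalized expression and the
ranks rescaled to [0, 100] (lowest gene 0, highest 100, ties averaged).
The per-gene similarity of two populations is
$1 - |\Delta\text{percentile}|/100$, and the overall similarity is the
squared Pearson correlation $R^2$ of the two percentile vectors, with the
correlation-test p-value attached. Percentiles are rank-based, hence
invariant to monotone transforms, and computed on size-factor-normalized
(not TPM) means by default, without patient adjustment; both choices are
configurable by passing a different matrix. Note that $R^2$ ignores the
correlation's sign: a perfectly reversed ranking also scores $R^2 = 1$ —
a property of the statistic itself, flagged here rather than hidden.

## Marker discovery

`find_markers()` applies two filters for a focal population:

1. **DE versus all**: the gene must be significantly upregulated
   ($\log_2 FC > 2$, adjusted $p < 0.05$) against *every* other population.
2. **Quantile non-overlap**: the 10th percentile of the gene's normalized
   expression across the focal population's *samples* must exceed the 90th
   percentile across every other population's samples (type-7 interpolation;
   levels configurable).

Specificity is the gap between those two quantiles in expression units, and
the top-k markers are ranked by specificity, ties broken by gene id for
determinism. The percentile here is a quantile across samples, not the
gene-rank percentile of the similarity module — the two readings are easy to
confuse, and the gene-rank reading would make a single gene's "10th
percentile higher than the 90th" degenerate, which is why the
sample-quantile reading is the default and only implemented one.
Validation on held-out data uses `score_panel()`: per-gene z-scores averaged
over the panel and a deterministic 1-d 2-means split (centres initialised at
the extremes), reporting the purity with which focal samples separate.

## Contamination QC

`qc_samples()` screens each sample against population marker panels with two
explicit rules. `foreign>own` fires when a foreign panel's mean
$\log_2$ expression exceeds the own panel's — a *dominant* foreign
signature. At a 50/50 admixture both panels shift by the same
$\log_2(0.5 \cdot 2^\tau + 0.5)$, so this rule alone is uninformative at
$f = 0.5$; detection there comes from `foreign-z`, an outlier test of the
sample's foreign-panel score against its population peers. The z-score uses
leave-one-out centring and a pooled within-population scale (all
populations, candidate excluded) to keep the null near-normal, and the
threshold (default 2) is interpreted per sample: the per-panel cutoff is
Šidák-adjusted across the foreign panels screened, so a pure sample's
expected false-flag rate is about $1 - \Phi(2) \approx 2.3\%$ however many
panels exist. The simulation suite checks that 50%-admixed samples are
flagged in ≥95% of runs while pure samples stay under a 5% false-flag rate,
and that the flag probability is monotone in the contamination fraction.

## Over-representation analysis

`ora()` is the generic hypergeometric test of a gene list against any GMT
collection over an *explicit* universe (typically the expressed genes):
$p = P(X \ge k)$ with universe $N$, set $K$, list $n$, overlap $k$, BH
across sets. No ontology structure, no database access; term hierarchies and
plot styles are out of scope.

## The simulator and what passing tests mean

`simulate_counts()` draws counts from
$\mathrm{NB}\!\left(s_i \cdot 2^{\beta_g + \tau_{g,\mathrm{pop}} + b_{g,\mathrm{patient}}},\ \alpha_g\right)$:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | genes |
| `populations` | 5 pops, 5–6 samples | study shape (29 samples, shared donors) |
| `baseline_log2_range` | [1, 11] | uniform log2 baseline means (counts ~2–2000) |
| `dispersion` | $a_0=0.05$, $a_1=5$ | bulk mean–dispersion trend $\alpha = a_0 + a_1/\mu$ |
| `libsize_sigma` | 0.3 | log-sd of library-size factors |
| `batch_sd` | 0.25 | log2-sd of per-gene patient shifts (centred) |
| `markers` | none | planted population-specific genes (one target each) |
| `contamination` | none | mean-vector mixing $(1-f)\cdot\text{own} + f\cdot\text{admixer}$ |
| `length_range` | [300, 10000] bp | log-uniform feature lengths (so TPM ≠ count ranks) |

The defaults mirror a five-population, up-to-nine-donor sorted-cell study at
a 2,000-gene desk scale; marker panels planted for QC experiments use 40
genes per population at $\log_2 FC = 6$, typical magnitudes for sorted-cell
panels. The generator reproduces NB moments, paired donor structure, length
bias and admixture — it does **not** model gene–gene correlation, GC or
positional bias, isoform structure, outlier samples, or un-shared donors.
Passing tests therefore demonstrate internal statistical correctness and
calibration under the stated generative model, not robustness to every
artifact of real sequencing data.

Problem sizes used by the validation suite (chosen as comfortable desk-scale
experiments): 200 null replicates of 2,000 genes for calibration; 10 seeds
of the default design with 20 planted markers for recovery; 100 seeds of a
600-gene five-population design for QC flag rates; 1,000 random instances
per estimator for oracle equivalence. `scripts/acceptance.R` re-runs scaled
versions of the same experiments from a command-line seed.

## Known limitations

* Wald inference with moment/trend dispersions is mildly anti-conservative
  at very small sample sizes; the calibration band, not numerical identity
  with any reference DE tool, is the contract.
* Separation (a group of all-zero counts) yields huge fold changes with
  non-significant p-values rather than a dedicated zero-handling rule.
* The `foreign-z` QC rule needs at least three same-population peers; the
  `foreign>own` rule is insensitive near 50/50 admixture by symmetry.
* Patient adjustment assumes patient effects are additive on the log scale
  and shared across populations; grand-mean donor shifts are unidentifiable.
* t-SNE-style embeddings are not provided; validation clustering uses the
  deterministic panel-score split instead.
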