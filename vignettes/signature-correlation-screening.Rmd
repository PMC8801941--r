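---
title: "Signature-correlation screening: model, assumptions and design choices"
author: "sigcorr maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-correlation screening: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigcorr)
```

# What this package computes

`sigcorr` implements a correlation-first analysis style for single-cell
RNA-seq: pathway activity is summarized per cell as the **percentage of
total UMI counts** falling in a gene set, and biology is screened by
ranking Pearson correlations of those scores — signature against
signature, transcription factor against target gene, condition against
condition — within a cell cluster. The motivating application is
testicular inflammation: linking Leydig-cell senescence (a CDKN-family
signature) to androgen synthesis, complement regulation, collagen/fibrosis
and cytokine pathways, and asking how those correlations shift between a
healthy condition and chronic orchitis. The package is the pipeline, not
the dataset: every stage is exercised against a synthetic generator with
planted, known correlation structure.

## The scoring primitive

For a gene set $S$ and cell $c$ with counts $x_{gc}$,

$$\mathrm{score}_S(c) = 100 \cdot \frac{\sum_{g \in S} x_{gc}}{\sum_g x_{gc}}.$$

Two consequences drive the design:

* **Depth invariance is exact.** Multiplying a cell's counts by any
  positive factor leaves its score unchanged, so scores are computed on
  *raw* counts and normalization is irrelevant to them. (It also makes
  the score a compositional quantity; see *Limitations*.)
* **Partition additivity.** Scores over any partition of the gene
  universe sum to exactly 100 per cell; the test suite asserts this to
  1e-9 in floating point.

Genes in a signature but absent from the matrix are dropped from the
numerator with a warning and reported as `n_genes_missing`; there is no
renormalization by list length. A signature with no measured genes is an
error, not a zero.

## QC and normalization

Cell filters are strict inequalities, gene filter inclusive, exactly as
conventionally written: detected genes $> 200$ and $< 7{,}000$,
mitochondrial percentage $< 20$ (computed on the raw matrix, before any
gene removal), genes kept when detected in $\ge 3$ cells. Order is fixed:
percent-mito, then cells, then genes. A cell with exactly 200 detected
genes, or exactly 20.0% mito, is removed. Mitochondrial genes are
recognized by the case-insensitive `mt-` symbol prefix (mouse
nomenclature); the generator names its planted mito genes the same way so
QC finds them by the same rule as real data.

Downstream gene-level statistics (DE, TF correlations, ligand–receptor
scores) use standard depth normalization,
$\ln(1 + 10^4\, x_{gc} / \mathrm{total}_c)$. This is a deliberate,
documented substitute for variance-stabilizing batch correction, which is
out of scope: conditions are analyzed separately except where a
correlation shift explicitly compares them, so no batch integration is
performed anywhere.

## The screens

**Signature screen.** Within one cluster × condition slice, the target
signature's score vector is correlated (Pearson, two-sided p from the
$t$-transform on $n-2$ df) against each candidate. Records pass when
$r \ge r_{\min}^{+}$ or $r \le r_{\max}^{-}$ — the per-figure cutoffs
(0.6, 0.32, −0.45, 0.75, −0.57, …) are plain configuration values, as no
rule generating them is known. Ranking is by $r$ descending, ties broken
lexicographically. p-values and a Benjamini–Hochberg column are reported
for transparency but **never** used to filter — the screens threshold on
$r$ alone, mirroring the analysis style this reproduces; readers should
treat the tables as exploratory rankings, not inference.

**TF screen.** Gene–gene correlations use normalized expression (the
documented split: signature–signature correlations use percentage scores;
anything involving individual genes uses normalized expression). TFs must
reach mean normalized expression ≥ 0.5 *within the screened slice* — the
most local reading of the "no < 0.5" rule, since the scale and slice it
was originally measured on are unstated. Three TFs (Hmgb4, Spz1, Tfam)
are excluded by default: their delayed transcription in elongating
spermatids leaves high ambient background in other clusters. Top-20 per
direction; a shortfall is a warning, not an error.

**Correlation shift.** Pairs present in both conditions report
$\Delta r = r_B - r_A$ and a `sign_flip` flag requiring opposite signs
*and* both $|r| > 0.1$ — the floor keeps noise-level correlations from
being narrated as flips.

**Differential expression.** Two-sided Wilcoxon rank-sum per gene on
normalized values, with the conventional prefilters: detection
$\max(\mathrm{pct}_A, \mathrm{pct}_B) \ge 0.2$ and
$|\mathrm{logFC}| \ge 0.25$ with
$\mathrm{logFC} = \ln(\overline{\mathrm{expm1}(A)} + 1) -
\ln(\overline{\mathrm{expm1}(B)} + 1)$ (natural log, the convention of
the tool lineage this follows). Survivors additionally need raw
$p \le 0.05$; no multiple-testing correction is applied to the filter
(an adjusted column is emitted, loudly, for transparency). Groups of ≤ 8
cells get the exact permutation distribution of the rank sum; larger
groups the normal approximation with tie and continuity corrections.

**Competitive gene-set test.** A simplified CAMERA-style procedure: for
per-gene statistics $z_g$ the set mean is compared to the out-of-set mean
with the variance inflated by $\mathrm{VIF} = 1 + (m-1)\bar\rho$, where
$\bar\rho$ is the mean pairwise correlation of the set genes' normalized
expression, clipped at 0 (the clip is logged when active; allowing
VIF < 1 would be anti-conservative). The declared divergence from the
full procedure: no moderated-statistic machinery, just the competitive
null, the VIF and a two-sided normal test. The acceptance suite shows the
point of the VIF directly: with 50 co-regulated genes
($\bar\rho \approx 0.2$) the unadjusted test rejects a true null in well
over 20% of runs while the adjusted test stays at nominal 5% ± 2%.

**Ligand–receptor permutation test.** Score = mean of [mean ligand
expression in sender, mean receptor expression in receiver] on normalized
values; null from shuffling cluster labels, add-one p-value
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + P)$. Sender and
receiver may be the same cluster (the shuffle then reuses one permuted
cell set, as a true label shuffle implies). Ordered pairs are distinct
throughout. Pairs under 10% detection in their cluster are scored but
flagged. Within one call, shuffles are shared across pairs — the
convention of the tool this reimplements; the test suite's null-rate
estimate instead runs pairs with independent streams so its binomial
error is clean.

# The synthetic world

The generator emulates exactly the structure the screens assume, and
nothing more:

* counts are negative binomial with variance $\mu + \mu^2/\theta$ and a
  single global size $\theta$ (default 2 — typical shallow-UMI
  overdispersion; per-gene dispersion would add realism the pipeline
  never exploits);
* per-cell library factors are log-normal (sdlog 0.35 default,
  a realistic spread of per-cell depth);
* per-gene base factors are log-normal (sdlog 0.7), giving the usual
  long-tailed expression distribution around `baseline_mean` 0.5 —
  about 1,300 counts on 2,000 genes, shallow-platform scale;
* discrete clusters perturb *background* gene means (log-normal,
  sdlog 0.25); module genes carry no cluster effect so planted
  correlations stay cluster-clean;
* mitochondrial genes are ordinary background genes whose means are
  rescaled so the expected mito share equals `mito_fraction` (default
  5%), and whose names carry the `mt-` prefix;
* each cluster receives `n_cells_per_cluster` cells in *each* condition
  (conditions are separate samples of the same tissue);
* a **module** is a gene block whose means are multiplied by
  $e^{\lambda z - \lambda^2/2}$ for a per-cell standard-normal latent
  $z$; modules sharing a latent factor co-vary, with sign given by the
  sign product of their loadings. The $-\lambda^2/2$ term keeps the
  expected mean loading-free, so `condition_mean_shift` is a pure fold
  change and `condition_loading` can flip a correlation between
  conditions without moving means.

**Planted correlation is operational, not closed-form.** The target
correlation between two modules' percentage scores is defined as the
large-$n$ Monte-Carlo limit under the generative model, computed by the
generator itself (default $10^5$ latent draws) with each module's count
total drawn as a single negative binomial moment-matched to the sum of
its genes' independent counts, and the background total moment-matched
the same way. No closed form is claimed: the score is a ratio of
correlated NB sums, and the exponential link plus the shared denominator
make any Gaussian formula an approximation. Pairs sharing no latent
factor (or with a zero effective loading) return exactly 0. Cluster-level
background perturbations are ignored in the target (they only jitter the
denominator; the effect is second order at realistic module shares).

Two consequences surfaced during development and are part of the stated
world rather than bugs:

* **Sign asymmetry.** Opposite-sign co-loaded pairs are slightly *more*
  negative than the mirrored positive pair: when one module rises it
  inflates the shared denominator and mechanically depresses the other
  module's score. Loadings planting negative targets are therefore
  calibrated separately.
* **Compositional dominance.** A planted module carrying a large share
  of a cell's counts compresses normalized fold changes of everything,
  including itself. Test worlds keep planted modules at realistic shares
  (≲ 15% of counts).

What the generator does **not** emulate — and hence what a green suite
does not establish robustness against: doublets, ambient RNA, batch
effects, per-gene dispersion structure, zero inflation beyond NB,
cluster-specific module regulation, and any real mouse-testis biology.
Loadings ship calibrated only so screens pass or fail informatively at
desk scale; no claim is made that they match effect sizes in the EAO
model, for which no effect-size information is available.

# Numerical and degenerate-input choices

* Correlations require $n \ge 3$ (hard error) and attach a low-$n$ flag
  below 10 cells; zero variance yields an explicit degenerate record
  (`r = NA`), never a silent 0.
* $|r| = 1$ reports $p = 0$ rather than evaluating the $t$-transform at
  a pole.
* All rankings break ties by name after $r$, so outputs are
  deterministic byte-for-byte; the MTX writer emits canonical
  column-major integer triplets for the same reason.
* Every stochastic routine takes its seed through one documented
  Lehmer-style derivation (`derive_seed`) from a single master seed, and
  restores the caller's RNG state afterwards.
* Zero-total cells: flagged (not dropped) by `percent_mt`, an error in
  `normalize_counts` and `score_signature` — they should never survive
  QC, and silently scoring them would hide upstream breakage.

# Open choices made here (and why)

* **Raw vs corrected counts for scores**: raw, because the percentage
  definition is only meaningful on counts and is depth-invariant anyway.
* **percent.mt before or after gene filtering**: before, on the raw
  matrix.
* **Was the p ≤ 0.05 DE filter raw or adjusted**: taken literally as
  raw; the adjusted column is emitted beside it.
* **Which per-gene statistic feeds the competitive test**: pluggable;
  signed normal scores from the Wilcoxon stage by default
  (`de_stats()`), declared rather than inferred.
* **Run configs**: JSON (`jsonlite` is universally available here);
  every stage block is validated before any stage executes.
* **DE null calibration is measured with the logFC prefilter off**: at
  realistic group sizes a null gene passes $|\mathrm{logFC}| \ge 0.25$
  only by extreme chance, and conditioning on that chance selects small
  p-values by construction — the detection prefilter, which is
  label-independent, stays on. The logFC threshold is exercised by the
  power and semantics tests instead.

# Limitations

Percentage scores are compositional: any strongly shifting set moves all
other scores mechanically, and correlations between scores inherit a
small negative background (kept negligible in the test worlds by using
small set shares). Screens report correlations, not effects: no partial
correlations, no library-size regression, no causal reading. The
ligand–receptor module bundles no interaction database and treats
ligand and receptor as single genes. Cluster labels are inputs;
clustering, embedding, batch correction and communication-pattern
decomposition are out of scope end to end.
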