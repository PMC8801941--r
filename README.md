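# sigcorr — signature-correlation screening for single-cell RNA-seq

`sigcorr` is an R package for a correlation-first style of scRNA-seq
analysis: pathway activity is summarized per cell as the **percentage of
total UMI counts in a gene set**, and biology is screened by ranking
Pearson correlations of those scores within a cell cluster — signature
against signature, transcription factor against target gene, and
condition against condition. It was built around the analysis pattern
used to link Leydig-cell senescence (the CDKN-family signature
Cdkn1a/1b/1c/2a/2b/2c/2d) with androgen synthesis, complement
regulation, collagen/fibrosis and cytokine pathways in mouse testis
under chronic inflammation, and to ask how those correlations *shift*
between healthy and inflamed conditions.

For a set $S$ and cell $c$:

$$\mathrm{score}_S(c) = 100\cdot\frac{\sum_{g\in S} x_{gc}}{\sum_g x_{gc}},
\qquad
r_{ST} = \mathrm{corr}\big(\mathrm{score}_S,\ \mathrm{score}_T\big)
\ \text{within one cluster × condition.}$$

## What's inside

| Stage | Function(s) | Notes |
|---|---|---|
| Synthetic data | `synthetic_config()`, `module_spec()`, `generate_counts()`, `planted_correlation()` | NB counts, log-normal library sizes, planted co-varying gene modules with known (Monte-Carlo) target correlations, condition shifts and correlation flips |
| I/O | `read_mtx()`, `write_mtx()`, `read_signatures()` (GMT/TSV), `read_annotation()` | 10x-style MTX triplet, genes × cells; canonical byte-stable writer |
| QC + normalization | `percent_mt()`, `filter_cells()`, `filter_genes()`, `run_qc()`, `normalize_counts()` | strict `nFeature > 200`, `< 7000`, `percent.mt < 20`; inclusive `min.cells = 3`; log1p depth normalization |
| Scoring | `score_signature()`, `score_table()` | percentage-of-counts on raw counts; exactly depth-invariant |
| Correlation screens | `pearson_cor()`, `correlation_screen()`, `tf_screen()`, `correlation_shift()` | threshold-ranked tables (e.g. `r >= 0.6 / r <= -0.45`), top-20 TF ranking with mean-expression ≥ 0.5 filter and Hmgb4/Spz1/Tfam exclusion, cross-condition sign-flip detection |
| Differential expression | `wilcoxon_de()`, `deg_counts()` | Wilcoxon rank-sum, `logfc.threshold = 0.25`, `min.pct = 0.2`, raw `p <= 0.05`; exact enumeration for tiny groups |
| Gene-set enrichment | `competitive_test()`, `enrichment_table()`, `de_stats()` | competitive test with VIF = 1 + (m−1)·ρ̄ inter-gene-correlation adjustment |
| Ligand–receptor | `lr_test()`, `pair_counts()` | cluster-label permutation null, add-one p-values, ordered cluster pairs |
| Orchestration | `run_pipeline()`, `sigcorr_main()` | JSON run config, stage validation up front, JSON manifest with checksums; `inst/exec/sigcorr` CLI |

Default signature lists (the senescence CDKN set, the mCRPs set
Cd59a/Cd59b/Cd55b/Cd55/Cd46, and the text-named androgen-synthesis and
collagen genes) ship in `inst/extdata/default_signatures.gmt`; fuller
pathway collections are user-supplied files.

## Worked example

A two-condition world ("Nt" healthy, "O50t" inflamed) with three planted
modules on one latent factor: senescence (up 1.5× in O50t),
androgen synthesis (anticorrelated with senescence), and complement,
whose loading *flips sign* in O50t.

```r
library(sigcorr)
cfg <- synthetic_config(
  n_genes = 1200, n_cells_per_cluster = c(Lc = 400, Im = 150),
  conditions = c("Nt", "O50t"),
  modules = list(
    module_spec("Senescence", 30, loading = 0.42, latent_factor_id = "f",
                condition_mean_shift = c(O50t = 1.5)),
    module_spec("Androgen", 30, loading = -0.42, latent_factor_id = "f"),
    module_spec("Complement", 30, loading = 0.42, latent_factor_id = "f",
                condition_loading = c(O50t = -0.42))),
  seed = 7)
sim <- generate_counts(cfg)
sim$truth$planted
#>     module_a   module_b condition        rho
#> 1 Senescence   Androgen        Nt -0.6104015
#> 2 Senescence Complement        Nt  0.6794697
#> 3   Androgen Complement        Nt -0.6127749
#> 4 Senescence   Androgen      O50t -0.6369659
#> 5 Senescence Complement      O50t -0.6349046
#> 6   Androgen Complement      O50t  0.6891600
```

The ledger holds the generator's own Monte-Carlo targets: senescence and
complement are planted at ρ ≈ +0.68 in Nt and ≈ −0.63 in O50t. Score and
screen in the Leydig cluster with the r ≥ 0.6 / r ≤ −0.45 cutoffs:

```r
qc <- run_qc(sim$matrix, qc_thresholds(min_features = 50, max_features = 1200))
sigs <- lapply(c("Senescence", "Androgen", "Complement"), function(m)
  signature_definition(m, subset(sim$truth$genes, module %in% m)$gene))
scores <- score_table(qc$matrix, sigs, sim$annotation)
correlation_screen(scores, "Senescence", cluster = "Lc", condition = "Nt",
                   config = screen_config(r_min_pos = 0.6, r_max_neg = -0.45))
#>    candidate      r        p n_cells
#> 1 Complement  0.628 3.33e-45     400
#> 2   Androgen -0.568 1.42e-35     400
```

Both planted non-null candidates are recovered at n = 400 (Androgen via
the negative bound; its r̂ −0.568 sits within sampling noise of the
planted −0.61). The cross-condition shift detector flags exactly the
planted flip:

```r
open_cfg <- screen_config()
correlation_shift(
  correlation_screen(scores, "Senescence", cluster = "Lc", condition = "Nt",   config = open_cfg),
  correlation_screen(scores, "Senescence", cluster = "Lc", condition = "O50t", config = open_cfg))
#>       target  candidate    r_a    r_b delta_r sign_flip
#> 1 Senescence Complement  0.628 -0.639 -1.2669      TRUE
#> 2 Senescence   Androgen -0.568 -0.652 -0.0843     FALSE
```

And Wilcoxon DE between conditions in Lc recovers the planted 1.5× shift
of the senescence module:

```r
norm <- normalize_counts(qc$matrix)
ann <- sim$annotation[sim$annotation$barcode %in% qc$matrix$cells, ]
de <- wilcoxon_de(norm, ann, cluster = "Lc",
                  condition_a = "O50t", condition_b = "Nt")
head(de[, c("gene", "log_fc", "p", "direction")], 3)
#>              gene log_fc        p direction
#> 1 Senescence.g002  0.460 1.22e-07        up
#> 2 Senescence.g014  0.398 5.81e-06        up
#> 3 Senescence.g021  0.383 1.76e-05        up
deg_counts(list(Lc = de))
#>   cluster n_up n_down
#> 1      Lc   23     4
```

23 of the 30 senescence-module genes (plus compositional echoes) come
out up in the inflamed condition; the direction, magnitude and which
genes are findable all follow from the planted truth.

The same flow is scriptable from the shell:

```sh
sigcorr simulate --config sim.json --seed 7 --out sim/
sigcorr qc --in sim/ --out qc/ --min-features 200 --max-features 7000 --max-pct-mt 20 --min-cells 3
sigcorr score --in qc/ --signatures sigs.gmt --annotation qc/annotation.tsv --out scores.tsv
sigcorr screen --scores scores.tsv --target Senescence_signature \
    --cluster Lc --condition O50t --r-min 0.32 --out screen.tsv
sigcorr run --config run.json   # whole pipeline + JSON manifest
```

## Documentation

The methods vignette
(`vignettes/signature-correlation-screening.Rmd`) describes the model
and its assumptions, the synthetic world and exactly which features of
real data it does and does not emulate, all tunable parameters with
their defaults and rationale, numerical/degenerate-input choices, and
known limitations (compositionality of percentage scores chief among
them).
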