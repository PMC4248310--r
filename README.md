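# pgex — population and single-cell analysis of promiscuous gene expression

Thymic epithelial cells (TEC) tolerize the developing T-cell repertoire by
*promiscuously* expressing thousands of genes that are otherwise restricted
to peripheral tissues, a program completed in mature medullary TEC by the
autoimmune regulator gene *Aire*. Measuring that program raises a chain of
unusual statistical problems that this package implements end to end, along
with a synthetic-data generator so every stage can be exercised against
known ground truth:

- **Is a gene expressed at all?** Per-gene local false discovery rates
  against an *empirical decoy null*: every gene model is shifted into
  intergenic space and re-quantified, and for gene *g* with FPKM *x*,

  `lfdr(x) = min(1, π0 · f0(x) / f(x))`

  where `f0` and `f` are kernel densities of log decoy and real FPKM, and
  the mixing proportion is estimated as `π0 = F_real(m0) / F_null(m0)` at
  the decoy median `m0`. A gene is detected when `lfdr < 0.05`.
- **Is it tissue-restricted?** Samples of a 64-array tissue atlas are
  clustered into 35 groups; a gene is a tissue-restricted antigen (TRA)
  when a large expression *step* (`value_k / value_(k+1) ≥ step gate`)
  separates its top 1–5 groups from the rest (the "dynamic step" rule),
  with a simple max-over-median threshold as the baseline.
- **Does it need Aire?** A minimal negative-binomial test (median-of-ratios
  size factors, moments dispersion shrunk to a trend, conditional
  two-sided test on condition sums, Benjamini–Hochberg FDR) feeds a
  four-way classification — *dependent* (induced and undetected in the
  Aire-KO), *enhanced*, *repressed*, *unchanged*.
- **What chromatin state marks its TSS?** ChIP/input enrichment in 1-kb
  TSS windows and TSS-anchored metagene profiles for H3K4me3/H3K27me3,
  Fisher's exact association between mark state and Aire regulation, and
  Mann-Whitney contrasts.
- **How is it transcribed in single cells?** ERCC-style spike-in curves
  (`log10 signal ~ log10 molecules`, per cell) calibrate absolute copy
  numbers; per-gene detection frequency and the population-normalised
  expression ratio among expressing cells quantify stochastic, bursty
  transcription; a permutation-calibrated structure score asks whether
  co-expression is clustered or random.

## Worked example

The `analysis/` directory is a numbered workflow over the package: stage 1
simulates a complete study (4000-gene annotation, three TEC populations
with two replicates each, an Aire-positive vs Aire-KO comparison whose
dependence is coupled to tissue restriction, a 64-array atlas, two histone
marks with input, and 174 single cells with spike-ins), and stages 2–6
analyse it.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_detection.R
...
Rscript analysis/06_single_cells.R
```

Stage 2 prints, per population:

```
mTEC_aire_pos: pi0 = 0.50, 1872 genes detected at lfdr < 5% (FPKM floor 1.97, realized FDP 0.0000)
population clustering: 3 significant clusters (support > 0.95)
```

so the decoy-based mixing proportion recovers the simulated 50% unexpressed
fraction, detection at a 5% local FDR keeps essentially no false genes, and
bootstrap clustering separates the three simulated populations with full
support. Stage 3 compares TRA classifiers on the planted truth:

```
dynamic step:     sens 0.942  spec 0.960  Youden 0.903
simple threshold: sens 0.512  spec 1.000  Youden 0.512
```

Stage 4 recovers 95% of planted Aire-regulated genes with their true class,
finds no bias in a 474-gene housekeeping control (median |log2FC| 0.08), and
correlates restriction specificity with the fraction of genes requiring
Aire for detection (r = 0.39 over 25 breadth sets). Stage 6 reports the
single-cell regime:

```
dependent  median frequency   1.1%   median ratio when detected  20.3-fold
enhanced   median frequency   2.6%   median ratio when detected  11.2-fold
tra        median frequency   9.2%   median ratio when detected   6.3-fold
other      median frequency  33.3%   median ratio when detected   3.8-fold
co-expression structure over 407 genes x 173 cells: z = 2.52 (no structure beyond chance)
```

i.e. fully Aire-dependent genes are transcribed in ~1% of cells but, when
present, far above their population level — and their co-expression shows
no structure beyond chance, the signature of stochastic target selection.

Outputs land under `results/` as TSV/JSON/Newick.

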