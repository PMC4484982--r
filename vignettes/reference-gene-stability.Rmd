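---
title: "Reference-gene stability selection: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability selection: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

# The problem

qRT-PCR quantifies a target transcript relative to one or more reference
genes assumed to be constant across samples. That assumption fails often —
classical housekeeping genes (actins, tubulins, GAPDH, rRNA) can respond
strongly to stress treatments — and a drifting reference propagates
multiplicatively into every fold change computed against it. `refstab`
implements the accepted remedy: screen candidates from transcriptome-scale
expression data, then rank their measured Ct stability with three algorithms
that make *different* assumptions, and only trust genes the methods agree on.

# Data model

The workflow consumes two inputs.

**Expression matrix** (genes × conditions, FPKM role, non-negative): used only
for screening. At least two conditions are required, since a standard
deviation over one value is undefined.

**Ct table** (long format): one row per technical well, keyed by
(sample, gene, biological replicate, technical replicate), with the sample's
experimental group attached. Aggregation to one mean Ct per (gene, sample) is
*two-stage* by default — technical replicates averaged within each biological
replicate, then biological means averaged — because the usual "mean of three
biological and three technical replicates" phrasing does not fix an order and
the two-stage mean weights biological replicates equally even when technical
counts are unbalanced. For balanced designs it equals the pooled mean
(`method = "pooled"`), which is also offered. Every (gene, sample) cell must
be present: geNorm and NormFinder operate on complete matrices, and a missing
cell is a hard error rather than a silent imputation. BestKeeper alone
tolerates per-gene missing samples (with a warning), since its statistics are
defined per gene. Ct values are validated as finite and positive; values
outside (5, 40) cycles warn but pass, since instruments differ.

Relative quantities are `q[g, s] = E_g^-(Ct[g,s] - min_s' Ct[g,s'])` with
per-gene efficiency E defaulting to 2 (the `2^-ΔCt` convention). Anchoring at
the per-gene minimum bounds q in (0, 1] and removes each gene's absolute
abundance — a 44-fold abundance gap between an rRNA and a metallothionein must
not influence any stability ranking, and tests assert this invariance
explicitly. Efficiencies are consumed as inputs (e.g. from standard-curve or
amplification-curve software); values must lie in (1, 2.2] and warn outside
the usual assay range [1.8, 2.1].

# The three stability measures

**geNorm.** The pairwise variation of genes j and k is the sample SD (n−1) of
`log2(q_j / q_k)`; M_j is the mean over all partners. Stepwise exclusion drops
the highest-M gene (ties: the lexicographically last gene id, a deterministic
rule recorded in the output) and recomputes, down to a final pair whose
2-gene M values are necessarily equal — the pair is reported tied with mean
rank 1.5 each. M < 1.5 is flagged "stable", the customary interpretive
threshold. The pairwise-variation series compares geometric-mean normalization
factors of the n and n+1 best-ranked genes, `V_n = SD(log2(NF_n / NF_(n+1)))`;
the smallest n with V_n below 0.15 is reported as the optimal reference count.
The 0.15 cut-off is conventional, not absolute, and `optimal_n` is NA when no
V clears it — the practical reading then is that the experiment, not the
threshold, should decide.

**NormFinder.** A variance-decomposition model on log2 quantities. Each
sample's column is centered by its mean over genes (absorbing sample-wide
loading/RT effects), which is why at least 3 genes are required. Per gene i
and group g with n_g ≥ 2 samples, the raw within-group variance s²_ig of
centered values mixes the gene's own noise with everyone's through the
centering; the corrected estimate is
`σ²_ig = max(0, (s²_ig − Σ_k s²_kg / (I(I−1))) · I/(I−2))`, the
method-of-moments solution with negative values floored at zero. The
intergroup deviation `d_ig` (group mean of centered values minus the gene's
grand mean; sums to zero over groups) is shrunk toward zero by its sampling
variance `v_ig = σ²_ig / n_g` through the empirical-Bayes factor
`γ² / (γ² + v_ig)`, where `γ² = max(0, Σ d² / ((I−1)(G−1)) − mean(v))` is the
between-group variance of the d's. The stability value is the mean over groups
of `|d̃_ig| + sqrt(v_ig · γ²/(γ² + v_ig))`; lower is more stable. Two
boundary behaviours are worth knowing: with a single group the model
degenerates and stability falls back to `sqrt(σ²)` (documented as a
deviation from the grouped model), and when γ² estimates to exactly zero —
no detectable systematic group differences anywhere — all grouped stabilities
collapse to 0 and the ranking ties; on real treatment data γ² is essentially
never zero.

Group definitions are deliberately configuration, not inference: in a
multi-treatment analysis the treatments are the natural groups; within a
single-treatment subset the time points (or control vs. treatment) are. The
orchestrator pairs each treatment's samples with the control samples so a
two-group structure survives subsetting; if no control group exists the
single-group fallback applies.

**BestKeeper.** Works on raw Ct, not quantities. Its "SD" is the mean
absolute deviation from the arithmetic mean Ct (cycles), and its "CV" is
100·SD/mean Ct — a percent-of-cycles measure, deliberately distinct from the
dimensionless screening CV, and the two are never compared. MAD around the
*arithmetic* mean is used because it exactly reproduces the published
consistency anchor relating a gene's SD, mean Ct and percent CV
(100 × 0.68 / 23.37 = 2.91), whereas the geometric-mean variant does not
round to the printed value pattern so cleanly; MAD ≤ classical SD always
(tested as a property). Ranking is ascending by (SD, CV, gene id) — a total,
deterministic key. SD > 1 cycle flags a gene unacceptable but does not drop
it from the table. The optional BestKeeper index (per-sample geometric mean
Ct of chosen genes, with per-gene Pearson correlations against it) is
provided; the regression block of the original program is not, as the
ranking here never uses it.

# Screening and consensus

The screening CV uses the sample SD (n−1 denominator): recomputing the
bundled published 12-gene table reproduces all printed CV values to ±0.001
under that convention, while the population SD does not (e.g. the rRNA row
gives 0.046 instead of the printed 0.054). One row (ACT101, recomputed
0.0897, printed 0.089) sits at the rounding boundary; the package documents
round-half-up and does not force agreement beyond the ±0.001 band. The filter
is strict (`cv < cv_max`), with `cv_max = 0.3` as the customary default.
Zero-mean genes are flagged rather than fatal.

The consensus score is the geometric mean of the per-method ranks (the
RefFinder-style convention), with arithmetic mean as an option; geNorm's tied
pair enters as rank 1.5 each and final consensus ranks are a tie-broken
permutation of 1..K. No published aggregation rule is uniquely recoverable
for this kind of comprehensive ranking, so the package documents its own rule
instead of guessing; the comprehensive orders printed in the motivating
literature are not a validation surface for it.

Validation wires the top `n_refs` consensus genes (default 3 — the
conventional minimum recommendation for reliable normalization) into
`2^-ΔΔCt` fold changes: per sample ΔCt = Ct(target) − mean Ct(references),
averaged per group; ΔΔCt = treated − control; fold = 2^−ΔΔCt. Averaging
reference Ct values is algebraically identical to dividing by the
geometric-mean normalization factor on the quantity scale (a cross-module
test asserts the equality), which is why the multi-reference combination rule
is stated this way. Fold-change uncertainty (error bars) is out of scope
here; only replicate-level SEs would be defensible and they depend on
instrument export details.

# The simulator

`simulate_ct()` draws
`Ct = baseline + group_effect + B + ε`, `B ~ N(0, σ²_bio)` shared by a
biological replicate's wells, `ε ~ N(0, σ²_tech)` per well — additive
Gaussian noise on the cycle scale, the standard qPCR error model and the
scale all three methods operate on. One root seed drives per-gene substreams
derived from a deterministic hash of the gene id, so adding or removing a
gene never perturbs another gene's draws (tested).

`stress_preset()` mirrors a typical abiotic-stress study: control plus
drought/cold/salt over a 0/3/6/12 h time course with all time-zero samples
grouped as control (untreated at onset), giving 13 samples with group sizes
4/3/3/3, and 3 biological × 3 technical replicates (1404 records). Twelve
genes span baselines of 16–30 cycles, matching the dynamic range qPCR panels
typically cover. Three genes are ideal references (no group effects,
σ_bio = 0.08, σ_tech = 0.06 — total ≈ 0.1 cycles, an optimistic but
attainable assay precision); nine carry fixed treatment effects with
magnitudes 0.5–2.5 cycles in nine *distinct* direction patterns. Distinctness
matters: two responsive genes with proportional effect patterns would be
co-regulated, hold a constant expression ratio, and legitimately fool geNorm
— a known limitation of ratio-based measures that the preset avoids on
purpose and real users should remember.

What the simulator does *not* emulate: amplification-efficiency differences
between genes (effects are on the Ct scale directly), heteroscedastic noise
at high Ct (stochastic template limits), plate/batch effects, missing wells,
and co-regulated gene modules. Passing the recovery tests therefore shows the
algorithms separate stable from responsive genes under clean Gaussian
conditions; it does not certify performance against co-regulation or batch
structure in real data.

`simulate_expression()` draws log-normal rows solving for a requested mean
and CV exactly (`sdlog² = log(1+cv²)`), for exercising the screening stage.

# Numerical and testing choices

* SD convention is n−1 everywhere (screening, geNorm, NormFinder); for geNorm
  the n vs n−1 choice scales all M and V values by a common factor and cannot
  change a ranking, so consistency was the deciding criterion.
* Ties are always broken deterministically (lexicographic gene id), so
  repeated runs on identical input produce byte-identical reports (tested).
* Reports render floats at 3 decimals, the precision such tables are
  conventionally printed at.
* The test suite checks each statistic against independent brute-force
  implementations (explicit loops over the defining equations) to 1e−10 on
  100 random 6-gene × 8-sample instances, and measures parameter recovery on
  100 simulated datasets of the preset design (12 × 13 × 9 records each) —
  sizes chosen so the full suite runs in seconds while estimating the
  recovery rate to a few percent.
* Known limitations: no handling of missing wells beyond BestKeeper; no
  efficiency estimation (efficiencies are inputs); no uncertainty on fold
  changes; the NormFinder best-pair feature of the original program is not
  implemented.
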