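# refstab

Selecting reference (housekeeping) genes for qRT-PCR normalization. Relative
quantification divides a target gene's signal by that of one or more reference
genes, so an unstable reference silently biases every downstream fold change —
in the worst case turning a ~3-fold induction into a reported several-hundred-fold
one. `refstab` implements the standard workflow for choosing references
defensibly, for anyone running qRT-PCR expression studies (plant stress
biology, clinical samples, any multi-condition design):

1. **Candidate screening** — per-gene mean (MV), sample SD and coefficient of
   variation CV = SD/MV across conditions of an expression matrix (FPKM or
   similar); candidates pass a strict CV < 0.3 screen.
2. **Ct processing** — long-format replicate-level Ct tables are validated and
   collapsed by a two-stage mean (technical within biological replicates, then
   biological), and converted to relative quantities `q = E^-ΔCt` anchored at
   each gene's minimum Ct (exactly `2^-ΔCt` for efficiency E = 2).
3. **Three independent stability rankings**
   - *geNorm*: a gene's M value is the mean over partners k of
     SD<sub>samples</sub>(log₂ q<sub>j</sub>/q<sub>k</sub>); stepwise exclusion of the
     highest-M gene leaves a tied most-stable pair, and the pairwise variation
     V(n/n+1) = SD(log₂ NF<sub>n</sub>/NF<sub>n+1</sub>) between geometric-mean
     normalization factors decides how many references are needed (V < 0.15).
   - *NormFinder*: a variance-decomposition model on sample-centered log
     quantities estimating each gene's intragroup variance and its shrunken
     intergroup deviation; stability = mean over groups of |deviation| + SE.
   - *BestKeeper*: descriptive dispersion of raw Ct — "SD" is the mean absolute
     deviation from the mean Ct in cycles, "CV" that deviation as a percent of
     mean Ct; SD > 1 cycle flags a gene unacceptable.
4. **Consensus** — per-method ranks combined by geometric mean (arithmetic
   optional), and the chosen reference set validated by `2^-ΔΔCt` fold changes
   of target genes.
5. **Simulator** — a seeded generator of replicate-level Ct tables
   (baseline + group effect + Gaussian biological/technical noise on the cycle
   scale) mirroring a control + drought/cold/salt time-course design, so the
   whole workflow is testable offline.

## Worked example

Screen the bundled 12-candidate expression table (four abiotic-stress
conditions) and analyse a simulated Ct experiment:

```r
library(refstab)

fpkm <- read_expression_matrix(refstab_example("candidate_fpkm.tsv"))
head(expression_stats(fpkm), 4)
#>     gene    mv    sd     cv cv_defined
#> 1    18S 653.8 35.05 0.0536       TRUE
#> 2 ACT101 351.1 31.48 0.0897       TRUE
#> 3   ACTB  25.1  4.73 0.1884       TRUE
#> 4   ACT7 449.7 61.75 0.1373       TRUE

rec    <- simulate_ct(stress_preset(seed = 42))   # 12 genes x 13 samples x 3x3 reps
report <- run_full_analysis(rec, targets = "RSP9")
report$subsets$all$genorm
#> geNorm stepwise ranking (most stable first):
#>  gene          m rank stable
#>  REF1 0.05441956  1.5   TRUE
#>  REF3 0.05441956  1.5   TRUE
#>  REF2 0.07421290  3.0   TRUE
#>  RSP1 0.35691555  4.0   TRUE
#>  ...
#> final (tied) pair: REF1/REF3
report$subsets$all$v_series$optimal_n
#> [1] 2
```

The three genes simulated with no treatment response (`REF1`–`REF3`) come out
on top; M values under 1.5 are flagged stable; V2/3 below 0.15 says two
references suffice for this (clean) simulated data. The `report` also carries
NormFinder and BestKeeper tables, the consensus ranking per treatment subset,
and `2^-ΔΔCt` fold changes of the requested target against the top consensus
references. `write_report_bundle(report, "out/")` emits one TSV per table plus
a JSON manifest.

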