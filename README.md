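# trajdeg

Trajectory classification and transcriptional coordination of
differentially expressed genes across a stimulus–deprivation design.

## The problem

In a chronic social-conflict paradigm, male mice that win daily agonistic
confrontations for 20 days (A20) develop a psychosis-like, addiction-like
behavioral state; after a further two weeks *without* confrontations
("fighting deprivation", AD) their aggressiveness increases rather than
normalizes. The analysis question for nucleus-accumbens transcriptomes
from the three groups — control (C), A20, AD, six animals each — is which
neurotransmitter genes **stay** altered after the stimulus is removed.
Those persistent genes, not the ones that respond acutely and then
normalize, are the candidates for the lasting pathology and the
aggression relapse.

`trajdeg` implements that paradigm as a tested pipeline for anyone with a
genes × samples expression table (FPKM-like units) and a three-group
design:

1. **Differential expression** for the ordered comparisons c1 = C vs A20,
   c2 = C vs AD, c3 = A20 vs AD: Welch's *t* (or exact Mann–Whitney) on
   log2(x+1), Benjamini–Hochberg FDR per comparison, directional calls at
   `p < 0.05` and `q < 0.05`.
2. **Trajectory classification**: each call triplet maps to one of six
   archetypes — `unchanged`, `transient`, `persistent_same_sign`,
   `persistent_reversed`, `deprivation_emergent`, `deprivation_shifted` —
   and a persistence ("pathology") flag: the gene still differs at AD
   from C and/or from A20. Per-system summaries use five bundled
   neurotransmitter gene panels (catecholaminergic, opioidergic/
   cannabinoidergic, serotonergic, GABAergic, glutamatergic).
3. **Coordination**: per group, the number of significantly correlated
   gene pairs (Pearson r, t-transform with df = n − 2, |r| > 0.811 at
   n = 6) among the flagged genes — a measure of condition-specific
   co-regulation.

A synthetic-data module (`simulation_spec()` / `generate_dataset()`)
plants known trajectory classes and per-group co-expression clusters with
truth labels, so the whole pipeline is validated end to end without
external data. Because the motivating study's raw expression is not
publicly deposited, the package also bundles its per-gene comparison
calls transcribed from the published per-system statements
(`nacc_call_fixture()`, 54 genes) and its printed 8-gene post-deprivation
correlation matrix as plain-text fixtures.

## Worked example

Classify the bundled call fixture and summarize it per system:

```r
library(trajdeg)
calls  <- nacc_call_fixture()
panels <- load_default_panels()
s <- summarize_panels(calls, panels)
panel_summary_table(s)[, 1:5]
```

```
                                                   system n_members n_tested n_deg n_pathology
catecholaminergic                       catecholaminergic        29       14    14           9
opioidergic_cannabinoidergic opioidergic_cannabinoidergic        13        6     6           3
serotonergic                                 serotonergic        20        8     8           7
GABAergic                                       GABAergic        23        6     6           1
glutamatergic                               glutamatergic        32       23    23           8
```

Reading the table: 14 of the 29 catecholaminergic panel genes carry at
least one significant comparison call, of which 4 were upregulated and 6
downregulated under the stimulus (c1); of the 23-gene GABAergic panel
only 6 respond at all and every one except `Gabra5` is `transient` —
that system tracks the stimulus but not the relapse. The default
persistence rule flags 8 glutamatergic genes
(`Gad1, Grid1, Grik4, Grik5, Grin3a, Grm2, Grm5, Grm7`) and 3 opioidergic
genes (`Oprk1, Pdyn, Penk`); the strict control-vs-deprived variant
recovers the six-gene catecholaminergic list
(`Adra2c, Drd1, Drd2, Maoa, Ppp1r1b, Th`):

```r
summarize_panel(calls, panels$catecholaminergic, "cvsad_only")$pathology_set
#> [1] "Adra2c"  "Drd1"    "Drd2"    "Maoa"    "Ppp1r1b" "Th"
```

Individual trajectories follow the same logic, e.g. tyrosine hydroxylase
— up under the stimulus, then significantly *below* both baselines after
deprivation:

```r
classify_gene("up", "down", "down")
#> [1] "persistent_reversed"
```

On the coordination side, the bundled published correlation matrix of 8
catecholaminergic/opioidergic genes in deprived animals (all off-diagonal
r ≥ 0.851, n = 6) is fully coordinated:

```r
r <- as.matrix(read.table(system.file("extdata", "ad_coordination_matrix.tsv",
                                      package = "trajdeg"),
                          header = TRUE, sep = "\t", row.names = 1))
s <- significant_pairs(coordination_from_matrix(r, n = 6), sign_filter = "positive")
s$total_count        # 28  (every unordered pair)
#> [1] 28
```

The `analysis/` directory holds the numbered workflow scripts
(`01_simulate.R` … `05_report.R`) that run the same machinery over a
simulated 500-gene dataset — planted-class recovery of ~93%, an
A20-specific cluster showing 24 significant pairs in A20 against 4–5 in
C/AD — and write all tables under `results/`.

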