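# archexpr

Classification of Edn1- and Notch-regulated gene sets from RPKM
transcriptomes of FACS-purified zebrafish pharyngeal-arch neural crest
cells (NCCs), with the downstream temporal and penetrance statistics and a
synthetic-data generator that makes every stage testable by planted-label
recovery.

## The problem

Jagged–Notch and Endothelin1 (Edn1) signaling antagonistically pattern the
zebrafish facial skeleton: Edn1 promotes and Notch restricts early
cartilage differentiation in the pharyngeal arches. A replicate-free bulk
RNA-seq design — wild-type arch NCCs at 20/28/36 hpf plus five
perturbation arms at 36 hpf (pathway mutants, heat-shock overexpression,
and the γ-secretase inhibitor DBZ) — lets pathway-regulated gene sets be
derived from deterministic threshold rules on expression ratios. This
package implements those rules exactly, plus the statistics applied to the
resulting lists, for anyone who wants to re-derive, audit or stress-test
this style of analysis.

## The method

With RPKM values `x`, zero cells replaced by 0.01 before any division:

1. **Arch enrichment.** Keep genes with `x > 3` in the wild-type 36 hpf
   double-positive sample, then require `DP/GFPonly ≥ 1.5` and
   `DP/DsRedonly ≥ 1.5` per stage. The 36 hpf set is the "total" arch
   universe.
2. **Classification.** Per pathway, with `r = fc_OE / fc_mut` (each
   fold-change against its own control):
   activated when `r ≥ 1.5` and `fc_OE ≥ 1`;
   inhibited when `r ≤ 0.667` and `fc_mut ≥ 1`.
   Notch uses NICD-overexpression and *jag1b*-mutant contrasts; Edn1 uses
   Edn1-overexpression and *edn1*-mutant contrasts.
3. **DBZ refinement.** Notch-activated genes must have
   `fc_NICD / fc_DBZ ≥ 1.25`, Notch-inhibited `≤ 0.8`.
4. **Statistics.** Temporal fold-change distributions per list
   (median/quartiles/5th–95th percentiles, counts > 10-fold), compared by
   Kruskal–Wallis then pairwise Mann–Whitney vs the total list with
   Bonferroni correction at α = 0.05 (exact enumeration under ties up to a
   combined n of 20); genotype × phenotype penetrance by Pearson
   chi-square (no continuity correction) or Fisher's exact test.

All comparisons are inclusive, all thresholds configurable
(`enrichment_thresholds()`, `classifier_thresholds()`).

## Worked example

The package ships a 20-gene noise-free fixture whose values sit exactly on
every decision boundary (also available as TSVs under `inst/extdata/`):

```r
library(archexpr)
wx <- plant_worked_example()
res <- classify_genes(wx$matrix, wx$design)
length(res$universe)      # arch-enriched genes at 36 hpf
res$notch; res$edn1       # classified lists
res$dbz_removed           # refinement audit
```

prints (names describe the planted behaviour):

```
arch-enriched at 36 hpf: 16 of 20 genes
notch activated: notch_act_1, boundary_act, boundary_dbz_up, co_pos_1
notch inhibited: notch_inh_1, boundary_inh, boundary_dbz, co_neg_1, antag_induced
edn1 activated:  edn1_act_1, co_pos_1, antag_induced
edn1 inhibited:  edn1_inh_1, co_neg_1
removed by DBZ:  dbz_removed_act, dbz_removed_inh
```

`boundary_rpkm` (RPKM exactly 3) is excluded by the floor, `boundary_enrich`
(enrichment ratio exactly 1.5) is retained, `boundary_act` / `boundary_inh`
sit exactly on the 1.5 / 0.667 classification boundaries, and
`boundary_dbz_up` / `boundary_dbz` on the 1.25 / 0.8 refinement boundaries
— every inclusive rule keeps its boundary gene. The temporal table shows
the planted 12× induction of `antag_induced` between 20 and 28 hpf and the
zero-replacement rule giving `zero_at_20` a 28/20 ratio of 5000
(= 50/0.01).

A full synthetic analysis (5,000 genes, 18 samples) runs through the
numbered drivers:

```sh
Rscript analysis/01_simulate.R      # dataset + planted truth -> results/data/
Rscript analysis/02_enrichment.R    # per-stage arch gene lists
Rscript analysis/03_classification.R# lists, Venn, top-20, recovery scores
Rscript analysis/04_temporal.R      # list-vs-total induction statistics
Rscript analysis/05_penetrance.R    # phenotype contingency tests
```

With the default noise level (`noise_sd = 0.2`) the Notch-inhibited list is
flagged as significantly more induced from 20 to 28 hpf than the total
arch list (Bonferroni-adjusted Mann–Whitney p far below 0.05), reproducing
the qualitative temporal structure of the design; the recovery table in
`results/classification/recovery.tsv` quantifies how threshold
classification degrades with noise (see the vignette for why).

## Package layout

- `R/` — implementation: IO and RPKM (`io.R`), generator (`simulate.R`),
  enrichment filter (`enrichment.R`), classifier (`classify.R`),
  statistics (`stats.R`), recovery scoring (`evaluate.R`), orchestration
  (`pipeline.R`).
- `analysis/` — numbered narrative drivers over the package.
- `vignettes/arch-gene-classification.Rmd` — the methods vignette: model,
  thresholds, generator calibration, numerical choices, limitations.
- `tests/testthat/` — unit, property and acceptance tests.
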