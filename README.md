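# cloniche

Quantitative tools for studying how T cell tolerance is organized in
early-life tissue, built around two kinds of evidence: the **clonal
architecture** of the CD4 T cell repertoire (from single-cell VDJ
sequencing) and the **spatial micro-anatomy** of dendritic cell (DC) / T
cell contacts (from in-situ transcriptomics or multiplex imaging cell
tables). The package is aimed at immunologists analyzing per-mouse
clonotype tables and per-cell tissue maps of neonatal versus adult liver,
but nothing in it is liver-specific.

## What it computes

**Repertoire module.** For each subject the package computes, from a
per-cell clonotype table:

- the **R20 score** — with clones ranked by descending size, the fraction
  of unique clones needed to account for 20 % of all sequenced cells:
  `R20 = k/C`, where `C` is the clone count and `k` the smallest number of
  top clones whose cumulative cell count reaches `0.2·N` (inclusive). A
  fully polyclonal repertoire scores ≈ 0.2; oligoclonal expansion drives
  the score toward `1/C`.
- the **expanded-clone fraction** — clones with more than one cell, over
  all clones;
- the **sharing classification** — a clone containing both Foxp3⁺ (Treg)
  and Foxp3⁻ (Tconv) cells is `SHARED`, evidence compatible with
  peripheral Treg induction from a shared precursor;
- depth-normalized versions of these via seeded subsampling without
  replacement (`subsample_statistic()`).

**Spatial module.** From a typed cell table (µm coordinates), the package
detects **DC–T microniches** with deterministic DBSCAN (core point:
≥ `min_samples` cells within `eps`, counting itself; clusters: connected
core components plus border points, with border ties resolved by nearest
core point), retains clusters with ≥ 1 DC and ≥ 3 T cells, and computes
whole-slide statistics: mean nearest-DC distance over T cells, niche
density per mm², and the fraction of niches that are **parenchymal**
(no vessel feature within 50 µm of the niche centroid).

**DE module.** Cells of one type inside niches are contrasted against the
same type outside: library-size normalization to a common total with
`log1p`, a two-sided Wilcoxon rank-sum test per gene (normal approximation
with tie and continuity corrections), Benjamini–Hochberg adjustment across
tested genes, and a `log2` fold change of normalized group means.

**Simulation module.** Seeded generators produce repertoires (tunable
clone-size law, Treg probability, forced cross-lineage sharing) and tissue
sections (planted DC–T clumps over Poisson background fields, point
vessels, Poisson gene counts with niche-conditional fold changes) with
full ground truth, so every stage is testable without any external data.

## Worked example

```r
library(cloniche)

## a PND7-like repertoire: strong expansion, frequent Treg/Tconv sharing
prm <- repertoire_sim_params(n_cells = 800,
                             clone_size_law = list(law = "GEOMETRIC", p = 0.6),
                             p_treg = 0.35, sharing_rate = 0.35)
sim <- simulate_repertoire(prm, seed = 7, subject_id = "pup1",
                           timepoint = "PND7")
summarize_subject(sim$repertoire, "pup1")
#>  subject_id timepoint n_cells n_clones       r20 monoclonal expanded_fraction
#>        pup1      PND7     800      470 0.0787234      FALSE         0.4148936
#>  expanded_frac_treg_only expanded_frac_tconv_only expanded_frac_shared
#>                0.2307692                      0.4            0.3692308
#>  shared_clone_count
#>                  72
```

Only 7.9 % of clones account for a fifth of the repertoire (compare
≈ 17 % for an adult-like, almost fully polyclonal subject), 41 % of
clones are expanded, and 72 clones contain both lineages.

```r
## a neonatal-like tissue: 8 planted DC-T niches, niche-biased expression
tis <- simulate_tissue(tissue_sim_params(n_niches = 8,
                         niche_composition = c(dc = 8, t = 16),
                         n_genes = 30, gene_names = cloniche:::fixture_gene_panel(),
                         niche_effects = cloniche:::fixture_niche_effects()),
                       seed = 7)
niches <- detect_microclusters(tis$cells)
slide_stats(tis$cells, niches, tis$vessels)
#>  mean_nearest_dc_distance n_niches tissue_area_mm2 foci_density_per_mm2
#>                    69.819        8         3.94594               2.0274
#>  parenchymal_fraction
#>                     1

mem <- assign_niche_membership(tis$cells, niches)
head(as.data.frame(de_inside_outside(tis$cells, tis$counts, mem, "DC")), 5)
#>      gene n_inside n_outside log2_fold_change      p_value      q_value
#>      Cd80       67       120        0.8024358 8.277648e-21 2.483294e-19
#>  Pdcd1lg2       67       120        0.6625578 5.222008e-18 7.833012e-17
#>      Ccr7       67       120        0.6906804 9.643816e-14 9.643816e-13
#>     Cd274       67       120        0.7068638 2.547640e-13 1.910730e-12
#>    gene17       67       120       -0.3698409 4.918627e-04 2.107983e-03
```

All eight planted niches are recovered, all are parenchymal (no vessel
within 50 µm), and the four genes given a 4-fold inside-niche effect on
DCs top the inside/outside contrast with positive fold changes at
q ≪ 0.05.

A command-line entry point wrapping the same functions is available:

```sh
Rscript inst/scripts/cloniche.R simulate fixtures --out-dir fx --seed 3
Rscript inst/scripts/cloniche.R repertoire summarize --input fx/rep_pnd7.tsv --out summary.tsv
Rscript inst/scripts/cloniche.R niche detect --cells fx/cells_neonatal.csv \
    --vessels fx/vessels_neonatal.json --out-dir niches
```

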