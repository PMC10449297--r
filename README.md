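# plasmatrace

Single-cell transcriptome analysis of multiple-myeloma tumour
heterogeneity and a cell-level model of extramedullary metastasis.

## The problem

Multiple myeloma (MM) is a plasma-cell malignancy of the bone marrow. In
some patients, tumour plasma cells escape the marrow and seed
extramedullary lesions; the clonal circulating plasma cells (CPCs) found
in peripheral blood are the travelling compartment of that process.
Smart-seq2 single-cell RNA sequencing of matched bone-marrow myeloma
cells (BMMCs) and CPCs makes it possible to ask *which marrow subclone
the circulating cells come from*. The tumour suppressor FAM46C — a
non-canonical poly(A) polymerase that stabilises mRNA — marks the axis of
heterogeneity: FAM46C-low subclones show a globally depressed
transcriptome and contribute disproportionately to the circulating
compartment.

`plasmatrace` implements that analysis as a reusable, tested pipeline
over gene-by-cell FPKM matrices:

1. **QC** — keep cells with > 1e5 mapped reads and > 1e3 detected genes
   (strict inequalities); keep transcripts with FPKM > 1 in at least one
   cell.
2. **Immunoglobulin specificity** — one-way ANOVA of each IGH/IGK/IGL
   gene across patients; genes with *P* < 1e-6 are patient-specific
   clonal markers (F = (SSB/(k−1))/(SSW/(N−k))).
3. **Differential expression** — per-patient two-sided unpaired t tests
   of CPC vs BMMC with log2 FC = log2((mean_A+1)/(mean_B+1)); a gene is
   called only when *P* < 0.05 **and** |log2 FC| > 1 in *every* required
   patient (the conjunctive rule).
4. **Subclone clustering** — Ward hierarchical clustering of BMMCs on
   z-scored log2(FPKM+1) over the DEG ∪ immunoglobulin feature space; the
   cluster number k ∈ 1..10 maximises the average silhouette width
   s(i) = (b(i)−a(i))/max(a(i),b(i)); the cluster with the highest mean
   FAM46C is the *high* group, all others merge into the *low* group.
5. **Metastasis model** — every CPC is assigned the BMMC with the
   largest Pearson correlation of log2(FPKM+1) profiles (its "possible
   contributor"); per-BMMC metastasis rate **M_j = C_j / C_p**, where
   C_j counts the CPCs assigned to BMMC j and C_p is the number of CPCs
   analysed; per-group contribution fractions and a Sankey export
   summarise the flow.

Because the original patient-level data are not deposited, the package
ships a **synthetic-data generator** (`simulate_patient()`,
`scenario_p17()`, `scenario_p20()`) that plants exactly the structure the
pipeline is designed to detect — patient-specific immunoglobulin genes,
FAM46C-low subclusters with a 0.7× whole-transcriptome depression, and
CPCs copied from designated source cells with noise and dropout — so
every stage is testable against known ground truth.

## Worked example

```r
library(plasmatrace)

sim <- simulate_patient(scenario_p17(seed = 1, noise_sd = 0.2,
                                     dropout_rate = 0.05))
res <- run_pipeline(sim$matrix)
#> QC: kept 76/76 cells, 1938/2000 transcripts
#> Specificity: skipped (single patient)
#> DEG: 38 genes pass the conjunctive rule over P17
#> P17: k = 3 clusters, high-FAM46C cluster 2
#> P17: C_p = 30, low-group contribution 83.3%

res$per_patient$P17$metastasis$contributions
#> # A tibble: 2 x 4
#>   group n_cpc fraction percent
#>   <chr> <int>    <dbl>   <dbl>
#> 1 low      25    0.833    83.3
#> 2 high      5    0.167    16.7
```

The three BMMC subclusters are recovered by silhouette selection (k = 3),
cluster 2 is labelled FAM46C-high, and 25 of the 30 circulating cells
trace back to the two FAM46C-low subclusters — the planted 83.3% / 16.7%
contribution split. `glance()`/`tidy()` summarise the fitted objects,
`autoplot()` and `plot_silhouette()` draw the embedding, the silhouette
profile and the contribution bars, and `write_results(res, dir)` writes
TSV/JSON artefacts with a manifest.

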