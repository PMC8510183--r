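# storagefx

Quantifying how biospecimen **storage conditions** — temperature, storage
time, and repeated freeze-thaw cycles — distort the microbiome composition
and antimicrobial resistome inferred from shotgun metagenomics.

When fecal or sewage samples sit in a refrigerator over a weekend, or are
frozen and thawed repeatedly before DNA isolation, the community that gets
sequenced is no longer the community that was collected: taxa with rigid
cell walls (*Firmicutes*, *Actinobacteria*, microbial eukaryotes) tend to
gain apparent abundance under warm storage and freeze-thaw stress, while
easily-lysed Gram-negative groups (*Bacteroidetes*, *Proteobacteria*) lose
it. `storagefx` packages the complete statistical workflow for measuring
such effects from genus-level and AMR-gene count tables, together with a
synthetic data generator that plants these effects with known ground truth
so that every stage of the pipeline can be validated end to end.

The package is aimed at bioinformaticians running storage/batch-effect
studies and at method developers who need a controlled testbed for
compositional batch effects.

## What it computes

* **Preprocessing** — read-pair halving, genome-size normalization
  (counts / genome Mbp), total sum scaling, genus/class aggregation.
* **Alpha diversity** — bias-corrected Chao1
  `S_obs + F1(F1-1)/(2(F2+1))`, Shannon/Pielou `J = H / ln S_obs`,
  Simpson `1 - Σ p_i²`, and seeded rarefaction curves (multivariate
  hypergeometric subsampling).
* **Beta diversity** — Hellinger transform `sqrt(count / sample total)`,
  Bray-Curtis dissimilarities `Σ|x_i − y_i| / Σ(x_i + y_i)`, PCoA with
  stress diagnostics, complete-linkage clustering supports for heat maps.
* **Permutational statistics** — one-way PERMANOVA
  (`F = (SS_B/(a−1)) / (SS_W/(N−a))` on squared dissimilarities, label
  permutation, add-one p), multivariate dispersion homogeneity
  (distances to group centroids in the PCoA embedding, permutation F
  test), Kruskal-Wallis with tie correction and Holm-adjusted Dunn post
  hoc tests, Levene's test via `car`.
* **Stored-vs-baseline summary** — mean ± SE Bray-Curtis dissimilarity of
  each storage condition's replicates to the matrix's 0 h replicates,
  with the 0 h row holding the replicate noise floor.
* **Constrained ordination** — correspondence analysis of the raw count
  table (chi-square residuals `Q = (P − rc')/sqrt(rc')`) constrained by
  the storage-condition factor, reporting the constrained inertia
  fraction, site/feature scores and condition centroids.
* **Differential abundance** — per-taxon negative-binomial Wald tests with
  custom size factors `s_j = total_j / mean(totals)`, method-of-moments
  dispersion moderated against a mean-dispersion trend, model
  `μ_ij = s_j · q_i · 2^(β_i x_j)`.
* **Resistome** — FPKM
  `fragments / (gene kb) / (bacterial fragments / 10⁶)`, AMR-class
  aggregation and shares, gene rarefaction, and a symmetric
  Procrustes/protest comparison (`m² = 1 − (Σσ)²`) of resistome vs
  taxonomic ordinations per sample matrix.
* **Spike-in correction** — expected mock-community composition from
  cells × genome size × extraction efficiency, the spiked/unspiked
  background factor from non-mock genera, background subtraction with
  clamping, and log2 profiles relative to the 0 h mean.
* **Synthesis** — `generate_dataset()` builds the full designed
  experiment: 4 sample matrices × {0 h; 16/64 h at −80/−20/5/22 °C} × 3
  replicates, spiked/unspiked duplicates with an 8-member mock community,
  and a 2–4 freeze-thaw-cycle series, with every planted quantity
  recorded for scoring.

## Worked example

```r
library(storagefx)

ds <- generate_dataset(design_spec(matrices = c("P1", "S1"), n_genera = 40,
                                   n_amr_genes = 30, library_size = 2e4,
                                   freeze_thaw_cycles = NULL), seed = 11)
ids  <- ds$sheet$sample_id[!ds$sheet$spiked]
sh   <- ds$sheet[match(ids, ds$sheet$sample_id), ]
norm <- total_sum_scale(genome_size_normalize(ds$taxa[, ids], ds$taxa_meta))
d    <- bray_curtis(hellinger(norm))

subset(dissimilarity_to_baseline(d, sh), matrix == "P1")
#>    condition mean_dissimilarity      se n_pairs
#>          0 h             0.0635 0.00666       3
#>  16 h, -80°C             0.0790 0.00253       9
#>  64 h, -80°C             0.1426 0.00549       9
#>  16 h, -20°C             0.0704 0.00199       9
#>  64 h, -20°C             0.1596 0.00324       9
#>    16 h, 5°C             0.0734 0.00413       9
#>    64 h, 5°C             0.1163 0.00290       9
#>   16 h, 22°C             0.0818 0.00152       9
#>   64 h, 22°C             0.2231 0.00175       9
```

Room-temperature storage for 64 h moves the community furthest from the
immediately-processed baseline (0.223 vs the 0.064 replicate noise floor);
16 h in the refrigerator is nearly indistinguishable from immediate
processing — the planted storage biology, recovered by the pipeline.

```r
permanova(d, sh$matrix, n_permutations = 999, seed = 1,
          check_dispersion = TRUE)
#> PERMANOVA (matrix): pseudo-F = 46.5, R2 = 0.472, p = 0.001 (betadisper p = 0.89)

resistome_vs_taxonomy(ds$taxa[, ids], ds$amr[, ids], sh,
                      n_permutations = 999, seed = 1)
#>  matrix n_samples    m2 correlation p_value
#>      P1        27 0.184       0.903   0.001
#>      S1        27 0.212       0.888   0.001
```

Samples separate strongly by their matrix of origin (R² = 0.47, p = 0.001,
with homogeneous dispersions), and the resistome ordination mirrors the
taxonomic one within each matrix (Procrustes r ≈ 0.9, p = 0.001).

`run_storage_analysis()` chains every stage (validation, alpha, beta,
PERMANOVA, the baseline-dissimilarity table, CCA, differential abundance,
resistome, spike correction) into one seeded, logged run and can write all
result tables plus a manifest to a directory.

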