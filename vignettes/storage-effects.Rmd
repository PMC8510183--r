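---
title: "Models and methods behind storagefx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind storagefx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(storagefx)
```

# The problem

Microbiome studies rarely control how long a biospecimen sat at what
temperature before DNA was isolated. Storage is a lysis experiment run by
accident: warm storage lets hardy, rigid-walled organisms persist or grow
while fragile Gram-negative cells lyse and their DNA degrades; freezing
preserves overall composition but shifts it once, and repeated freeze-thaw
cycles preferentially crack thick cell walls, boosting the apparent
abundance of *Firmicutes*, *Actinobacteria* and microbial eukaryotes.
`storagefx` implements the statistical workflow for measuring these
distortions from genus-level taxonomic and AMR-gene count tables, and a
synthetic generator that plants them so the whole pipeline can be scored
against known truth.

# The synthetic experiment

`design_spec()` encodes the study layout: four sample matrices (two
pig-feces-like, `P1`/`P2`; two sewage-like, `S1`/`S2`), storage at −80,
−20, 5 and 22 °C for 16 and 64 h plus an unstored 0 h cell, three
DNA-isolation replicates per cell, spiked and unspiked duplicates, and a
freeze-thaw series (2–4 cycles at the two frozen temperatures for `P1`
and `S1`, timed at 40/64/88 h). The default unspiked main design is
therefore 4 × (1 + 4·2) × 3 = 108 samples, doubling with spiking and
growing by 72 freeze-thaw samples.

## Community model

Baseline log2 abundances for each genus are the sum of three Gaussian
components: one shared by all matrices (sd 1.5), one shared within a
matrix type (pig feces vs sewage, sd 1.0), and one matrix-specific
(sd 0.5). This makes all four matrices mutually distinguishable while
keeping same-type matrices more alike — the dominant, storage-independent
clustering by sample origin.

A storage condition perturbs the baseline on the log2 scale:

$$\log_2 a_{i}(T, t) = \log_2 a_i(0) + \big(\beta_{p(i)}(T) + \delta_i\big)\cdot \frac{t}{64\,\mathrm{h}},$$

where $\beta_{p}(T)$ is a per-phylum log2 rate, $\delta_i \sim N(0,
0.3^2)$ is a taxon-level deviation around its phylum, and time is scaled
linearly over the 0–64 h span (the data constrain only a gradient, not a
functional form, so the simplest monotone map is used). Profiles are
re-closed to sum to one, making the effects explicitly compositional. The
default rates (`default_phylum_effects()`) put Firmicutes (+1.6) and
Actinobacteria (+1.2) up and Bacteroidetes (−1.6) / Proteobacteria
(−1.2) down at 22 °C, half that at 5 °C, and a sign-flipped rate of
roughly 0.75× magnitude at both frozen temperatures. The two frozen
temperatures share one rate vector *and* one set of taxon deviations, so
−80 °C and −20 °C samples differ only by counting noise — the
"frozen samples resemble each other" structure. Magnitudes were chosen
once to give a realistic ordering and dynamic range of stored-vs-baseline
dissimilarities (replicate floor near 0.06–0.08, worst condition near
0.2); they are rates per unit scaled time, not measured fold changes.

Freeze-thaw cycles add `slope × cycles` on the log2 scale on top of the
frozen storage effect, with positive slopes (+0.3 to +0.4) for
rigid-walled groups and negative for Bacteroidetes/Proteobacteria.

Counts are gamma-Poisson: `sample_counts()` draws negative-binomial
counts with mean `profile × library size` and dispersion 0.05 (dispersion
0 degenerates to Poisson). The dispersion doubles as the replicate-noise
model and matches the differential-abundance model downstream. Library
sizes are lognormal around 2 × 10⁵ fragments (sdlog 0.3) — a desk-scale
stand-in for the millions of reads of a real study, chosen so that a full
default dataset simulates in well under a second while per-genus counts
remain deep enough for NB inference.

## Mock community and spiking

The 8-member mock community spans five bacterial phyla and two eukaryotes.
Spike read contributions are proportional to
`cells_per_mg × genome_size_bp × extraction_efficiency`, with default
efficiencies 1.0 (Gram-negative), 0.3 (Gram-positive), 0.1 (eukaryote) —
encoding that an extraction protocol recovers the most DNA per cell from
easily lysed Gram-negatives. Densities are 10⁹ cells/mg for Gram-positives
(halved for P1), 10⁸ for Gram-negatives, 2 × 10⁷ for *Saccharomyces* and
2 × 10⁶ for *Cryptosporidium*. Contributions are added to the *mean*
count vector and noise is applied once to the combined mean, so the
planted decomposition `spiked mean = native mean + contribution` is exact
and recorded in the ground truth. The default spike fraction is 10% of
the native library — large enough that correction quality is measurable
above counting noise, small enough not to drown the native community.

## AMR genes

Each of the 150 default genes is assigned a bacterial host genus, a drug
class (eight classes with tetracycline and macrolide most common), a
length (uniform 500–3000 bp) and a lognormal per-genome copy factor. Gene
means are `host count × copy factor × gene kb × scale`, so the resistome
inherits the taxonomic storage effects through its hosts — which is what
makes the Procrustes taxonomy-resistome comparison recoverable, and what
a real resistome does to first order.

## What the generator does *not* emulate

Read-level artifacts (mapping ambiguity, contig-level hit inflation),
DNA-extraction chemistry, library-preparation batch effects,
contamination in blanks, and between-taxon correlation beyond the phylum
effect structure. Passing the planted-truth checks therefore demonstrates
that the *statistics* recover effects of the modelled kind at realistic
depths and replication — not that any particular real dataset satisfies
the model.

# Analysis methods

**Preprocessing.** Mapped read-pair counts are halved to fragments (odd
entries are an error unless explicitly permitted), divided by genome size
per Mbp, and total-sum scaled. The genome-size unit is a pure rescaling
cancelled by TSS; normalized tables are kept as reals. All-zero samples
are warned about and retained.

**Alpha diversity** uses the raw count table: Chao1 needs integer
singleton/doubleton counts, and rarefaction subsamples fragments. The
bias-corrected Chao1 `S_obs + F1(F1−1)/(2(F2+1))` is used because it
stays finite with no doubletons. Shannon entropy uses the natural log;
Pielou's evenness is flagged `NA` below two observed taxa. Rarefaction
draws multivariate hypergeometric subsamples via sequential `rhyper`,
seeded.

**Beta diversity.** Bray-Curtis on Hellinger-transformed tables.
Hellinger square-roots relative abundances so that dominant taxa do not
monopolize the geometry. PCoA double-centers −d²/2 (Gower) and keeps
positive-eigenvalue axes for coordinates; negative eigenvalues are
reported but excluded, with no Cailliez/Lingoes correction — diagnostics,
not coordinates, are the point of those axes. Eigenvalues within
`1e-9 × max|λ|` of zero are dropped.

**PERMANOVA** partitions squared dissimilarities
(`SS_total = Σ_{i<j} d²/N`, within-group analog per group) and permutes
group labels; p-values use the add-one estimator with a default of 999
permutations, so the smallest attainable p is 0.001. The headline
matrix-effect test is so strong here that finer resolution buys nothing;
users probing borderline effects can raise `n_permutations`. The
dispersion check embeds the distance matrix by PCoA, computes distances
to group *centroids* (negative-eigenvalue axes subtract in the squared
distance, clamped at zero), and permutes labels around an ANOVA F — a
significant result means location and spread effects are confounded.

**CCA** works on the raw count table because the chi-square metric
carries its own row/column weighting. The standardized residual matrix
`Q = (P − rcᵀ)/sqrt(rcᵀ)` is projected onto the row-weighted space
spanned by the condition factor; the SVD of the projection gives the
constrained axes, and `ΣQ²` is the total inertia. Zero-sum rows and
columns are dropped with a warning; a constant factor is an error.

**Differential abundance** is an in-package negative-binomial Wald test,
deliberately simpler than DESeq2 (no Cox-Reid adjustment, no LFC priors):
size factors are column totals over their mean (the custom size-factor
rule appropriate when a handful of genera dominate the totals),
dispersions are per-taxon method-of-moments estimates on normalized
counts floored at 1e-8 and moderated by taking the maximum of the taxon
estimate and a fitted `a₀ + a₁/μ` trend — a conservative sharing rule
that keeps the 3-replicate false-positive rate at or below nominal (the
type-I rate at p < 0.01 measures ≈ 0.01 in the calibration tests). The
IRLS fit caps natural-log coefficients at ±50 so taxa absent from one
group report an extreme but finite fold change.

**Procrustes/protest** centers both coordinate sets, scales each to unit
sum of squares, takes the SVD of the cross-product, and reports
`m² = 1 − (Σσ)²`; significance permutes sample rows of the second matrix
with add-one smoothing. The comparison uses the first `min(n − 1, axes)`
principal coordinates of each ordination — all the metric information
available — since the number of axes is otherwise an arbitrary choice.

**Dissimilarity groups.** Pairs are classed as within-replicate,
within-matrix or between-matrix; Levene's test (raw and log values)
justifies the nonparametric route, Kruskal-Wallis (tie-corrected) tests
the overall difference, and Dunn's z tests run only when KW p < 0.05,
with Holm adjustment — chosen because it dominates Bonferroni uniformly
and the source analysis names no correction.

**Spike correction.** The background factor
`f = spiked non-mock mass / unspiked non-mock mass` per (matrix,
condition) is computed from replicate means on TSS relative abundances
(configurable to raw counts); the correction `spiked − f × unspiked`
is applied per spiked replicate. Negative corrected values are clamped to
zero and flagged; clamping induces a small positive bias for members
whose spike is tiny relative to their native background (in the default
experiment the pooled bias stays within a few percent of the spike
level). Members with a zero 0 h mean are excluded from the relative
profiles with a warning.

# Numerical conventions

Distance matrices must be symmetric to 1e-12 with an exactly zero
diagonal. Closure (profiles summing to 1) holds to 1e-12. Linkage ties in
the clustering supports are broken deterministically by sorting labels
before clustering. All permutation tests and all simulation draws take
explicit seeds; derived seeds come from a fixed integer mixing rule, so
identical seeds give byte-identical outputs everywhere, including the
TSV/JSON files the pipeline writes.

# Problem sizes used in validation

The test suite validates closed-form estimators on 100 random fixtures
each; calibrates PERMANOVA type-I error on 500 null simulations of 12
samples (199 permutations each) and against exhaustive enumeration at
N = 6; checks NB fold-change recovery at 3 vs 3 replicates × 200 taxa and
the null false-positive rate on 500 taxa; tests protest null uniformity
over 500 seeds; measures spike-correction bias over 200 seeded
spiked/unspiked pairs for each of the eight stored conditions at the
default 200-genus panel; and runs all planted-truth checks on the full
default dataset (288 samples). These sizes give Monte-Carlo errors
comfortably below the margins being tested while keeping the whole suite
under half a minute.

# Limitations

One-way designs only (no multi-factor PERMANOVA or blocked permutations);
no phylogeny-aware distances; the NB test approximates rather than
reproduces DESeq2; the generator's effects are log-linear in scaled time
with a single shared dispersion, which real storage kinetics need not
follow; and long-term storage (months) is outside the modelled 0–64 h
span.
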