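#' Resistome quantification
#'
#' AMR gene abundance as FPKM — fragments per kilobase of reference gene
#' per million bacterial fragments — plus class-level aggregation, gene
#' rarefaction, and the Procrustes comparison of resistome and taxonomic
#' ordination per sample matrix.
#'
#' @name resistome
NULL

#' FPKM normalization of AMR gene counts
#'
#' FPKM_gj = fragments_gj / (length_g / 1000) / (bacterial_total_j / 1e6).
#'
#' @param amr gene x sample fragment count table.
#' @param gene_lengths named vector (bp) or gene_meta data.frame with
#'   `gene` and `length_bp`.
#' @param bacterial_totals named per-sample bacterial fragment totals
#'   (> 0); see [bacterial_fragment_totals()].
#' @return list with `fpkm` (gene x sample) and `bacterial_totals`.
#' @export
fpkm <- function(amr, gene_lengths, bacterial_totals) {
  validate_count_table(amr)
  if (is.data.frame(gene_lengths)) {
    gene_lengths <- stats::setNames(gene_lengths$length_bp, gene_lengths$gene)
  }
  len <- gene_lengths[rownames(amr)]
  if (any(is.na(len) | len <= 0)) {
    stop("missing or non-positive length for gene(s): ",
         paste(rownames(amr)[is.na(len) | len <= 0], collapse = ", "),
         call. = FALSE)
  }
  bt <- bacterial_totals[colnames(amr)]
  bad <- is.na(bt) | bt <= 0
  if (any(bad)) {
    stop("zero or missing bacterial fragment total for sample(s): ",
         paste(colnames(amr)[bad], collapse = ", "), call. = FALSE)
  }
  out <- sweep(amr / (len / 1000), 2, bt / 1e6, "/")
  list(fpkm = out, bacterial_totals = bt)
}

#' Per-sample bacterial fragment totals from a taxon table
#'
#' Sums taxon fragment counts over bacterial genera only (eukaryotes,
#' archaea and viruses excluded), the denominator for FPKM.
#'
#' @param taxa genus x sample count table.
#' @param taxa_meta feature metadata with `feature_id` and `domain`.
#' @return named numeric vector.
#' @export
bacterial_fragment_totals <- function(taxa, taxa_meta) {
  validate_count_table(taxa)
  dom <- taxa_meta$domain[match(rownames(taxa), taxa_meta$feature_id)]
  if (any(is.na(dom))) {
    stop("taxa missing domain annotation: ",
         paste(rownames(taxa)[is.na(dom)], collapse = ", "), call. = FALSE)
  }
  colSums(taxa[dom == "bacteria", , drop = FALSE])
}

#' Aggregate FPKM to antimicrobial classes
#'
#' @param fpkm_table gene x sample FPKM matrix.
#' @param gene_classes named vector or gene_meta data.frame (`gene`,
#'   `amr_class`).
#' @return list with `classes` (class x sample FPKM), `total` (per-sample
#'   total AMR FPKM), and `shares` (class percentage of total per sample).
#' @export
class_abundance <- function(fpkm_table, gene_classes) {
  if (is.data.frame(gene_classes)) {
    gene_classes <- stats::setNames(gene_classes$amr_class, gene_classes$gene)
  }
  cls <- aggregate_features(fpkm_table, gene_classes)
  total <- colSums(cls)
  shares <- sweep(cls, 2, ifelse(total == 0, 1, total), "/") * 100
  list(classes = cls, total = total, shares = shares)
}

#' AMR gene rarefaction
#'
#' Rarefaction of observed AMR genes by subsampling fragments without
#' replacement; same contract as [rarefy_curve()].
#'
#' @inheritParams rarefy_curve
#' @export
amr_rarefaction <- function(counts, depths, iterations = 100, seed = 1) {
  rarefy_curve(counts, depths, iterations = iterations, seed = seed)
}

#' Procrustes comparison of resistome and taxonomy per sample matrix
#'
#' Within each matrix, both tables are Hellinger-transformed, Bray-Curtis
#' dissimilarities are computed and embedded by PCoA, and the two
#' ordinations are superimposed with a symmetric Procrustes rotation whose
#' significance comes from a row permutation test. The comparison uses the
#' first min(n - 1, available) principal coordinates of each ordination.
#'
#' @param taxa genus x sample count table.
#' @param amr gene- or class-level AMR table (counts or FPKM).
#' @param sheet sample sheet.
#' @param n_permutations permutations per matrix.
#' @param seed RNG seed.
#' @return data.frame with matrix, n_samples, m2, correlation, p_value.
#' @export
resistome_vs_taxonomy <- function(taxa, amr, sheet, n_permutations = 999,
                                  seed = 1) {
  ids <- intersect(colnames(taxa), colnames(amr))
  sheet <- sheet[match(ids, sheet$sample_id), , drop = FALSE]
  out <- list()
  for (mx in unique(sheet$matrix)) {
    sel <- ids[sheet$matrix == mx]
    if (length(sel) < 4) {
      warning(sprintf("matrix '%s' has < 4 samples; skipped", mx), call. = FALSE)
      next
    }
    pa <- pcoa(bray_curtis(hellinger(taxa[, sel, drop = FALSE])))
    pb <- pcoa(bray_curtis(hellinger(amr[, sel, drop = FALSE])))
    k <- min(length(sel) - 1, ncol(pa$coordinates), ncol(pb$coordinates))
    pr <- procrustes_protest(pa$coordinates[, seq_len(k), drop = FALSE],
                             pb$coordinates[, seq_len(k), drop = FALSE],
                             n_permutations = n_permutations,
                             seed = mix_seed(seed, match(mx, unique(sheet$matrix))))
    out[[mx]] <- data.frame(matrix = mx, n_samples = length(sel),
                            m2 = pr$m2, correlation = pr$correlation,
                            p_value = pr$p_value, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
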