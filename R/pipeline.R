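#' End-to-end storage-effect analysis
#'
#' Orchestrates the full workflow — synthesis (or loading) of count
#' tables, validation, preprocessing, alpha diversity, Bray-Curtis
#' ordination, PERMANOVA with its dispersion check, the
#' stored-vs-baseline dissimilarity table, constrained correspondence
#' analysis, differential abundance, resistome quantification with the
#' Procrustes taxonomy comparison, and mock-community spike correction —
#' as one seeded, logged run. Spiked and unspiked sample sets are always
#' analyzed separately.
#'
#' @name pipeline
NULL

#' Validate a dataset bundle
#'
#' Checks identifier consistency between tables and the sample sheet,
#' nonnegativity, annotation completeness, and replicate counts per
#' design cell. Fatal problems and warnings are distinguished.
#'
#' @param taxa genus x sample count table.
#' @param sheet sample sheet.
#' @param taxa_meta feature metadata (genome sizes, domains).
#' @param amr optional gene x sample table.
#' @param gene_meta optional gene metadata.
#' @return data.frame with columns severity ("error"/"warning") and
#'   message; zero rows when the bundle is clean.
#' @export
validate_inputs <- function(taxa, sheet, taxa_meta, amr = NULL,
                            gene_meta = NULL) {
  issues <- list()
  note <- function(sev, msg) issues[[length(issues) + 1]] <<- data.frame(
    severity = sev, message = msg, stringsAsFactors = FALSE)
  miss <- setdiff(colnames(taxa), sheet$sample_id)
  if (length(miss)) note("error", paste("samples missing from sheet:",
                                        paste(miss, collapse = ", ")))
  extra <- setdiff(sheet$sample_id, colnames(taxa))
  if (length(extra)) note("warning", paste("sheet rows without counts:",
                                           paste(extra, collapse = ", ")))
  if (any(taxa < 0)) note("error", "negative taxon counts")
  unann <- setdiff(rownames(taxa), taxa_meta$feature_id)
  if (length(unann)) note("error", paste("genera without metadata:",
                                         paste(unann, collapse = ", ")))
  gs <- taxa_meta$genome_size_bp[match(rownames(taxa), taxa_meta$feature_id)]
  if (any(!is.na(match(rownames(taxa), taxa_meta$feature_id)) &
          (is.na(gs) | gs <= 0))) {
    note("error", "genus with missing or non-positive genome size")
  }
  sh <- sheet[match(colnames(taxa), sheet$sample_id), , drop = FALSE]
  sh <- sh[!is.na(sh$sample_id), , drop = FALSE]
  if (nrow(sh)) {
    cell <- paste(sh$matrix, condition_label(sh), sh$spiked)
    reps <- table(cell)
    if (length(unique(reps)) > 1) {
      note("warning", sprintf("unbalanced replicate counts per design cell (%s)",
                              paste(range(reps), collapse = "-")))
    }
  }
  if (!is.null(amr)) {
    if (any(amr < 0)) note("error", "negative AMR counts")
    if (!is.null(gene_meta)) {
      ung <- setdiff(rownames(amr), gene_meta$gene)
      if (length(ung)) note("error", paste("genes without metadata:",
                                           paste(ung, collapse = ", ")))
    }
  }
  if (length(issues) == 0) {
    return(data.frame(severity = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Run the full storage-effect analysis
#'
#' @param data a [generate_dataset()] bundle, or NULL to simulate one
#'   from `design`/`model`/`mock`.
#' @param design,model,mock synthesis parameters (used when `data` is
#'   NULL).
#' @param seed master seed for synthesis and all permutation tests.
#' @param outdir optional directory; when given, every result table is
#'   written as TSV plus a JSON manifest with the seed and config hash.
#' @param diff_alpha significance threshold for differential abundance.
#' @param kw_alpha Kruskal-Wallis gate for the Dunn post hoc test.
#' @param permanova_permutations,procrustes_permutations permutation
#'   counts.
#' @param diffabund_pairs "baseline" (each stored condition vs 0 h,
#'   default) or "all" (every condition pair).
#' @param quiet suppress progress messages.
#' @return a report list with one element per stage (see Details), plus
#'   `manifest`.
#' @details Stages and their outputs: `validation`; `alpha` (per-sample
#'   indices); `beta` (distance matrices, PCoA, silhouette by matrix and
#'   by condition); `adonis` (PERMANOVA by matrix, plus per-matrix
#'   condition tests with dispersion checks); `dissimilarity` (group
#'   comparison and the stored-vs-0 h table); `cca` (per-matrix
#'   constrained ordination); `diffabund` (per-matrix pairwise NB Wald
#'   tests and significance counts); `resistome` (FPKM, class shares,
#'   Procrustes vs taxonomy); `spike` (background factors, corrected
#'   mock abundances, condition profiles). Every stage is computed
#'   separately for unspiked and spiked sample sets where both exist.
#' @export
run_storage_analysis <- function(data = NULL, design = design_spec(),
                                 model = effect_model(), mock = mock_spec(),
                                 seed = 1, outdir = NULL, diff_alpha = 0.01,
                                 kw_alpha = 0.05,
                                 permanova_permutations = 999,
                                 procrustes_permutations = 999,
                                 diffabund_pairs = c("baseline", "all"),
                                 quiet = FALSE) {
  diffabund_pairs <- match.arg(diffabund_pairs)
  t0 <- Sys.time()
  log_stage <- function(name, expr) {
    st <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    if (!quiet) message(sprintf("[%s] %.1fs", name,
                                as.numeric(Sys.time() - st, units = "secs")))
    out
  }

  ds <- log_stage("simulate", data %||% generate_dataset(design, model, mock, seed))
  val <- log_stage("validate", validate_inputs(ds$taxa, ds$sheet, ds$taxa_meta,
                                               ds$amr, ds$gene_meta))
  if (any(val$severity == "error")) {
    stop("validation failed: ",
         paste(val$message[val$severity == "error"], collapse = "; "),
         call. = FALSE)
  }

  states <- sort(unique(ds$sheet$spiked))  # FALSE first
  per_state <- function(fun) {
    out <- lapply(states, function(sp) {
      ids <- ds$sheet$sample_id[ds$sheet$spiked == sp]
      fun(ids, sp)
    })
    names(out) <- ifelse(states, "spiked", "unspiked")
    out
  }

  alpha <- log_stage("alpha", per_state(function(ids, sp) {
    alpha_diversity(ds$taxa[, ids, drop = FALSE])
  }))

  beta <- log_stage("beta", per_state(function(ids, sp) {
    x <- ds$taxa[, ids, drop = FALSE]
    norm <- total_sum_scale(genome_size_normalize(x, ds$taxa_meta))
    d <- bray_curtis(hellinger(norm))
    ord <- pcoa(d)
    sh <- ds$sheet[match(ids, ds$sheet$sample_id), ]
    list(distance = d, pcoa = ord, normalized = norm,
         silhouette_matrix = mean_silhouette(d, sh$matrix),
         silhouette_condition = mean_silhouette(d, condition_label(sh)))
  }))

  adonis <- log_stage("adonis", per_state(function(ids, sp) {
    d <- beta[[if (sp) "spiked" else "unspiked"]]$distance
    sh <- ds$sheet[match(ids, ds$sheet$sample_id), ]
    overall <- if (length(unique(sh$matrix)) >= 2) {
      permanova(d, sh$matrix, permanova_permutations,
                seed = mix_seed(seed, 41L), check_dispersion = TRUE)
    } else NULL
    by_matrix <- lapply(unique(sh$matrix), function(mx) {
      idx <- sh$matrix == mx & sh$freeze_thaw_cycles == 0
      permanova(d[sh$sample_id[idx], sh$sample_id[idx]],
                condition_label(sh[idx, ]), permanova_permutations,
                seed = mix_seed(seed, 42L + match(mx, unique(sh$matrix))),
                check_dispersion = TRUE)
    })
    names(by_matrix) <- unique(sh$matrix)
    list(overall = overall, by_matrix = by_matrix)
  }))

  dissim <- log_stage("dissimilarity", per_state(function(ids, sp) {
    d <- beta[[if (sp) "spiked" else "unspiked"]]$distance
    sh <- ds$sheet[match(ids, ds$sheet$sample_id), ]
    pg <- pair_dissimilarity_groups(d, sh)
    list(groups = dissimilarity_groups(pg$value, pg$group, kw_alpha = kw_alpha),
         to_baseline = dissimilarity_to_baseline(d, sh))
  }))

  cca_res <- log_stage("cca", per_state(function(ids, sp) {
    sh <- ds$sheet[match(ids, ds$sheet$sample_id), ]
    out <- lapply(unique(sh$matrix), function(mx) {
      idx <- sh$matrix == mx & sh$freeze_thaw_cycles == 0
      cca_constrained(ds$taxa[, sh$sample_id[idx], drop = FALSE],
                      condition_label(sh[idx, ]))
    })
    names(out) <- unique(sh$matrix)
    out
  }))

  diffab <- log_stage("diffabund", per_state(function(ids, sp) {
    sh <- ds$sheet[match(ids, ds$sheet$sample_id), ]
    sh <- sh[sh$freeze_thaw_cycles == 0, ]
    out <- lapply(unique(sh$matrix), function(mx) {
      shm <- sh[sh$matrix == mx, ]
      conds <- unique(condition_label(shm))
      pairs <- if (diffabund_pairs == "baseline") {
        cbind("0h", setdiff(conds, "0h"))
      } else t(utils::combn(conds, 2))
      res <- lapply(seq_len(nrow(pairs)), function(i) {
        sel <- condition_label(shm) %in% pairs[i, ]
        x <- ds$taxa[, shm$sample_id[sel], drop = FALSE]
        g <- factor(condition_label(shm[sel, ]), levels = pairs[i, ])
        r <- nb_wald_test(x, g, alpha = diff_alpha)
        r$group_a <- pairs[i, 1]; r$group_b <- pairs[i, 2]
        r
      })
      list(tests = res, counts = significance_counts(res))
    })
    names(out) <- unique(sh$matrix)
    out
  }))

  resist <- log_stage("resistome", per_state(function(ids, sp) {
    bt <- bacterial_fragment_totals(ds$taxa[, ids, drop = FALSE], ds$taxa_meta)
    fq <- fpkm(ds$amr[, ids, drop = FALSE], ds$gene_meta, bt)
    ca <- class_abundance(fq$fpkm, ds$gene_meta)
    sh <- ds$sheet[match(ids, ds$sheet$sample_id), ]
    pr <- resistome_vs_taxonomy(ds$taxa[, ids, drop = FALSE],
                                ds$amr[, ids, drop = FALSE], sh,
                                n_permutations = procrustes_permutations,
                                seed = mix_seed(seed, 51L))
    list(fpkm = fq$fpkm, classes = ca, procrustes = pr)
  }))

  spike <- if (all(c(TRUE, FALSE) %in% states)) log_stage("spike", {
    sp_ids <- ds$sheet$sample_id[ds$sheet$spiked]
    un_ids <- ds$sheet$sample_id[!ds$sheet$spiked]
    mg <- intersect(mock$genus, rownames(ds$taxa))
    corr <- correct_spiked(ds$taxa[, sp_ids, drop = FALSE],
                           ds$taxa[, un_ids, drop = FALSE],
                           mg, ds$sheet)
    list(correction = corr,
         profiles = mock_condition_profiles(corr$corrected, ds$sheet))
  }) else {
    if (!quiet) message("[spike] skipped: no matched spiked/unspiked sets")
    NULL
  }

  report <- list(data = ds, validation = val, alpha = alpha, beta = beta,
                 adonis = adonis, dissimilarity = dissim, cca = cca_res,
                 diffabund = diffab, resistome = resist, spike = spike)
  report$manifest <- list(
    package_version = as.character(utils::packageVersion("storagefx")),
    seed = seed,
    n_samples = ncol(ds$taxa), n_genera = nrow(ds$taxa),
    n_amr_genes = nrow(ds$amr),
    stages = setdiff(names(report), "data"),
    elapsed_s = as.numeric(Sys.time() - t0, units = "secs"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Mean silhouette width of a labelling on a distance matrix
#'
#' a(i) is the mean distance to the sample's own group, b(i) the smallest
#' mean distance to any other group; s(i) = (b - a) / max(a, b).
#'
#' @param d distance matrix.
#' @param labels group labels.
#' @return mean silhouette width over samples in groups of size >= 2.
#' @export
mean_silhouette <- function(d, labels) {
  d <- check_distance_matrix(d)
  labels <- as.character(labels)
  sizes <- table(labels)
  if (length(sizes) < 2) return(NA_real_)
  s <- vapply(seq_len(nrow(d)), function(i) {
    li <- labels[i]
    if (sizes[li] < 2) return(NA_real_)
    a <- mean(d[i, labels == li & seq_len(nrow(d)) != i])
    b <- min(vapply(setdiff(names(sizes), li), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s, na.rm = TRUE)
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(report$data, file.path(outdir, "input"))
  for (state in names(report$alpha)) {
    utils::write.table(report$alpha[[state]],
                       file.path(outdir, sprintf("alpha_%s.tsv", state)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_count_table(report$beta[[state]]$distance,
                      file.path(outdir, sprintf("bray_curtis_%s.tsv", state)),
                      id_column = "sample_id")
    utils::write.table(report$dissimilarity[[state]]$to_baseline,
                       file.path(outdir, sprintf("dissimilarity_to_0h_%s.tsv", state)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$resistome[[state]]$procrustes,
                       file.path(outdir, sprintf("procrustes_%s.tsv", state)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$spike)) {
    utils::write.table(report$spike$correction$audit,
                       file.path(outdir, "spike_correction_audit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(report$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  hash <- unname(tools::md5sum(manifest_path))
  m <- report$manifest; m$manifest_md5 <- hash
  jsonlite::write_json(m, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
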