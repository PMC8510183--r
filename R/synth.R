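#' Synthetic storage-experiment generator
#'
#' Generates genus-level taxonomic and AMR-gene count tables for a
#' designed storage experiment: four sample matrices (two pig-feces-like,
#' two sewage-like), four storage temperatures, storage times of 0/16/64
#' hours in triplicate, spiked and unspiked duplicates carrying an
#' eight-member mock community, and a freeze-thaw-cycle series. Storage
#' effects are planted at the phylum level (warm storage favours
#' Firmicutes and Actinobacteria at the expense of Bacteroidetes and
#' Proteobacteria; frozen storage flips the signs; freeze-thaw cycles
#' favour rigid-walled organisms), so every downstream analysis can be
#' scored against known ground truth.
#'
#' @name synth
NULL

PHYLA <- data.frame(
  phylum = c("Firmicutes", "Bacteroidetes", "Proteobacteria", "Actinobacteria",
             "Spirochaetes", "Fusobacteria", "Euryarchaeota", "Ascomycota",
             "Apicomplexa"),
  domain = c("bacteria", "bacteria", "bacteria", "bacteria", "bacteria",
             "bacteria", "archaea", "eukaryote", "eukaryote"),
  prob = c(0.30, 0.25, 0.17, 0.10, 0.06, 0.03, 0.03, 0.03, 0.03),
  stringsAsFactors = FALSE)

MOCK_GENERA <- c("Propionibacterium", "Bacteroides", "Staphylococcus",
                 "Fusobacterium", "Escherichia", "Salmonella",
                 "Cryptosporidium", "Saccharomyces")

#' Experimental design specification
#'
#' @param matrices sample matrix ids (two pig feces, two sewage by
#'   default).
#' @param temperatures storage temperatures in degrees C.
#' @param times storage durations in hours; must contain 0 (immediate
#'   processing), which carries no temperature factor.
#' @param replicates DNA-isolation replicates per design cell (>= 2).
#' @param freeze_thaw_cycles cycle counts for the freeze-thaw series
#'   (empty vector or NULL disables the series).
#' @param freeze_thaw_matrices matrices entering the freeze-thaw series.
#' @param freeze_thaw_temperatures temperatures of the series; must be
#'   frozen (< 0).
#' @param spiked generate spiked duplicates alongside unspiked samples.
#' @param n_genera number of genera (>= 20; includes the 8 mock genera).
#' @param n_amr_genes number of AMR genes.
#' @param library_size expected sequencing depth in fragments per sample.
#' @param spike_fraction expected fraction of a spiked library
#'   contributed by the mock community.
#' @return object of class `design_spec`.
#' @export
design_spec <- function(matrices = c("P1", "P2", "S1", "S2"),
                        temperatures = c(-80, -20, 5, 22),
                        times = c(0, 16, 64),
                        replicates = 3,
                        freeze_thaw_cycles = c(2, 3, 4),
                        freeze_thaw_matrices = intersect(c("P1", "S1"), matrices),
                        freeze_thaw_temperatures = c(-80, -20),
                        spiked = TRUE,
                        n_genera = 200,
                        n_amr_genes = 150,
                        library_size = 2e5,
                        spike_fraction = 0.1) {
  if (replicates < 2) stop("replicates must be >= 2", call. = FALSE)
  if (sum(times == 0) != 1) stop("time 0 must appear exactly once", call. = FALSE)
  if (n_genera < 20) stop("n_genera must be >= 20", call. = FALSE)
  fc <- freeze_thaw_cycles %||% numeric(0)
  if (length(fc) > 0 && any(freeze_thaw_temperatures >= 0)) {
    stop("freeze-thaw cycles are only defined at frozen temperatures", call. = FALSE)
  }
  structure(list(matrices = matrices, temperatures = temperatures,
                 times = times, replicates = replicates,
                 freeze_thaw_cycles = fc,
                 freeze_thaw_matrices = if (length(fc)) freeze_thaw_matrices else character(0),
                 freeze_thaw_temperatures = freeze_thaw_temperatures,
                 spiked = spiked, n_genera = n_genera,
                 n_amr_genes = n_amr_genes, library_size = library_size,
                 spike_fraction = spike_fraction),
            class = "design_spec")
}

#' Planted storage-effect model
#'
#' Per-phylum log2-fold-change rates per unit scaled storage time
#' (hours/64), one rate per temperature; the two frozen temperatures
#' share one rate so that deep-frozen and frozen samples differ only by
#' noise. Warm storage must favour Firmicutes/Actinobacteria and
#' disfavour Bacteroidetes/Proteobacteria; frozen effects are
#' sign-flipped; freeze-thaw slopes (per cycle) are positive for
#' rigid-walled groups (Firmicutes, Actinobacteria, eukaryotes).
#'
#' @param phylum_effects phylum x temperature matrix of log2 rates.
#' @param freeze_thaw_effects named vector of per-cycle log2 slopes.
#' @param taxon_effect_sd sd of per-taxon deviations around the phylum
#'   rate (log2 units).
#' @param nb_dispersion negative-binomial dispersion of replicate counts.
#' @param library_size_lognormal_sd sd of log library size.
#' @return object of class `effect_model`.
#' @export
effect_model <- function(phylum_effects = default_phylum_effects(),
                         freeze_thaw_effects = c(
                           Firmicutes = 0.30, Actinobacteria = 0.30,
                           Ascomycota = 0.40, Apicomplexa = 0.40,
                           Bacteroidetes = -0.30, Proteobacteria = -0.30),
                         taxon_effect_sd = 0.30,
                         nb_dispersion = 0.05,
                         library_size_lognormal_sd = 0.3) {
  warm <- as.character(c(5, 22))
  frozen <- colnames(phylum_effects)[as.numeric(colnames(phylum_effects)) < 0]
  up <- c("Firmicutes", "Actinobacteria")
  down <- c("Bacteroidetes", "Proteobacteria")
  ok <- all(phylum_effects[up, warm] > 0) && all(phylum_effects[down, warm] < 0) &&
    all(phylum_effects[up, frozen] < 0) && all(phylum_effects[down, frozen] > 0)
  if (!ok) {
    stop("phylum effects must be positive for Firmicutes/Actinobacteria and negative for Bacteroidetes/Proteobacteria at warm temperatures, sign-flipped when frozen",
         call. = FALSE)
  }
  if (any(freeze_thaw_effects[c("Firmicutes", "Actinobacteria", "Ascomycota",
                                "Apicomplexa")] <= 0)) {
    stop("freeze-thaw slopes must be positive for rigid-walled groups", call. = FALSE)
  }
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  structure(list(phylum_effects = phylum_effects,
                 freeze_thaw_effects = freeze_thaw_effects,
                 taxon_effect_sd = taxon_effect_sd,
                 nb_dispersion = nb_dispersion,
                 library_size_lognormal_sd = library_size_lognormal_sd),
            class = "effect_model")
}

#' Default phylum-level log2 rates per temperature
#'
#' Columns are temperatures (-80, -20, 5, 22); the frozen columns are
#' identical by construction. Magnitudes are chosen to reproduce the
#' qualitative ordering of storage dissimilarities (largest change at
#' 22 C for 64 h, mild change at 5 C for 16 h) rather than any measured
#' fold change.
#'
#' @return phylum x temperature numeric matrix.
#' @export
default_phylum_effects <- function() {
  temps <- c(-80, -20, 5, 22)
  m <- matrix(0, nrow = nrow(PHYLA), ncol = length(temps),
              dimnames = list(PHYLA$phylum, as.character(temps)))
  warm22 <- c(Firmicutes = 1.6, Actinobacteria = 1.2,
              Bacteroidetes = -1.6, Proteobacteria = -1.2)
  frozen <- c(Firmicutes = -1.2, Actinobacteria = -0.9,
              Bacteroidetes = 1.2, Proteobacteria = 0.9)
  m[names(warm22), "22"] <- warm22
  m[names(warm22), "5"] <- warm22 / 2
  m[names(frozen), "-80"] <- frozen
  m[names(frozen), "-20"] <- frozen
  m
}

#' Mock community specification
#'
#' Eight cultured organisms spanning bacteria and eukaryotes, with spike
#' cell densities, genome sizes, and DNA-extraction efficiencies per cell
#' class (Gram-negative cells lyse most readily, Gram-positive less, and
#' thick-walled eukaryotes least).
#'
#' @param gram_positive_cells cells/mg of each Gram-positive member
#'   (halved for the P1 matrix in the default experiment).
#' @param extraction_efficiency named relative DNA yield per cell class.
#' @return data.frame of class `mock_spec` with columns genus, cell_class,
#'   phylum, genome_size_bp, cells_per_mg, extraction_efficiency.
#' @export
mock_spec <- function(gram_positive_cells = 1e9,
                      extraction_efficiency = c(gram_negative = 1.0,
                                                gram_positive = 0.3,
                                                eukaryote = 0.1)) {
  df <- data.frame(
    genus = MOCK_GENERA,
    cell_class = c("gram_positive", "gram_negative", "gram_positive",
                   "gram_negative", "gram_negative", "gram_negative",
                   "eukaryote", "eukaryote"),
    phylum = c("Actinobacteria", "Bacteroidetes", "Firmicutes",
               "Fusobacteria", "Proteobacteria", "Proteobacteria",
               "Apicomplexa", "Ascomycota"),
    genome_size_bp = c(2.6e6, 5.2e6, 2.8e6, 2.2e6, 5.1e6, 4.9e6, 9.1e6, 1.2e7),
    cells_per_mg = c(gram_positive_cells, 1e8, gram_positive_cells,
                     1e8, 1e8, 1e8, 2e6, 2e7),
    stringsAsFactors = FALSE)
  df$extraction_efficiency <- unname(extraction_efficiency[df$cell_class])
  if (any(df$cells_per_mg <= 0)) stop("cells_per_mg must be positive", call. = FALSE)
  class(df) <- c("mock_spec", "data.frame")
  df
}

# Deterministic genus panel shared across matrices: the 8 mock genera plus
# synthetic genera with phylum assignments and genome sizes.
build_taxonomy <- function(n_genera, seed) {
  ms <- mock_spec()
  with_seed(mix_seed(seed, 1L), {
    n_extra <- n_genera - length(MOCK_GENERA)
    phyla <- sample(PHYLA$phylum, n_extra, replace = TRUE, prob = PHYLA$prob)
    extra <- data.frame(
      feature_id = sprintf("Genus_%03d", seq_len(n_extra)),
      genus = sprintf("Genus_%03d", seq_len(n_extra)),
      phylum = phyla,
      genome_size_bp = round(exp(stats::rnorm(n_extra, log(4e6), 0.4))),
      stringsAsFactors = FALSE)
    mock <- data.frame(feature_id = ms$genus, genus = ms$genus,
                       phylum = ms$phylum, genome_size_bp = ms$genome_size_bp,
                       stringsAsFactors = FALSE)
    out <- rbind(mock, extra)
    out$domain <- PHYLA$domain[match(out$phylum, PHYLA$phylum)]
    out
  })
}

#' Baseline (0 h) community profile for one sample matrix
#'
#' Log-abundances are the sum of a genus component shared by all matrices,
#' a component shared within the matrix type (pig feces vs sewage, from
#' the id's first letter), and a matrix-specific component — so matrices
#' are mutually distinct but same-type matrices resemble each other.
#'
#' @param matrix_id e.g. "P1".
#' @param n_genera number of genera (>= 20).
#' @param seed RNG seed; profiles are deterministic given (matrix_id,
#'   n_genera, seed).
#' @param taxonomy optional precomputed [build_taxonomy()] table.
#' @return list with `profile` (relative abundances summing to 1),
#'   `log2_abundance`, `feature_meta`, `matrix_id`.
#' @export
simulate_baseline <- function(matrix_id, n_genera = 200, seed = 1,
                              taxonomy = NULL) {
  if (n_genera < 20) stop("n_genera must be >= 20", call. = FALSE)
  tax <- taxonomy %||% build_taxonomy(n_genera, seed)
  if (length(unique(tax$phylum)) < 4) {
    stop("at least 4 phylum groups required", call. = FALSE)
  }
  n <- nrow(tax)
  base <- with_seed(mix_seed(seed, 2L), stats::rnorm(n, 0, 1.5))
  type_key <- sum(utf8ToInt(substr(matrix_id, 1, 1)))
  type_comp <- with_seed(mix_seed(seed, 100L + type_key), stats::rnorm(n, 0, 1.0))
  mat_key <- sum(utf8ToInt(matrix_id) * seq_along(utf8ToInt(matrix_id)))
  mat_comp <- with_seed(mix_seed(seed, 1000L + mat_key), stats::rnorm(n, 0, 0.5))
  log2_ab <- base + type_comp + mat_comp
  prof <- 2^log2_ab
  prof <- prof / sum(prof)
  names(prof) <- tax$feature_id
  list(profile = prof, log2_abundance = stats::setNames(log2_ab, tax$feature_id),
       feature_meta = tax, matrix_id = matrix_id)
}

#' Apply a planted storage effect to a baseline profile
#'
#' log2 expected abundance = baseline + (phylum rate + taxon deviation) *
#' scaled time, with time scaled linearly to [0, 1] over the 0-64 h span;
#' the profile is then re-closed to sum to 1. At time 0 the baseline is
#' returned exactly.
#'
#' @param baseline result of [simulate_baseline()].
#' @param condition list with `temperature_C` and `time_h` (optionally
#'   `freeze_thaw_cycles`).
#' @param model an [effect_model()].
#' @param taxon_dev optional per-taxon log2 deviations (default 0).
#' @return expected relative-abundance profile under the condition.
#' @export
apply_storage_effect <- function(baseline, condition, model,
                                 taxon_dev = NULL) {
  t_scaled <- condition$time_h / 64
  if (condition$time_h == 0) return(baseline$profile)
  key <- as.character(condition$temperature_C)
  if (!key %in% colnames(model$phylum_effects)) {
    stop(sprintf("unknown temperature %s°C", key), call. = FALSE)
  }
  eff <- model$phylum_effects[baseline$feature_meta$phylum, key]
  dev <- taxon_dev %||% numeric(length(eff))
  ft <- condition$freeze_thaw_cycles %||% 0
  ft_eff <- if (ft > 0) {
    slopes <- model$freeze_thaw_effects[baseline$feature_meta$phylum]
    slopes[is.na(slopes)] <- 0
    unname(slopes) * ft
  } else 0
  log2_ab <- baseline$log2_abundance + (eff + dev) * t_scaled + ft_eff
  prof <- 2^log2_ab
  stats::setNames(prof / sum(prof), names(baseline$profile))
}

#' Draw counts from an expected profile
#'
#' Gamma-Poisson (negative binomial) counts with mean profile *
#' library_size; dispersion 0 degenerates to Poisson.
#'
#' @param profile expected relative abundances.
#' @param library_size total expected fragments (> 0).
#' @param nb_dispersion dispersion (>= 0).
#' @param seed RNG seed.
#' @return integer count vector, named as the profile.
#' @export
sample_counts <- function(profile, library_size, nb_dispersion = 0.05, seed = 1) {
  if (library_size <= 0) stop("library_size must be > 0", call. = FALSE)
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  mu <- profile * library_size
  with_seed(seed, {
    k <- if (nb_dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion)
    stats::setNames(as.numeric(k), names(profile))
  })
}

#' Add mock-community spike contributions to a mean vector
#'
#' Planted read contributions are proportional to cells_per_mg *
#' genome_size_bp * extraction_efficiency, scaled so they total
#' `spike_fraction` of the native library. The contribution is added to
#' the native mean of each mock genus (noise is applied afterwards, once,
#' to the combined mean).
#'
#' @param native_mean named vector of native expected fragment counts.
#' @param mock a [mock_spec()].
#' @param spike_fraction spike share of the native library total.
#' @return list with `mean` (spiked mean vector) and `contribution`
#'   (planted fragments per mock genus, zero elsewhere).
#' @export
spike_mock <- function(native_mean, mock, spike_fraction = 0.1) {
  missing <- setdiff(mock$genus, names(native_mean))
  if (length(missing) > 0) {
    stop("mock genus not present in the taxon panel: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  contrib <- stats::setNames(numeric(length(native_mean)), names(native_mean))
  if (spike_fraction > 0) {
    w <- expected_mock_profile(mock)
    contrib[mock$genus] <- w[mock$genus] * spike_fraction * sum(native_mean)
  }
  list(mean = native_mean + contrib, contribution = contrib)
}

#' Simulate AMR gene counts linked to host taxa
#'
#' Each gene's expected count is host taxon count * copy factor * gene
#' length (kb) * `scale`, with gamma-Poisson noise. Genes whose host is
#' absent get zero mean.
#'
#' @param host_counts named taxon count vector.
#' @param gene_meta data.frame with gene, host_genus, length_bp,
#'   amr_class, copy_factor.
#' @param scale global proportionality constant.
#' @param nb_dispersion dispersion.
#' @param seed RNG seed.
#' @return named integer gene count vector.
#' @export
simulate_amr <- function(host_counts, gene_meta, scale = 1,
                         nb_dispersion = 0.05, seed = 1) {
  unknown <- setdiff(gene_meta$host_genus, names(host_counts))
  if (length(unknown) > 0) {
    stop("gene(s) mapped to unknown taxon: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mu <- host_counts[gene_meta$host_genus] * gene_meta$copy_factor *
    (gene_meta$length_bp / 1000) * scale
  with_seed(seed, {
    k <- if (nb_dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion)
    stats::setNames(as.numeric(k), gene_meta$gene)
  })
}

AMR_CLASSES <- c(tetracycline = 0.30, macrolide = 0.20, `beta-lactam` = 0.15,
                 aminoglycoside = 0.12, lincosamide = 0.08, sulfonamide = 0.06,
                 phenicol = 0.05, glycopeptide = 0.04)

#' Generate the AMR gene panel
#'
#' Genes are assigned to bacterial host genera, drug classes, lengths and
#' per-genome copy factors. Classes are preferentially linked to phyla so
#' that planted taxonomic storage effects propagate into class-level
#' resistome shifts.
#'
#' @param n_genes number of genes.
#' @param taxonomy [build_taxonomy()] table.
#' @param seed RNG seed.
#' @return data.frame with gene, host_genus, host_phylum, amr_class,
#'   length_bp, copy_factor.
#' @export
build_amr_genes <- function(n_genes, taxonomy, seed = 1) {
  bact <- taxonomy[taxonomy$domain == "bacteria", ]
  with_seed(mix_seed(seed, 3L), {
    hosts <- sample(bact$feature_id, n_genes, replace = TRUE)
    cls <- sample(names(AMR_CLASSES), n_genes, replace = TRUE, prob = AMR_CLASSES)
    data.frame(gene = sprintf("amr_%03d", seq_len(n_genes)),
               host_genus = hosts,
               host_phylum = bact$phylum[match(hosts, bact$feature_id)],
               amr_class = cls,
               length_bp = round(stats::runif(n_genes, 500, 3000)),
               copy_factor = exp(stats::rnorm(n_genes, 0, 0.5)),
               stringsAsFactors = FALSE)
  })
}

condition_label <- function(sheet) {
  ft <- sheet$freeze_thaw_cycles %||% rep(0, nrow(sheet))
  ft[is.na(ft)] <- 0
  ifelse(ft > 0,
         sprintf("FT%d_%gC", ft, sheet$temperature_C),
         ifelse(sheet$time_h == 0, "0h",
                sprintf("%gh_%gC", sheet$time_h, sheet$temperature_C)))
}

#' Generate a complete synthetic storage-experiment dataset
#'
#' @param design a [design_spec()].
#' @param model an [effect_model()].
#' @param mock a [mock_spec()] (the Gram-positive density is halved for
#'   matrix P1, matching the experimental spiking scheme).
#' @param seed master RNG seed; outputs are byte-identical given the same
#'   seed.
#' @return list with `taxa` (genus x sample counts), `amr` (gene x sample
#'   counts), `sheet` (sample metadata), `taxa_meta`, `gene_meta`, and
#'   `truth` (expected profiles per condition, per-sample expected means,
#'   planted spike contributions, library sizes, the effect model and
#'   design).
#' @export
generate_dataset <- function(design = design_spec(), model = effect_model(),
                             mock = mock_spec(), seed = 1) {
  tax <- build_taxonomy(design$n_genera, seed)
  genes <- build_amr_genes(design$n_amr_genes, tax, seed)
  spike_states <- if (design$spiked) c(FALSE, TRUE) else FALSE

  sheet <- list(); taxa_cols <- list(); amr_cols <- list()
  native_mean <- list(); spiked_contrib <- list()
  expected <- list(); lib_sizes <- c()

  for (mi in seq_along(design$matrices)) {
    mx <- design$matrices[mi]
    mock_mx <- if (mx == "P1") {
      m <- mock; m$cells_per_mg[m$cell_class == "gram_positive"] <-
        m$cells_per_mg[m$cell_class == "gram_positive"] / 2; m
    } else mock
    bl <- simulate_baseline(mx, design$n_genera, seed, taxonomy = tax)
    # taxon deviations per temperature class; frozen temperatures share one
    # draw so -80 and -20 differ only by sampling noise
    dev <- with_seed(mix_seed(seed, 20L + mi), {
      d <- matrix(stats::rnorm(nrow(tax) * 3, 0, model$taxon_effect_sd),
                  ncol = 3, dimnames = list(tax$feature_id,
                                            c("frozen", "5", "22")))
      d
    })
    dev_for <- function(temp) {
      if (temp < 0) dev[, "frozen"] else dev[, as.character(temp)]
    }
    amr_scale_ref <- bl$profile * design$library_size
    mu_ref <- sum(amr_scale_ref[genes$host_genus] * genes$copy_factor *
                    (genes$length_bp / 1000))
    amr_scale <- 0.1 * design$library_size / mu_ref

    cells <- data.frame(temperature_C = NA_real_, time_h = 0, ft = 0)
    for (tm in design$temperatures) {
      for (ti in setdiff(design$times, 0)) {
        cells <- rbind(cells, data.frame(temperature_C = tm, time_h = ti, ft = 0))
      }
    }
    if (mx %in% design$freeze_thaw_matrices) {
      ft_times <- c(40, 64, 88)[seq_along(design$freeze_thaw_cycles)]
      for (tm in design$freeze_thaw_temperatures) {
        for (ci in seq_along(design$freeze_thaw_cycles)) {
          cells <- rbind(cells, data.frame(temperature_C = tm,
                                           time_h = ft_times[ci],
                                           ft = design$freeze_thaw_cycles[ci]))
        }
      }
    }

    for (ci in seq_len(nrow(cells))) {
      cond <- list(temperature_C = cells$temperature_C[ci],
                   time_h = cells$time_h[ci],
                   freeze_thaw_cycles = cells$ft[ci])
      td <- if (cells$time_h[ci] == 0) NULL else dev_for(cond$temperature_C)
      prof <- apply_storage_effect(bl, cond, model, taxon_dev = td)
      cond_key <- sprintf("%s|%s", mx, condition_label(
        data.frame(temperature_C = cond$temperature_C, time_h = cond$time_h,
                   freeze_thaw_cycles = cond$freeze_thaw_cycles)))
      expected[[cond_key]] <- prof
      for (sp in spike_states) {
        for (rep_i in seq_len(design$replicates)) {
          sid <- sprintf("%s_%s_r%d_%s", mx,
                         gsub("-", "m", condition_label(
                           data.frame(temperature_C = cond$temperature_C,
                                      time_h = cond$time_h,
                                      freeze_thaw_cycles = cond$freeze_thaw_cycles))),
                         rep_i, if (sp) "spiked" else "unspiked")
          cell_seed <- mix_seed(seed, 10000L * mi + 100L * ci +
                                  10L * rep_i + as.integer(sp))
          lib <- with_seed(mix_seed(cell_seed, 1L),
                           stats::rlnorm(1, log(design$library_size),
                                         model$library_size_lognormal_sd))
          mu_native <- prof * lib
          contrib <- stats::setNames(numeric(length(prof)), names(prof))
          mu <- mu_native
          if (sp) {
            spk <- spike_mock(mu_native, mock_mx, design$spike_fraction)
            mu <- spk$mean
            contrib <- spk$contribution
          }
          counts <- sample_counts(mu / sum(mu), sum(mu),
                                  model$nb_dispersion,
                                  seed = mix_seed(cell_seed, 2L))
          amr <- simulate_amr(counts, genes, scale = amr_scale,
                              nb_dispersion = model$nb_dispersion,
                              seed = mix_seed(cell_seed, 3L))
          sheet[[sid]] <- data.frame(
            sample_id = sid, matrix = mx,
            temperature_C = cond$temperature_C, time_h = cond$time_h,
            replicate = rep_i, spiked = sp,
            freeze_thaw_cycles = cond$freeze_thaw_cycles,
            stringsAsFactors = FALSE)
          taxa_cols[[sid]] <- counts
          amr_cols[[sid]] <- amr
          native_mean[[sid]] <- mu_native
          spiked_contrib[[sid]] <- contrib
          lib_sizes[sid] <- lib
        }
      }
    }
  }

  taxa <- do.call(cbind, taxa_cols)
  amr <- do.call(cbind, amr_cols)
  rownames(taxa) <- tax$feature_id
  rownames(amr) <- genes$gene
  sheet <- do.call(rbind, sheet)
  rownames(sheet) <- NULL
  taxa_meta <- data.frame(feature_id = tax$feature_id, genus = tax$genus,
                          phylum = tax$phylum, domain = tax$domain,
                          genome_size_bp = tax$genome_size_bp,
                          stringsAsFactors = FALSE)
  list(taxa = taxa, amr = amr, sheet = sheet,
       taxa_meta = taxa_meta, gene_meta = genes,
       truth = list(expected_profiles = expected,
                    native_mean = do.call(cbind, native_mean),
                    spike_contribution = do.call(cbind, spiked_contrib),
                    library_sizes = lib_sizes,
                    effect_model = model, design = design, seed = seed))
}

#' Write a generated dataset as TSV tables
#'
#' @param ds result of [generate_dataset()].
#' @param outdir output directory (created if missing).
#' @return invisibly, the written paths.
#' @export
write_dataset <- function(ds, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(taxa = file.path(outdir, "taxa_counts.tsv"),
             amr = file.path(outdir, "amr_counts.tsv"),
             sheet = file.path(outdir, "sample_sheet.tsv"),
             taxa_meta = file.path(outdir, "taxa_meta.tsv"),
             gene_meta = file.path(outdir, "gene_meta.tsv"))
  write_count_table(ds$taxa, paths["taxa"], id_column = "genus")
  write_count_table(ds$amr, paths["amr"], id_column = "gene")
  for (nm in c("sheet", "taxa_meta", "gene_meta")) {
    utils::write.table(ds[[nm]], paths[nm], sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(paths)
}
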