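test_that("baseline profiles are deterministic, closed, and matrix-distinct", {
  a <- simulate_baseline("P1", 200, seed = 1)
  b <- simulate_baseline("P1", 200, seed = 1)
  expect_identical(a, b)
  expect_equal(sum(a$profile), 1, tolerance = 1e-12)
  p2 <- simulate_baseline("P2", 200, seed = 1)
  bc <- sum(abs(a$profile - p2$profile)) / sum(a$profile + p2$profile)
  expect_gt(bc, 0)
  # same-type matrices resemble each other more than cross-type ones
  s1 <- simulate_baseline("S1", 200, seed = 1)
  bc_ps <- sum(abs(a$profile - s1$profile)) / sum(a$profile + s1$profile)
  expect_gt(bc_ps, bc)
  expect_error(simulate_baseline("P1", 10), "n_genera")
})

test_that("storage effects follow the planted log2 formula and vanish at 0 h", {
  bl <- simulate_baseline("P1", 50, seed = 3)
  em <- effect_model()
  expect_identical(apply_storage_effect(bl, list(temperature_C = 22, time_h = 0), em),
                   bl$profile)
  # direct evaluation: at 22C / 64 h with zero taxon deviation, every
  # taxon's pre-closure log2 abundance shifts by its phylum rate
  cond <- list(temperature_C = 22, time_h = 64)
  prof <- apply_storage_effect(bl, cond, em, taxon_dev = rep(0, 50))
  eff <- em$phylum_effects[bl$feature_meta$phylum, "22"]
  expected <- 2^(bl$log2_abundance + eff)
  expect_equal(prof, expected / sum(expected), tolerance = 1e-12)
  expect_equal(sum(prof), 1, tolerance = 1e-12)
  # both frozen temperatures share one effect vector
  pm80 <- apply_storage_effect(bl, list(temperature_C = -80, time_h = 64), em,
                               taxon_dev = rep(0, 50))
  pm20 <- apply_storage_effect(bl, list(temperature_C = -20, time_h = 64), em,
                               taxon_dev = rep(0, 50))
  expect_identical(pm80, pm20)
  expect_error(apply_storage_effect(bl, list(temperature_C = 37, time_h = 16), em),
               "unknown temperature")
})

test_that("warm-favored taxa gain expected abundance monotonically in time at 22C", {
  bl <- simulate_baseline("S1", 60, seed = 5)
  em <- effect_model()
  warm <- bl$feature_meta$phylum %in% c("Firmicutes", "Actinobacteria")
  profs <- sapply(c(0, 16, 64), function(t) {
    apply_storage_effect(bl, list(temperature_C = 22, time_h = t), em,
                         taxon_dev = rep(0, 60))
  })
  gains <- t(apply(profs[warm, ], 1, diff))
  expect_true(all(gains >= -1e-15))
})

test_that("count sampling has the right moments and degenerate limits", {
  prof <- rep(1 / 10, 10)
  names(prof) <- paste0("g", 1:10)
  k <- sample_counts(prof, 1e4 * 10, nb_dispersion = 0, seed = 8)
  # Poisson mean 1e4 per taxon over 10 draws: within 5 SE
  expect_lt(abs(mean(k) - 1e4), 5 * sqrt(1e4 / 10))
  expect_identical(sample_counts(prof, 500, 0.1, seed = 2),
                   sample_counts(prof, 500, 0.1, seed = 2))
  expect_error(sample_counts(prof, 0), "library_size")
  expect_error(sample_counts(prof, 100, -0.1), "dispersion")
})

test_that("mock spiking is additive on means with proportional contributions", {
  bl <- simulate_baseline("P2", 40, seed = 9)
  native <- bl$profile * 2e4
  spk <- spike_mock(native, mock_spec(), spike_fraction = 0.1)
  expect_equal(spk$mean, native + spk$contribution)
  expect_equal(sum(spk$contribution), 0.1 * sum(native), tolerance = 1e-9)
  expect_true(all(spk$contribution >= 0))
  expect_identical(spike_mock(native, mock_spec(), 0)$mean, native)
  # two members with equal cells and efficiency but genome sizes 2:1
  # receive planted reads 2:1 (Escherichia ~5.1 Mb vs Fusobacterium 2.2 Mb,
  # both Gram-negative with 1e8 cells/mg)
  ms <- mock_spec()
  ratio <- spk$contribution["Escherichia"] / spk$contribution["Fusobacterium"]
  expect_equal(unname(ratio), 5.1 / 2.2, tolerance = 1e-9)
  bad <- native[setdiff(names(native), "Salmonella")]
  expect_error(spike_mock(bad, mock_spec()), "Salmonella")
})

test_that("amr simulation is proportional to host counts and seeded", {
  tax <- storagefx:::build_taxonomy(40, seed = 2)
  genes <- build_amr_genes(25, tax, seed = 2)
  hosts <- setNames(rep(100, 40), tax$feature_id)
  a <- simulate_amr(hosts, genes, scale = 1, nb_dispersion = 0, seed = 4)
  b <- simulate_amr(hosts * 2, genes, scale = 1, nb_dispersion = 0, seed = 4)
  expect_identical(a, simulate_amr(hosts, genes, scale = 1, nb_dispersion = 0, seed = 4))
  # doubling every host roughly doubles totals (Poisson noise only)
  expect_equal(sum(b) / sum(a), 2, tolerance = 0.05)
  # absent host -> zero mean
  hosts0 <- hosts; hosts0[genes$host_genus[1]] <- 0
  z <- simulate_amr(hosts0, genes, scale = 1, nb_dispersion = 0, seed = 4)
  expect_equal(unname(z[genes$gene[genes$host_genus == genes$host_genus[1]]]),
               rep(0, sum(genes$host_genus == genes$host_genus[1])))
  genes_bad <- genes; genes_bad$host_genus[1] <- "NoSuchGenus"
  expect_error(simulate_amr(hosts, genes_bad, 1), "unknown taxon")
})

test_that("the default design enumerates 108 unspiked samples and doubles when spiked", {
  des <- design_spec(freeze_thaw_cycles = NULL, spiked = FALSE,
                     n_genera = 30, n_amr_genes = 20, library_size = 5e3)
  ds <- generate_dataset(des, seed = 3)
  expect_equal(ncol(ds$taxa), 4 * (1 + 4 * 2) * 3)  # 108
  des2 <- design_spec(freeze_thaw_cycles = NULL, spiked = TRUE,
                      n_genera = 30, n_amr_genes = 20, library_size = 5e3)
  ds2 <- generate_dataset(des2, seed = 3)
  expect_equal(ncol(ds2$taxa), 216)
  expect_setequal(colnames(ds2$taxa), ds2$sheet$sample_id)
  expect_equal(anyDuplicated(ds2$sheet$sample_id), 0)
})

test_that("generated datasets are byte-identical under a fixed seed", {
  a <- generate_dataset(small_design(), seed = 21)
  b <- generate_dataset(small_design(), seed = 21)
  expect_identical(a$taxa, b$taxa)
  expect_identical(a$amr, b$amr)
  expect_identical(a$truth$spike_contribution, b$truth$spike_contribution)
  c_ <- generate_dataset(small_design(), seed = 22)
  expect_false(identical(a$taxa, c_$taxa))
})

test_that("spiked means decompose exactly into native mean plus planted spike", {
  ds <- small_ds
  sp <- ds$sheet$sample_id[ds$sheet$spiked]
  expected_profile_total <- colSums(ds$truth$native_mean[, sp]) +
    colSums(ds$truth$spike_contribution[, sp])
  # spike contributions are 10% of the native library by design
  expect_equal(colSums(ds$truth$spike_contribution[, sp]) /
                 colSums(ds$truth$native_mean[, sp]),
               rep(0.1, length(sp)), ignore_attr = TRUE, tolerance = 1e-9)
  un <- ds$sheet$sample_id[!ds$sheet$spiked]
  expect_true(all(ds$truth$spike_contribution[, un] == 0))
})

test_that("expected profiles in the ground truth are closed and keyed", {
  ds <- small_ds
  sums <- vapply(ds$truth$expected_profiles, sum, numeric(1))
  expect_equal(unname(sums), rep(1, length(sums)), tolerance = 1e-12)
  expect_true(all(grepl("^(P1|S1)\\|", names(ds$truth$expected_profiles))))
})

test_that("design and model validation reject inconsistent settings", {
  expect_error(design_spec(replicates = 1), "replicates")
  expect_error(design_spec(times = c(0, 0, 16)), "exactly once")
  expect_error(design_spec(freeze_thaw_temperatures = c(5),
                           freeze_thaw_cycles = c(2, 3)), "frozen")
  pe <- default_phylum_effects()
  pe["Firmicutes", "22"] <- -1
  expect_error(effect_model(phylum_effects = pe), "positive")
  expect_error(effect_model(nb_dispersion = -1), "nb_dispersion")
})

test_that("dataset TSVs round-trip and a YAML config drives the simulator", {
  dir <- withr::local_tempdir()
  write_dataset(small_ds, dir)
  taxa <- read_count_table(file.path(dir, "taxa_counts.tsv"))
  expect_equal(taxa, small_ds$taxa)
  cfg <- file.path(dir, "cfg.yaml")
  writeLines(c("design:", "  matrices: [P1]", "  n_genera: 25",
               "  n_amr_genes: 20", "  library_size: 5000",
               "  freeze_thaw_cycles: ~", "seed: 4"), cfg)
  ds <- simulate_from_config(cfg, outdir = file.path(dir, "out"))
  expect_true(file.exists(file.path(dir, "out", "config_echo.yaml")))
  expect_equal(ncol(ds$taxa), 2 * (1 + 8) * 3)  # spiked + unspiked
  writeLines(c("nonsense: 1"), cfg)
  expect_error(simulate_from_config(cfg), "unknown config key")
})
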