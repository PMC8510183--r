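test_that("permanova matches vegan's adonis2 partition on random fixtures", {
  skip_if_not_installed("vegan")
  for (i in 1:5) {
    r <- random_count_table(15, 18, seed = 400 + i, lambda = 20)
    d <- bray_curtis(r)
    g <- factor(rep(c("a", "b", "c"), each = 6))
    mine <- permanova(d, g, n_permutations = 99, seed = 1)
    ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
    expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
    expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)
  }
})

test_that("permanova is invariant to sample reordering and flat under no signal", {
  r <- random_count_table(10, 12, seed = 409)
  d <- bray_curtis(r)
  g <- factor(rep(c("a", "b"), each = 6))
  ord <- sample(12)
  a <- permanova(d, g, 99, seed = 2)
  b <- permanova(d[ord, ord], g[ord], 99, seed = 2)
  expect_equal(a$pseudo_F, b$pseudo_F, tolerance = 1e-12)
  # duplicated points in both groups: zero between-group signal
  pts <- random_count_table(8, 3, seed = 410)
  dup <- cbind(pts, pts)
  colnames(dup) <- paste0("s", 1:6)
  dd <- bray_curtis(dup)
  res <- permanova(dd, factor(rep(c("a", "b"), each = 3)), 199, seed = 3)
  expect_lt(res$pseudo_F, 1e-10)
  expect_equal(res$p_value, 1, tolerance = 0.01)
  expect_error(permanova(dd, factor(c("a", rep("b", 5))), 99, 1), "singleton")
})

test_that("permanova permutation p matches exhaustive enumeration at N = 6", {
  fx <- euclidean_fixture(6, 2, seed = 421)
  d <- fx$d
  g <- factor(rep(c("a", "b"), each = 3))
  est <- permanova(d, g, n_permutations = 1999, seed = 7)
  # exhaustive: every reassignment of 3 of 6 samples to group 'a'
  combos <- combn(6, 3)
  f_all <- apply(combos, 2, function(idx) {
    gg <- factor(ifelse(seq_len(6) %in% idx, "a", "b"))
    permanova(d, gg, n_permutations = 1, seed = 1)$pseudo_F
  })
  p_exact <- mean(f_all >= est$pseudo_F - 1e-12)
  expect_equal(est$p_value, p_exact, tolerance = 0.05)
})

test_that("betadisper distances match vegan centroids and detect spread differences", {
  skip_if_not_installed("vegan")
  r <- random_count_table(15, 16, seed = 431, lambda = 25)
  d <- bray_curtis(r)
  g <- factor(rep(c("a", "b"), each = 8))
  mine <- betadisper_test(d, g, n_permutations = 199, seed = 1)
  ref <- vegan::betadisper(as.dist(d), g, type = "centroid")
  expect_equal(unname(mine$distances), unname(ref$distances), tolerance = 1e-10)
  # mirror-image clusters: identical dispersion, p near 1
  set.seed(432)
  pts <- matrix(rnorm(20), 10, 2)
  mirror <- rbind(pts, -pts)
  rownames(mirror) <- paste0("s", 1:20)
  dm <- as.matrix(dist(mirror))
  sym <- betadisper_test(dm, factor(rep(c("a", "b"), each = 10)), 199, seed = 2)
  expect_gt(sym$p_value, 0.5)
  expect_true(all(sym$distances >= 0))
})

test_that("betadisper has power against a tight-vs-diffuse pair of clusters", {
  hits <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    tight <- matrix(rnorm(20, sd = 0.2), 10, 2)
    diffuse <- matrix(rnorm(20, sd = 2.0), 10, 2)
    pts <- rbind(tight, diffuse)
    rownames(pts) <- paste0("s", 1:20)
    d <- as.matrix(dist(pts))
    betadisper_test(d, factor(rep(c("t", "d"), each = 10)), 199,
                    seed = s)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("kruskal-wallis H matches the hand rank formula and dunn flags separated groups", {
  vals <- c(1, 2, 3, 4, 5, 6)
  g <- factor(rep(c("a", "b", "c"), each = 2))
  res <- dissimilarity_groups(vals, g, kw_alpha = 1)  # force post hoc
  n <- 6
  rbar <- tapply(rank(vals), g, mean)
  h_hand <- (12 / (n * (n + 1))) * sum(2 * rbar^2) - 3 * (n + 1)
  expect_equal(res$kruskal_H, h_hand, tolerance = 1e-10)
  # disjoint ranges
  v2 <- c(1:6, 101:106)
  g2 <- factor(rep(c("lo", "hi"), each = 6))
  r2 <- dissimilarity_groups(v2, g2)
  expect_lt(r2$kruskal_p, 0.01)
  expect_true(all(r2$dunn$p_adjusted < 0.05))
  expect_warning(
    dissimilarity_groups(c(v2, 5), factor(c(as.character(g2), "solo"))),
    "excluding")
})

test_that("dunn z statistics agree with the tie-corrected formula", {
  set.seed(441)
  vals <- c(rnorm(6), rnorm(6, 2), rnorm(5, 4))
  g <- factor(rep(c("a", "b", "c"), c(6, 6, 5)))
  dt <- dunn_test(vals, g)
  r <- rank(vals); n <- length(vals)
  z_ab <- (mean(r[g == "a"]) - mean(r[g == "b"])) /
    sqrt((n * (n + 1) / 12) * (1 / 6 + 1 / 6))
  expect_equal(dt$z[dt$group_a == "a" & dt$group_b == "b"], z_ab,
               tolerance = 1e-10)
  expect_equal(dt$p_adjusted, p.adjust(dt$p, "holm"))
})

test_that("pair groups partition pairs into replicate / matrix / between classes", {
  ids <- small_ds$sheet$sample_id[!small_ds$sheet$spiked]
  d <- bray_curtis(hellinger(small_ds$taxa[, ids]))
  sh <- small_ds$sheet[match(ids, small_ds$sheet$sample_id), ]
  pg <- pair_dissimilarity_groups(d, sh)
  expect_equal(nrow(pg), choose(length(ids), 2))
  expect_true(all(table(pg$group) > 0))
  # replicate pairs should be the most similar class on average
  m <- tapply(pg$value, pg$group, mean)
  expect_true(m["within_replicate"] < m["within_matrix"])
  expect_true(m["within_matrix"] < m["between_matrix"])
})

test_that("the 0 h row of the baseline table equals within-replicate distances", {
  ids <- small_ds$sheet$sample_id[!small_ds$sheet$spiked &
                                    small_ds$sheet$matrix == "P1"]
  d <- bray_curtis(hellinger(small_ds$taxa[, ids]))
  sh <- small_ds$sheet[match(ids, small_ds$sheet$sample_id), ]
  tb <- dissimilarity_to_baseline(d, sh)
  zero <- ids[sh$time_h == 0]
  hand <- mean(d[zero, zero][lower.tri(d[zero, zero])])
  expect_equal(tb$mean_dissimilarity[tb$condition == "0 h"], hand,
               tolerance = 1e-12)
  expect_equal(tb$n_pairs[tb$condition == "0 h"], 3)
  expect_true(all(tb$n_pairs[tb$condition != "0 h"] == 9))
  # stored replicates identical to 0 h replicates -> mean 0
  zd <- matrix(0, 6, 6, dimnames = list(paste0("x", 1:6), paste0("x", 1:6)))
  zsh <- data.frame(sample_id = paste0("x", 1:6), matrix = "M",
                    temperature_C = rep(c(NA, 22), each = 3),
                    time_h = rep(c(0, 64), each = 3), replicate = rep(1:3, 2),
                    spiked = FALSE, freeze_thaw_cycles = 0)
  ztb <- dissimilarity_to_baseline(zd, zsh)
  expect_equal(ztb$mean_dissimilarity, c(0, 0))
  expect_error(dissimilarity_to_baseline(zd[4:6, 4:6], zsh[4:6, ]), "0 h")
})

test_that("custom size factors are totals over their mean", {
  m <- cbind(s1 = c(40, 60), s2 = c(100, 200))
  rownames(m) <- c("a", "b")
  expect_equal(custom_size_factors(m), c(s1 = 0.5, s2 = 1.5))
  r <- random_count_table(20, 7, seed = 451)
  expect_equal(mean(custom_size_factors(r)), 1, tolerance = 1e-12)
  m0 <- cbind(s1 = c(0, 0), s2 = c(1, 1)); rownames(m0) <- c("a", "b")
  expect_error(custom_size_factors(m0), "s1")
})

test_that("nb wald test is null on identical groups and recovers planted effects", {
  m <- matrix(50, 20, 6, dimnames = list(paste0("t", 1:20), paste0("s", 1:6)))
  g <- factor(rep(c("a", "b"), each = 3))
  res <- nb_wald_test(m, g, size_factors = rep(1, 6))
  expect_equal(res$log2_fold_change, rep(0, 20), tolerance = 1e-8)
  expect_true(all(res$p > 0.9))
  # parameter recovery: planted LFC = 1, dispersion 0.05
  set.seed(461)
  n <- 200
  q <- rlnorm(n, log(100), 1)
  mu <- outer(q, c(1, 1, 1, 2, 2, 2))
  k <- matrix(rnbinom(n * 6, mu = mu, size = 1 / 0.05), n,
              dimnames = list(paste0("t", 1:n), paste0("s", 1:6)))
  r2 <- nb_wald_test(k, g, size_factors = rep(1, 6))
  expect_gt(mean(r2$log2_fold_change), 0.8)
  expect_lt(mean(r2$log2_fold_change), 1.2)
  # all-zero taxa are excluded and reported
  k0 <- rbind(k, zero = 0)
  r3 <- nb_wald_test(k0, g, size_factors = rep(1, 6))
  expect_equal(attr(r3, "excluded"), "zero")
  expect_error(nb_wald_test(k, factor(rep("a", 6))), "2 condition")
})

test_that("nb wald LFC signs track strong planted effects", {
  set.seed(471)
  n <- 150
  q <- rlnorm(n, log(200), 0.7)
  sign_truth <- sample(c(-1, 1), n, replace = TRUE)
  mu <- outer(q, rep(1, 6))
  mu[, 4:6] <- mu[, 4:6] * 2^(2 * sign_truth)   # |LFC| = 2
  k <- matrix(rnbinom(n * 6, mu = mu, size = 1 / 0.05), n,
              dimnames = list(paste0("t", 1:n), paste0("s", 1:6)))
  r <- nb_wald_test(k, factor(rep(c("a", "b"), each = 3)),
                    size_factors = rep(1, 6))
  strong <- r$base_mean >= 50
  agree <- sign(r$log2_fold_change[strong]) == sign_truth[strong]
  expect_gte(mean(agree), 0.95)
})

test_that("significance counts are bounded and track planted single-condition effects", {
  res <- data.frame(taxon = rep(c("t1", "t2"), each = 3),
                    group_a = rep(c("A", "A", "B"), 2),
                    group_b = rep(c("B", "C", "C"), 2),
                    significant = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  sc <- significance_counts(res)
  expect_equal(sc$n_significant[sc$taxon == "t1" & sc$condition == "A"], 2)
  expect_equal(sc$n_significant[sc$taxon == "t1" & sc$condition == "B"], 1)
  expect_true(all(sc$n_significant[sc$taxon == "t2"] == 0))
  expect_true(all(sc$n_significant <= 2))
})
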