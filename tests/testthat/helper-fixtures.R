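# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

random_count_table <- function(n_features, n_samples, seed, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_features * n_samples, lambda), n_features, n_samples)
  dimnames(m) <- list(sprintf("f%02d", seq_len(n_features)),
                      sprintf("s%02d", seq_len(n_samples)))
  m
}

# A small two-matrix dataset reused across module tests (built once).
small_design <- function() {
  design_spec(matrices = c("P1", "S1"), n_genera = 40, n_amr_genes = 30,
              library_size = 2e4, freeze_thaw_cycles = NULL)
}

small_ds <- generate_dataset(small_design(), seed = 11)

# Points in Euclidean space with labelled distance matrix, for PCoA
# oracles.
euclidean_fixture <- function(n, k, seed) {
  set.seed(seed)
  pts <- matrix(rnorm(n * k), n, k)
  rownames(pts) <- sprintf("s%02d", seq_len(n))
  list(points = pts, d = as.matrix(dist(pts)))
}

# O(n^3) agglomerative complete-linkage clustering, independent of
# stats::hclust, as a brute-force oracle for merge heights.
naive_complete_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(j, i) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
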