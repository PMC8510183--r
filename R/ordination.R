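#' Ordination and dissimilarity geometry
#'
#' Beta-diversity workflow: Hellinger transformation, Bray-Curtis
#' dissimilarities, principal-coordinates analysis with stress diagnostics,
#' constrained correspondence analysis on raw counts (chi-square metric),
#' symmetric Procrustes comparison of ordinations with a permutation test,
#' and the clustering supports used for heat maps.
#'
#' Distance matrices are represented as labelled symmetric numeric matrices
#' with a zero diagonal.
#'
#' @name ordination
NULL

#' Hellinger transformation
#'
#' entry <- sqrt(count / sample total), so squared entries sum to 1 per
#' sample. Downweights dominant taxa before Bray-Curtis or Euclidean
#' geometry.
#'
#' @param x count table (features x samples), nonnegative.
#' @return transformed table.
#' @export
hellinger <- function(x) {
  validate_count_table(x)
  totals <- colSums(x)
  zero <- totals == 0
  if (any(zero)) {
    warning("all-zero sample(s) left as zeros: ",
            paste(colnames(x)[zero], collapse = ", "), call. = FALSE)
    totals[zero] <- 1
  }
  sqrt(sweep(x, 2, totals, "/"))
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i) over sample pairs
#' (columns). A pair of all-zero samples has an undefined dissimilarity
#' (NA, with a warning).
#'
#' @param x feature x sample table, nonnegative.
#' @return symmetric sample x sample matrix, zero diagonal, entries in
#'   [0, 1].
#' @export
bray_curtis <- function(x) {
  validate_count_table(x)
  num <- as.matrix(stats::dist(t(x), method = "manhattan"))
  totals <- colSums(x)
  den <- outer(totals, totals, "+")
  d <- num / den
  diag(d) <- 0
  if (any(!is.finite(d))) {
    warning("pair(s) of all-zero samples: dissimilarity undefined (NA)",
            call. = FALSE)
    d[!is.finite(d)] <- NA_real_
    diag(d) <- 0
  }
  dimnames(d) <- list(colnames(x), colnames(x))
  d
}

#' Principal-coordinates analysis (classical MDS)
#'
#' Gower double-centering of -d^2/2 followed by a symmetric
#' eigendecomposition. Coordinates use the positive eigenvalues only
#' (scaled eigenvectors); negative eigenvalues are reported but excluded
#' from coordinates (no Cailliez/Lingoes correction).
#'
#' @param d symmetric labelled distance matrix.
#' @param eps eigenvalues within `eps * max(|lambda|)` of zero are dropped.
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all, in
#'   non-increasing order), `variance_explained` (positive axes, fraction of
#'   the positive-eigenvalue sum), and `trace`.
#' @export
pcoa <- function(d, eps = 1e-9) {
  d <- check_distance_matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  b <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  lambda <- e$values
  tol <- eps * max(abs(lambda), 1e-300)
  pos <- which(lambda > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda[pos]), length(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  list(coordinates = coords,
       eigenvalues = lambda,
       variance_explained = lambda[pos] / sum(lambda[pos]),
       trace = sum(diag(b)))
}

#' Stress data: original vs ordination distances
#'
#' Pairs each original dissimilarity with the Euclidean distance in the
#' first `k` ordination axes, plus a Spearman rank correlation summarizing
#' the monotone association (the ordination's goodness of fit).
#'
#' @param d original distance matrix.
#' @param ordination result of [pcoa()].
#' @param k number of axes (default all).
#' @return list with `pairs` (data.frame: original, ordinated) and
#'   `rank_correlation` (NA when fewer than 3 pairs).
#' @export
stress_data <- function(d, ordination, k = NULL) {
  d <- check_distance_matrix(d)
  coords <- ordination$coordinates
  k <- min(k %||% ncol(coords), ncol(coords))
  od <- as.matrix(stats::dist(coords[, seq_len(k), drop = FALSE]))
  idx <- lower.tri(d)
  pairs <- data.frame(original = d[idx], ordinated = od[idx])
  rc <- if (nrow(pairs) >= 3) {
    suppressWarnings(stats::cor(pairs$original, pairs$ordinated, method = "spearman"))
  } else NA_real_
  list(pairs = pairs, rank_correlation = rc)
}

#' Constrained correspondence analysis
#'
#' Chi-square standardized residuals Q = (P - r c') / sqrt(r c') of the
#' relative count table P are projected onto the (row-weighted) space
#' spanned by a condition factor; the singular value decomposition of the
#' projected matrix gives the constrained axes. Total inertia is sum(Q^2)
#' (the chi-square statistic over the grand total); the constrained
#' fraction is the share explained by the factor. Raw counts are the
#' appropriate input: the chi-square metric has its own internal weighting.
#'
#' @param x raw count table (features x samples).
#' @param condition factor (length = number of samples) with >= 2 levels.
#' @param eps relative tolerance for dropping null axes.
#' @return list with `site_scores` (linear-combination scores, samples x
#'   axes), `site_scores_wa` (weighted-average scores), `feature_scores`,
#'   `level_centroids`, `eigenvalues`, `total_inertia`,
#'   `constrained_inertia`, `constrained_fraction`.
#' @export
cca_constrained <- function(x, condition, eps = 1e-9) {
  validate_count_table(x)
  condition <- as.factor(condition)
  if (length(condition) != ncol(x)) {
    stop("condition factor must have one value per sample", call. = FALSE)
  }
  if (nlevels(droplevels(condition)) < 2) {
    stop("condition factor must have >= 2 levels", call. = FALSE)
  }
  keep_f <- rowSums(x) > 0
  keep_s <- colSums(x) > 0
  if (!all(keep_f) || !all(keep_s)) {
    warning("dropping zero-sum rows/columns from the chi-square analysis",
            call. = FALSE)
    x <- x[keep_f, keep_s, drop = FALSE]
    condition <- droplevels(condition[keep_s])
  }
  y <- t(x)                             # samples x features
  p <- y / sum(y)
  r <- rowSums(p)
  cc <- colSums(p)
  q <- (p - outer(r, cc)) / sqrt(outer(r, cc))
  total_inertia <- sum(q^2)

  z <- stats::model.matrix(~condition)[, -1, drop = FALSE]
  z <- sweep(z, 2, colSums(r * z))      # weighted centering (sum(r) = 1)
  zw <- sqrt(r) * z
  qrz <- qr(zw)
  qhat <- qr.fitted(qrz, q)
  s <- svd(qhat)
  tol <- eps * max(s$d, 1e-300)
  k <- which(s$d > tol)
  lambda <- s$d[k]^2

  sites_lc <- (1 / sqrt(r)) * qhat %*% s$v[, k, drop = FALSE]
  sites_wa <- (1 / sqrt(r)) * q %*% s$v[, k, drop = FALSE]
  feats <- (1 / sqrt(cc)) * t(q) %*% s$u[, k, drop = FALSE]
  axis_names <- paste0("CCA", seq_along(k))
  dimnames(sites_lc) <- list(rownames(y), axis_names)
  dimnames(sites_wa) <- list(rownames(y), axis_names)
  dimnames(feats) <- list(colnames(y), axis_names)
  centroids <- apply(sites_lc, 2, function(v) {
    tapply(r * v, condition, sum) / tapply(r, condition, sum)
  })
  centroids <- matrix(centroids, nrow = nlevels(condition),
                      dimnames = list(levels(condition), axis_names))
  list(site_scores = sites_lc,
       site_scores_wa = sites_wa,
       feature_scores = feats,
       level_centroids = centroids,
       eigenvalues = lambda,
       total_inertia = total_inertia,
       constrained_inertia = sum(lambda),
       constrained_fraction = sum(lambda) / total_inertia)
}

#' Symmetric Procrustes comparison with permutation test (protest)
#'
#' Both coordinate sets are column-centered and scaled to unit sum of
#' squares; the optimal rotation comes from the singular value
#' decomposition of the cross-product. The statistic m2 = 1 - (sum of
#' singular values)^2 is the residual sum of squares; correlation =
#' sqrt(1 - m2). Significance is assessed by permuting the sample rows of
#' the second matrix, with add-one smoothing.
#'
#' @param a,b coordinate matrices with identical rownames (sample ids) in
#'   the same order; differing axis counts are zero-padded.
#' @param n_permutations permutation count (default 999).
#' @param seed RNG seed.
#' @return list with `m2`, `correlation`, `p_value`, `n_permutations`.
#' @export
procrustes_protest <- function(a, b, n_permutations = 999, seed = 1) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (is.null(rownames(a)) || is.null(rownames(b)) ||
      !identical(rownames(a), rownames(b))) {
    stop("coordinate matrices must carry identical sample rownames in the same order",
         call. = FALSE)
  }
  k <- max(ncol(a), ncol(b))
  pad <- function(m) cbind(m, matrix(0, nrow(m), k - ncol(m)))
  std <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    ss <- sum(m^2)
    if (ss == 0) stop("degenerate (constant) configuration", call. = FALSE)
    m / sqrt(ss)
  }
  as_ <- std(pad(a))
  bs <- std(pad(b))
  m2_of <- function(bm) {
    d <- svd(crossprod(as_, bm))$d
    max(0, 1 - sum(d)^2)
  }
  m2 <- m2_of(bs)
  perm <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    m2_of(bs[sample(nrow(bs)), , drop = FALSE])
  }, numeric(1)))
  p <- (1 + sum(perm <= m2)) / (1 + n_permutations)
  list(m2 = m2,
       correlation = sqrt(1 - m2),
       p_value = p,
       n_permutations = n_permutations)
}

#' Clustering supports for abundance heat maps
#'
#' Selects the most abundant features (by mean relative abundance),
#' standardizes each selected row to zero mean and unit variance, and
#' builds complete-linkage trees: features on 1 - Pearson correlation,
#' samples on the Bray-Curtis matrix of the full table (or a supplied
#' distance matrix). Linkage ties are resolved deterministically by
#' ordering features and samples lexicographically first.
#'
#' @param x relative-abundance table (features x samples).
#' @param n_top number of features to keep (default 30).
#' @param sample_dist optional precomputed sample distance matrix.
#' @return list with `matrix` (standardized, n_top x samples),
#'   `feature_tree`, `sample_tree` (hclust objects).
#' @export
cluster_supports <- function(x, n_top = 30, sample_dist = NULL) {
  validate_count_table(x)
  rel <- total_sum_scale(x)
  keep <- names(sort(rowMeans(rel), decreasing = TRUE))[seq_len(min(n_top, nrow(rel)))]
  if (length(keep) < 2) stop("fewer than 2 features after selection", call. = FALSE)
  sub <- rel[sort(keep), , drop = FALSE]
  std <- t(scale(t(sub)))
  if (any(!is.finite(std))) {
    stop("constant feature row(s) cannot be standardized: ",
         paste(rownames(sub)[apply(std, 1, function(r) any(!is.finite(r)))],
               collapse = ", "), call. = FALSE)
  }
  fd <- stats::as.dist(1 - stats::cor(t(std)))
  sd_ <- sample_dist %||% bray_curtis(x)
  sd_ <- check_distance_matrix(sd_)
  ord <- order(rownames(sd_))
  list(matrix = std,
       feature_tree = stats::hclust(fd, method = "complete"),
       sample_tree = stats::hclust(stats::as.dist(sd_[ord, ord]), method = "complete"))
}

check_distance_matrix <- function(d, tol = 1e-12) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (max(abs(d - t(d)), na.rm = TRUE) > tol * max(1, max(abs(d), na.rm = TRUE))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal", call. = FALSE)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  }
  d
}
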