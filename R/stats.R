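#' Permutational and count-based statistics
#'
#' PERMANOVA on a dissimilarity matrix with a multivariate-dispersion
#' homogeneity check, nonparametric comparison of dissimilarity groups
#' (Levene, Kruskal-Wallis, Dunn post hoc), the stored-vs-baseline
#' dissimilarity summary, and negative-binomial Wald tests for
#' differential abundance with custom size factors.
#'
#' @name storage-stats
NULL

#' PERMANOVA (one-way) on a distance matrix
#'
#' Partitions squared dissimilarities into between- and within-group sums
#' of squares: SS_total = (1/N) sum_{i<j} d_ij^2, SS_within = sum over
#' groups of (1/n_g) sum_{i<j in g} d_ij^2. The pseudo-F statistic
#' (SS_between/(a-1)) / (SS_within/(N-a)) is referred to its permutation
#' distribution under random relabelling; p uses add-one smoothing.
#'
#' @param d distance matrix.
#' @param group factor with >= 2 groups, each of size >= 2.
#' @param n_permutations permutations (default 999).
#' @param seed RNG seed.
#' @param check_dispersion also run [betadisper_test()] and report its p.
#' @return list with `pseudo_F`, `R2`, `p_value`, `n_permutations`,
#'   `df`, and `betadisper_p` (NA unless requested).
#' @export
permanova <- function(d, group, n_permutations = 999, seed = 1,
                      check_dispersion = FALSE) {
  d <- check_distance_matrix(d)
  group <- droplevels(as.factor(group))
  n <- nrow(d)
  if (length(group) != n) stop("one group label per sample required", call. = FALSE)
  if (nlevels(group) < 2) stop(">= 2 groups required", call. = FALSE)
  if (any(table(group) < 2)) stop("singleton group(s) not allowed", call. = FALSE)
  d2 <- d^2
  a <- nlevels(group)
  ss_total <- sum(d2[lower.tri(d2)]) / n
  f_stat <- function(g) {
    ss_within <- 0
    for (lev in levels(group)) {
      idx <- which(g == lev)
      ss_within <- ss_within +
        sum(d2[idx, idx][lower.tri(d2[idx, idx, drop = FALSE])]) / length(idx)
    }
    ss_between <- ss_total - ss_within
    (ss_between / (a - 1)) / (ss_within / (n - a))
  }
  f_obs <- f_stat(group)
  perm <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    f_stat(group[sample(n)])
  }, numeric(1)))
  p <- (1 + sum(perm >= f_obs)) / (1 + n_permutations)
  ss_within <- ss_total - f_obs * (a - 1) * ss_total / (f_obs * (a - 1) + (n - a))
  r2 <- 1 - ss_within / ss_total
  bd <- if (check_dispersion) {
    betadisper_test(d, group, n_permutations = n_permutations,
                    seed = mix_seed(seed, 77L))$p_value
  } else NA_real_
  list(pseudo_F = f_obs, R2 = r2, p_value = p,
       n_permutations = n_permutations,
       df = c(between = a - 1, within = n - a),
       betadisper_p = bd)
}

#' Homogeneity of multivariate dispersions
#'
#' Embeds the distance matrix by PCoA (keeping imaginary axes), computes
#' each sample's distance to its group centroid — positive-eigenvalue axes
#' add to, negative-eigenvalue axes subtract from, the squared distance —
#' and tests equality of mean distances across groups with an ANOVA F
#' whose null distribution is obtained by permuting group labels. A small
#' p-value indicates heterogeneous dispersions, i.e. a PERMANOVA location
#' effect cannot be cleanly separated from a spread effect.
#'
#' @inheritParams permanova
#' @return list with `F`, `p_value`, `distances` (to own-group centroid),
#'   `group_means`.
#' @export
betadisper_test <- function(d, group, n_permutations = 999, seed = 1) {
  d <- check_distance_matrix(d)
  group <- droplevels(as.factor(group))
  n <- nrow(d)
  if (any(table(group) < 2)) stop("groups of size 1 not allowed", call. = FALSE)
  a <- -0.5 * d^2
  b <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- 1e-9 * max(abs(e$values), 1e-300)
  pos <- e$values > tol
  neg <- e$values < -tol
  up <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  un <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))
  dist_to_centroids <- function(g) {
    out <- numeric(n)
    for (lev in levels(g)) {
      idx <- which(g == lev)
      cp <- colMeans(up[idx, , drop = FALSE])
      cn <- if (ncol(un)) colMeans(un[idx, , drop = FALSE]) else numeric(0)
      d2 <- rowSums(sweep(up[idx, , drop = FALSE], 2, cp)^2)
      if (ncol(un)) d2 <- d2 - rowSums(sweep(un[idx, , drop = FALSE], 2, cn)^2)
      out[idx] <- sqrt(pmax(0, d2))
    }
    out
  }
  f_of <- function(g) {
    z <- dist_to_centroids(g)
    m <- tapply(z, g, mean)
    nG <- tapply(z, g, length)
    ssb <- sum(nG * (m - mean(z))^2)
    ssw <- sum((z - m[g])^2)
    (ssb / (nlevels(g) - 1)) / (ssw / (n - nlevels(g)))
  }
  f_obs <- f_of(group)
  perm <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    f_of(factor(group[sample(n)], levels = levels(group)))
  }, numeric(1)))
  z <- dist_to_centroids(group)
  list(F = f_obs,
       p_value = (1 + sum(perm >= f_obs)) / (1 + n_permutations),
       distances = stats::setNames(z, rownames(d)),
       group_means = tapply(z, group, mean))
}

#' Partition pairwise dissimilarities by sample relationship
#'
#' Classifies every sample pair as `within_replicate` (same matrix and
#' same storage condition), `within_matrix` (same matrix, different
#' condition), or `between_matrix`.
#'
#' @param d distance matrix over samples.
#' @param sheet sample sheet with `sample_id`, `matrix`, `temperature_C`,
#'   `time_h`, `freeze_thaw_cycles`.
#' @return data.frame with `value`, `group`, `sample_a`, `sample_b`.
#' @export
pair_dissimilarity_groups <- function(d, sheet) {
  d <- check_distance_matrix(d)
  ids <- rownames(d)
  m <- sheet$matrix[match(ids, sheet$sample_id)]
  cond <- condition_label(sheet)[match(ids, sheet$sample_id)]
  if (any(is.na(m))) stop("sample(s) missing from sheet", call. = FALSE)
  idx <- which(lower.tri(d), arr.ind = TRUE)
  grp <- ifelse(m[idx[, 1]] != m[idx[, 2]], "between_matrix",
                ifelse(cond[idx[, 1]] == cond[idx[, 2]],
                       "within_replicate", "within_matrix"))
  data.frame(value = d[lower.tri(d)],
             group = factor(grp, levels = c("within_replicate", "within_matrix",
                                            "between_matrix")),
             sample_a = ids[idx[, 1]], sample_b = ids[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Compare groups of dissimilarities
#'
#' Levene's test (on raw and, where positive, log dissimilarities) probes
#' variance homogeneity; a Kruskal-Wallis test assesses the overall group
#' difference; when significant at `kw_alpha`, Dunn's pairwise z tests
#' with Holm adjustment identify the differing pairs.
#'
#' @param values numeric dissimilarities.
#' @param groups factor parallel to `values`.
#' @param kw_alpha gate for the post hoc test (default 0.05).
#' @return list with `levene_p`, `levene_log_p`, `kruskal_p`, `kruskal_H`,
#'   `dunn` (data.frame or NULL).
#' @export
dissimilarity_groups <- function(values, groups, kw_alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  sizes <- table(groups)
  if (any(sizes < 2)) {
    warning("excluding group(s) with < 2 values: ",
            paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
    keep <- groups %in% names(sizes)[sizes >= 2]
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop(">= 2 usable groups required", call. = FALSE)
  lev <- car::leveneTest(values ~ groups)
  pos <- values > 0
  lev_log <- if (sum(pos) > nlevels(groups) &&
                 nlevels(droplevels(groups[pos])) == nlevels(groups)) {
    car::leveneTest(log(values[pos]) ~ droplevels(groups[pos]))[["Pr(>F)"]][1]
  } else NA_real_
  kw <- stats::kruskal.test(values, groups)
  dunn <- if (kw$p.value < kw_alpha) dunn_test(values, groups) else NULL
  list(levene_p = lev[["Pr(>F)"]][1],
       levene_log_p = lev_log,
       kruskal_p = kw$p.value,
       kruskal_H = unname(kw$statistic),
       dunn = dunn)
}

#' Dunn's pairwise rank test
#'
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j)), with
#' the tie correction T = sum(t^3 - t) / (12 (N - 1)); two-sided p-values
#' are Holm-adjusted.
#'
#' @inheritParams dissimilarity_groups
#' @return data.frame with group pair, z, p, p_adjusted.
#' @export
dunn_test <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  r <- rank(values)
  nn <- length(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (nn - 1))
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  z <- apply(pairs, 2, function(pr) {
    (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt((nn * (nn + 1) / 12 - tie_corr) * (1 / ng[pr[1]] + 1 / ng[pr[2]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
             z = as.numeric(z), p = p,
             p_adjusted = stats::p.adjust(p, method = "holm"),
             stringsAsFactors = FALSE)
}

#' Mean dissimilarity of stored samples to the unstored baseline
#'
#' For each sample matrix and each storage condition, the mean and
#' standard error over all pairs between the condition's replicates and
#' the matrix's 0 h replicates (3 x 3 = 9 pairs in the default design).
#' The 0 h row instead summarizes the pairwise dissimilarities among the
#' 0 h replicates themselves, i.e. the replicate-level noise floor.
#' Freeze-thaw samples are excluded.
#'
#' @param d distance matrix.
#' @param sheet sample sheet (see [pair_dissimilarity_groups()]).
#' @return data.frame with matrix, condition, temperature_C, time_h,
#'   mean_dissimilarity, se, n_pairs.
#' @export
dissimilarity_to_baseline <- function(d, sheet) {
  d <- check_distance_matrix(d)
  sheet <- sheet[match(rownames(d), sheet$sample_id), , drop = FALSE]
  if (any(is.na(sheet$sample_id))) stop("sample(s) missing from sheet", call. = FALSE)
  ft <- sheet$freeze_thaw_cycles %||% rep(0, nrow(sheet))
  ft[is.na(ft)] <- 0
  keep <- ft == 0
  out <- list()
  for (mx in unique(sheet$matrix[keep])) {
    base_idx <- which(keep & sheet$matrix == mx & sheet$time_h == 0)
    if (length(base_idx) == 0) {
      stop(sprintf("no 0 h samples for matrix '%s'", mx), call. = FALSE)
    }
    sub <- d[base_idx, base_idx, drop = FALSE]
    vals <- sub[lower.tri(sub)]
    out[[length(out) + 1]] <- data.frame(
      matrix = mx, condition = "0 h", temperature_C = NA_real_, time_h = 0,
      mean_dissimilarity = mean(vals),
      se = stats::sd(vals) / sqrt(length(vals)), n_pairs = length(vals),
      stringsAsFactors = FALSE)
    conds <- unique(sheet[keep & sheet$matrix == mx & sheet$time_h != 0,
                          c("temperature_C", "time_h")])
    if (nrow(conds) > 0) {
      conds <- conds[order(conds$temperature_C, conds$time_h), , drop = FALSE]
    }
    for (i in seq_len(nrow(conds))) {
      idx <- which(keep & sheet$matrix == mx &
                     sheet$temperature_C == conds$temperature_C[i] &
                     sheet$time_h == conds$time_h[i])
      vals <- as.vector(d[idx, base_idx])
      out[[length(out) + 1]] <- data.frame(
        matrix = mx,
        condition = sprintf("%g h, %g°C", conds$time_h[i], conds$temperature_C[i]),
        temperature_C = conds$temperature_C[i], time_h = conds$time_h[i],
        mean_dissimilarity = mean(vals),
        se = stats::sd(vals) / sqrt(length(vals)), n_pairs = length(vals),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Custom size factors from column totals
#'
#' factor_j = total_j / mean(totals); the factors average to 1 by
#' construction. This is the depth-proportional alternative to
#' median-of-ratios size factors.
#'
#' @param x raw count table.
#' @return named numeric vector, one factor per sample.
#' @export
custom_size_factors <- function(x) {
  validate_count_table(x)
  totals <- colSums(x)
  if (any(totals == 0)) {
    stop("zero-total sample(s): ",
         paste(colnames(x)[totals == 0], collapse = ", "), call. = FALSE)
  }
  totals / mean(totals)
}

#' Negative-binomial Wald test for a two-condition comparison
#'
#' Per taxon, fits the model mu_ij = s_j * q_i * 2^(beta_i * x_j) with x
#' the condition indicator and s the supplied size factors, by iteratively
#' reweighted least squares under a negative-binomial variance
#' mu + phi mu^2. The per-taxon dispersion phi is a method-of-moments
#' estimate on size-factor-normalized counts, floored at 1e-8 and
#' moderated against a fitted mean-dispersion trend (a0 + a1/mu) by taking
#' the maximum of the taxon estimate and the trend — a conservative
#' sharing rule that guards the small-replicate case. The Wald statistic
#' beta/SE(beta) is referred to the standard normal.
#'
#' @param x raw count table.
#' @param group two-level factor over samples.
#' @param size_factors per-sample factors (default [custom_size_factors()]).
#' @param alpha significance threshold on p (default 0.01).
#' @return data.frame: taxon, base_mean, log2_fold_change (level 2 vs
#'   level 1), se, wald, p, significant; all-zero taxa are dropped and
#'   listed in attribute "excluded".
#' @export
nb_wald_test <- function(x, group, size_factors = NULL, alpha = 0.01) {
  validate_count_table(x)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("exactly 2 condition levels required", call. = FALSE)
  if (any(table(group) < 2)) stop(">= 2 replicates per condition required", call. = FALSE)
  s <- size_factors %||% custom_size_factors(x)
  xs <- as.numeric(group) - 1
  norm <- sweep(x, 2, s, "/")
  nz <- rowSums(x) > 0
  excluded <- rownames(x)[!nz]
  xm <- x[nz, , drop = FALSE]
  nm <- norm[nz, , drop = FALSE]

  base_mean <- rowMeans(nm)
  phi_hat <- nb_dispersion_mom(nm, group, s)
  phi_trend <- nb_dispersion_trend(base_mean, phi_hat)
  phi <- pmax(phi_hat, phi_trend, 1e-8)

  res <- t(vapply(seq_len(nrow(xm)), function(i) {
    nb_irls_two_group(xm[i, ], s, xs, phi[i])
  }, numeric(3)))
  lfc <- res[, 1] / log(2)
  se <- res[, 2] / log(2)
  wald <- res[, 1] / res[, 2]
  p <- 2 * stats::pnorm(-abs(wald))
  out <- data.frame(taxon = rownames(xm), base_mean = base_mean,
                    log2_fold_change = lfc, se = se, wald = wald, p = p,
                    significant = p < alpha, dispersion = phi,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- excluded
  attr(out, "comparison") <- paste(levels(group)[2], "vs", levels(group)[1])
  out
}

# Method-of-moments dispersion on normalized counts:
# Var(k/s) = q/s + phi q^2 within a group with mean q.
nb_dispersion_mom <- function(nm, group, s) {
  n <- ncol(nm)
  g <- as.integer(group)
  gm <- vapply(split(seq_len(n), g), function(idx) rowMeans(nm[, idx, drop = FALSE]),
               numeric(nrow(nm)))
  fit <- gm[, g, drop = FALSE]
  resid2 <- (nm - fit)^2
  df <- n - nlevels(group)
  v <- rowSums(resid2) / df
  shot <- rowMeans(sweep(fit, 2, s, "/"))   # Poisson part q/s averaged
  q2 <- rowMeans(fit^2)
  pmax((v - shot) / pmax(q2, 1e-300), 1e-8)
}

# Dispersion-mean trend phi(mu) = a0 + a1/mu fitted by regression on taxa
# with informative estimates; coefficients clamped nonnegative.
nb_dispersion_trend <- function(base_mean, phi_hat) {
  use <- phi_hat > 1e-7 & base_mean > 0
  if (sum(use) < 10) return(rep(stats::median(phi_hat), length(phi_hat)))
  co <- stats::coef(stats::lm(phi_hat[use] ~ I(1 / base_mean[use])))
  a0 <- max(co[1], 0); a1 <- max(co[2], 0)
  a0 + a1 / pmax(base_mean, 1e-300)
}

# IRLS for log-link NB with offset log(s) and design (1, x); returns
# c(beta, se_beta, converged) on the natural-log scale.
nb_irls_two_group <- function(k, s, x, phi, max_iter = 50, tol = 1e-10) {
  X <- cbind(1, x)
  m1 <- sum(k[x == 0]) / sum(s[x == 0])
  m2 <- sum(k[x == 1]) / sum(s[x == 1])
  eps <- 0.5 / sum(s)
  beta <- c(log(max(m1, eps)), log(max(m2, eps)) - log(max(m1, eps)))
  for (it in seq_len(max_iter)) {
    eta <- log(s) + X %*% beta
    mu <- pmin(exp(eta), 1e12)
    w <- as.vector(mu / (1 + phi * mu))
    z <- eta - log(s) + (k - mu) / mu
    fit <- stats::lm.wfit(X, as.vector(z), w)
    new_beta <- pmin(pmax(fit$coefficients, -50), 50)
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  eta <- log(s) + X %*% beta
  mu <- pmin(exp(eta), 1e12)
  w <- as.vector(mu / (1 + phi * mu))
  info <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(info + diag(1e-12, 2))))[2]
  c(beta[2], se, it < max_iter)
}

#' Count significant pairwise comparisons per taxon and condition
#'
#' Given the results of all pairwise condition comparisons, counts, for
#' every taxon, how many comparisons involving each condition were
#' significant.
#'
#' @param results data.frame with columns taxon, group_a, group_b,
#'   significant (rbind of [nb_wald_test()] outputs augmented with the two
#'   group labels), or a list of such data.frames.
#' @return data.frame taxon x condition with integer counts (long format:
#'   taxon, condition, n_significant).
#' @export
significance_counts <- function(results) {
  if (is.data.frame(results)) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    r[, c("taxon", "group_a", "group_b", "significant")]
  }))
  conds <- sort(unique(c(df$group_a, df$group_b)))
  taxa <- sort(unique(df$taxon))
  out <- expand.grid(taxon = taxa, condition = conds,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_significant <- mapply(function(tx, cd) {
    sum(df$significant & df$taxon == tx & (df$group_a == cd | df$group_b == cd))
  }, out$taxon, out$condition)
  out
}
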