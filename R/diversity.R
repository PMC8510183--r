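#' Alpha diversity and rarefaction
#'
#' Richness (bias-corrected Chao1), Shannon entropy with Pielou's evenness,
#' Simpson diversity, and rarefaction curves. All alpha indices are defined
#' on raw (integer) counts: Chao1 depends on singleton/doubleton counts and
#' rarefaction subsamples reads, so normalized tables are rejected where it
#' matters.
#'
#' @name diversity
NULL

#' Bias-corrected Chao1 richness estimate
#'
#' S_obs + F1 (F1 - 1) / (2 (F2 + 1)), where F1 and F2 are the numbers of
#' singleton and doubleton features. The bias-corrected form remains finite
#' when no doubletons are observed.
#'
#' @param counts integer count vector for one sample.
#' @return estimated richness (>= observed richness).
#' @export
chao1 <- function(counts) {
  check_raw_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon entropy and Pielou's evenness
#'
#' H = -sum p_i log p_i over taxa with nonzero counts (natural log);
#' J = H / log(S_obs). Evenness is undefined (NA) with fewer than two taxa
#' present.
#'
#' @param counts count vector for one sample.
#' @return list with `shannon` and `pielou`.
#' @export
shannon_pielou <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  p <- counts[counts > 0]
  if (length(p) == 0) return(list(shannon = 0, pielou = NA_real_))
  p <- p / sum(p)
  h <- -sum(p * log(p))
  j <- if (length(p) < 2) NA_real_ else h / log(length(p))
  list(shannon = h, pielou = j)
}

#' Simpson diversity index
#'
#' 1 - sum p_i^2; the probability that two randomly drawn reads belong to
#' different taxa. Invariant to rescaling of counts.
#'
#' @param counts count vector for one sample.
#' @return diversity in [0, 1).
#' @export
simpson <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  tot <- sum(counts)
  if (tot == 0) return(0)
  p <- counts / tot
  1 - sum(p^2)
}

#' Alpha diversity table for all samples
#'
#' @param x raw count table (features x samples, integer-valued).
#' @return data.frame with sample_id, richness, chao1, shannon, pielou,
#'   simpson.
#' @export
alpha_diversity <- function(x) {
  validate_count_table(x, allow_real = FALSE)
  res <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    sp <- shannon_pielou(v)
    data.frame(sample_id = colnames(x)[j],
               richness = sum(v > 0),
               chao1 = chao1(v),
               shannon = sp$shannon,
               pielou = sp$pielou,
               simpson = simpson(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Rarefaction curve by subsampling without replacement
#'
#' For each depth, reads are subsampled without replacement (multivariate
#' hypergeometric draw) `iterations` times and the mean number of observed
#' features is reported.
#'
#' @param counts integer count vector.
#' @param depths subsampling depths (each <= total count).
#' @param iterations Monte-Carlo repeats per depth.
#' @param seed RNG seed.
#' @return data.frame with depth, mean_richness, sd_richness.
#' @export
rarefy_curve <- function(counts, depths, iterations = 100, seed = 1) {
  check_raw_counts(counts)
  total <- sum(counts)
  if (any(depths > total)) {
    stop(sprintf("depth exceeds total count (%d)", total), call. = FALSE)
  }
  if (any(depths < 1)) stop("depths must be >= 1", call. = FALSE)
  with_seed(seed, {
    res <- lapply(depths, function(d) {
      rich <- vapply(seq_len(iterations), function(i) {
        sub <- rhyper_multi(counts, d)
        sum(sub > 0)
      }, numeric(1))
      data.frame(depth = d, mean_richness = mean(rich), sd_richness = stats::sd(rich))
    })
    do.call(rbind, res)
  })
}

# Multivariate hypergeometric draw: subsample `size` reads without
# replacement from urns with `counts` balls, via sequential rhyper.
rhyper_multi <- function(counts, size) {
  n <- length(counts)
  out <- numeric(n)
  remaining <- sum(counts)
  left <- size
  for (i in seq_len(n)) {
    if (left == 0) break
    remaining <- remaining - counts[i]
    if (remaining == 0) {
      out[i] <- left
      left <- 0
      break
    }
    k <- stats::rhyper(1, counts[i], remaining, left)
    out[i] <- k
    left <- left - k
  }
  out
}

check_raw_counts <- function(counts) {
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(counts != round(counts))) {
    stop("integer-valued raw counts required (use the raw count table, not a normalized one)",
         call. = FALSE)
  }
  invisible(counts)
}
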