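#' Mock-community spike correction
#'
#' A spiked sample's reads for a mock genus are the sum of the planted
#' spike and the native background. The correction estimates the
#' background from the matched unspiked samples: a factor f
#' (spiked/unspiked ratio of the non-mock community mass, unique per
#' sample matrix and storage condition) rescales the unspiked abundances
#' onto the spiked sample's compositional scale before subtraction.
#'
#' @name spikefix
NULL

#' Expected mock-community read profile
#'
#' Member weight proportional to cells_per_mg * genome_size_bp *
#' extraction_efficiency, closed to sum to 1.
#'
#' @param mock a [mock_spec()].
#' @return named vector of expected relative read abundances.
#' @export
expected_mock_profile <- function(mock) {
  if (any(is.na(mock$genome_size_bp) | mock$genome_size_bp <= 0)) {
    stop("missing genome size for mock member(s)", call. = FALSE)
  }
  w <- mock$cells_per_mg * mock$genome_size_bp * mock$extraction_efficiency
  stats::setNames(w / sum(w), mock$genus)
}

# Replicate-mean abundance per (matrix, condition), on the requested scale.
condition_means <- function(x, sheet, scale = c("relative", "raw")) {
  scale <- match.arg(scale)
  if (scale == "relative") x <- suppressWarnings(total_sum_scale(x))
  sheet <- sheet[match(colnames(x), sheet$sample_id), , drop = FALSE]
  key <- paste(sheet$matrix, condition_label(sheet), sep = "|")
  means <- vapply(split(seq_len(ncol(x)), key), function(idx) {
    rowMeans(x[, idx, drop = FALSE])
  }, numeric(nrow(x)))
  means  # features x condition-keys
}

#' Spiked/unspiked background factor per matrix and condition
#'
#' f = (non-mock-genus mass in the spiked replicate means) /
#' (non-mock-genus mass in the unspiked replicate means), computed on
#' relative abundances by default.
#'
#' @param spiked,unspiked genus x sample count tables of the spiked and
#'   matched unspiked samples.
#' @param mock_genera character vector of mock genus ids.
#' @param sheet sample sheet covering both tables.
#' @param scale "relative" (total-sum-scaled, default) or "raw".
#' @return data.frame with matrix, condition, f.
#' @export
background_factor <- function(spiked, unspiked, mock_genera, sheet,
                              scale = "relative") {
  ms <- condition_means(spiked, sheet, scale)
  mu <- condition_means(unspiked, sheet, scale)
  common <- intersect(colnames(ms), colnames(mu))
  if (length(common) == 0) {
    stop("no matched spiked/unspiked (matrix, condition) cells", call. = FALSE)
  }
  nonmock <- setdiff(rownames(spiked), mock_genera)
  num <- colSums(ms[nonmock, common, drop = FALSE])
  den <- colSums(mu[nonmock, common, drop = FALSE])
  if (any(den == 0)) {
    stop("zero non-mock mass in unspiked cell(s): ",
         paste(common[den == 0], collapse = ", "), call. = FALSE)
  }
  parts <- strsplit(common, "|", fixed = TRUE)
  data.frame(matrix = vapply(parts, `[[`, "", 1),
             condition = vapply(parts, `[[`, "", 2),
             f = unname(num / den), stringsAsFactors = FALSE)
}

#' Background-correct mock genera in spiked samples
#'
#' background_g = f * (unspiked replicate-mean abundance of g); corrected
#' = spiked abundance - background, per spiked replicate. Negative
#' corrected values are clamped to zero and flagged (configurable).
#'
#' @inheritParams background_factor
#' @param f factor table from [background_factor()] (recomputed when
#'   NULL).
#' @param clamp clamp negative corrected values to zero (default TRUE).
#' @return list with `corrected` (mock genus x spiked sample matrix, on
#'   the chosen abundance scale) and `audit` (long data.frame: sample_id,
#'   genus, spiked_value, background, corrected, clamped).
#' @export
correct_spiked <- function(spiked, unspiked, mock_genera, sheet, f = NULL,
                           scale = "relative", clamp = TRUE) {
  present <- mock_genera %in% rownames(spiked) | mock_genera %in% rownames(unspiked)
  if (any(!present)) {
    warning("mock genus absent from both tables, skipped: ",
            paste(mock_genera[!present], collapse = ", "), call. = FALSE)
    mock_genera <- mock_genera[present]
  }
  f <- f %||% background_factor(spiked, unspiked, mock_genera, sheet, scale)
  sp_ab <- if (scale == "relative") suppressWarnings(total_sum_scale(spiked)) else spiked
  un_means <- condition_means(unspiked, sheet, scale)
  sh <- sheet[match(colnames(spiked), sheet$sample_id), , drop = FALSE]
  key <- paste(sh$matrix, condition_label(sh), sep = "|")
  fkey <- paste(f$matrix, f$condition, sep = "|")
  audit <- list()
  corrected <- matrix(NA_real_, length(mock_genera), ncol(spiked),
                      dimnames = list(mock_genera, colnames(spiked)))
  for (j in seq_len(ncol(spiked))) {
    fj <- f$f[match(key[j], fkey)]
    if (is.na(fj)) next
    bg <- fj * un_means[mock_genera, match(key[j], colnames(un_means))]
    bg[is.na(bg)] <- 0
    spv <- sp_ab[mock_genera, j]
    corr <- spv - bg
    clamped <- corr < 0
    if (clamp) corr[clamped] <- 0
    corrected[, j] <- corr
    audit[[j]] <- data.frame(sample_id = colnames(spiked)[j],
                             genus = mock_genera, spiked_value = spv,
                             background = bg, corrected = corr,
                             clamped = clamped, stringsAsFactors = FALSE)
  }
  list(corrected = corrected, audit = do.call(rbind, audit), f = f)
}

#' Mock-member abundance profiles relative to the 0 h mean
#'
#' Per matrix and member: log2(abundance / mean abundance at 0 h), with a
#' t-based 95% confidence interval over replicates for every condition.
#'
#' @param corrected mock genus x spiked sample abundance matrix (e.g.
#'   `$corrected` from [correct_spiked()]).
#' @param sheet sample sheet.
#' @param conf confidence level (default 0.95).
#' @return data.frame: matrix, condition, genus, log2_ratio, ci_lower,
#'   ci_upper, n_replicates.
#' @export
mock_condition_profiles <- function(corrected, sheet, conf = 0.95) {
  sh <- sheet[match(colnames(corrected), sheet$sample_id), , drop = FALSE]
  cond <- condition_label(sh)
  out <- list()
  for (mx in unique(sh$matrix)) {
    base_idx <- which(sh$matrix == mx & sh$time_h == 0)
    for (g in rownames(corrected)) {
      base_mean <- mean(corrected[g, base_idx])
      if (!is.finite(base_mean) || base_mean <= 0) {
        warning(sprintf("zero 0 h mean for %s in %s; member excluded", g, mx),
                call. = FALSE)
        next
      }
      for (cd in unique(cond[sh$matrix == mx])) {
        idx <- which(sh$matrix == mx & cond == cd)
        vals <- log2(pmax(corrected[g, idx], .Machine$double.xmin) / base_mean)
        n <- length(vals)
        se <- stats::sd(vals) / sqrt(n)
        tq <- stats::qt(1 - (1 - conf) / 2, df = max(n - 1, 1))
        out[[length(out) + 1]] <- data.frame(
          matrix = mx, condition = cd, genus = g,
          log2_ratio = mean(vals), ci_lower = mean(vals) - tq * se,
          ci_upper = mean(vals) + tq * se, n_replicates = n,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(matrix = character(0), condition = character(0),
                      genus = character(0), log2_ratio = numeric(0),
                      ci_lower = numeric(0), ci_upper = numeric(0),
                      n_replicates = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
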