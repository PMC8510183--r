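#' Count tables and preprocessing
#'
#' A count table is a plain numeric matrix with features (taxa or AMR genes)
#' as rows and samples as columns, with unique row and column names. The
#' preprocessing chain mirrors common practice for shotgun metagenomic
#' profiles: mapped read-pair counts are halved to fragment counts, divided
#' by the genome size of each organism, and total-sum scaled to relative
#' abundances.
#'
#' @name counts
NULL

#' Validate a feature-by-sample count table
#'
#' @param x numeric matrix, features x samples, with unique dimnames.
#' @param allow_real allow non-integer entries (default TRUE; normalized
#'   tables are real-valued).
#' @return the validated matrix, invisibly unchanged.
#' @export
validate_count_table <- function(x, allow_real = TRUE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("count table must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("count table must have feature rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    stop("feature and sample identifiers must be unique", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("count table contains non-finite values", call. = FALSE)
  if (any(x < 0)) stop("count table contains negative entries", call. = FALSE)
  if (!allow_real && any(x != round(x))) {
    stop("count table must be integer-valued", call. = FALSE)
  }
  invisible(x)
}

#' Read a tab-delimited count table (features x samples)
#'
#' @param path TSV file; first column feature ids, header row sample ids.
#' @return numeric matrix with dimnames.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  validate_count_table(m)
  m
}

#' Write a count table as TSV
#'
#' Round-trips through [read_count_table()] losslessly to 12 significant
#' digits.
#'
#' @param x count table matrix.
#' @param path output file.
#' @param id_column name for the feature-id column (default "feature_id").
#' @export
write_count_table <- function(x, path, id_column = "feature_id") {
  df <- data.frame(id = rownames(x), signif(x, 15), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Halve mapped read-pair counts to fragment counts
#'
#' Paired-end mapping counts both mates of a proper pair; dividing by two
#' yields fragment counts. Odd entries indicate a bookkeeping problem and
#' are rejected unless `allow_odd` is set.
#'
#' @param x raw mapped-read count table (integer-valued).
#' @param allow_odd permit odd entries (result then has .5 values).
#' @return the table with every entry divided by 2.
#' @export
halve_pairs <- function(x, allow_odd = FALSE) {
  validate_count_table(x)
  if (!allow_odd) {
    odd <- which(x %% 2 != 0, arr.ind = TRUE)
    if (nrow(odd) > 0) {
      i <- odd[1, ]
      stop(sprintf(
        "odd read count at feature '%s', sample '%s' (%g); set allow_odd = TRUE to halve anyway",
        rownames(x)[i[1]], colnames(x)[i[2]], x[i[1], i[2]]), call. = FALSE)
    }
  }
  x / 2
}

#' Normalize counts by genome size
#'
#' Divides each feature's counts by its genome size, expressed in `unit_bp`
#' basepairs (default per Mbp so magnitudes stay comparable to counts). The
#' scaling unit cancels under subsequent total sum scaling.
#'
#' @param x count table.
#' @param feature_meta data.frame with columns `feature_id` and
#'   `genome_size_bp`.
#' @param unit_bp basepair unit of the divisor (default 1e6).
#' @return normalized table, same dimensions and order.
#' @export
genome_size_normalize <- function(x, feature_meta, unit_bp = 1e6) {
  validate_count_table(x)
  sizes <- feature_meta$genome_size_bp[match(rownames(x), feature_meta$feature_id)]
  missing <- rownames(x)[is.na(sizes) | sizes <= 0]
  if (length(missing) > 0) {
    stop("missing or non-positive genome size for feature(s): ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  x / (sizes / unit_bp)
}

#' Total sum scaling to relative abundances
#'
#' Scales every sample (column) to sum to 1. All-zero samples are retained
#' as all-zero columns with a warning.
#'
#' @param x count table (raw or genome-size normalized).
#' @return relative-abundance table.
#' @export
total_sum_scale <- function(x) {
  validate_count_table(x)
  totals <- colSums(x)
  zero <- totals == 0
  if (any(zero)) {
    warning("all-zero sample(s) retained as zeros: ",
            paste(colnames(x)[zero], collapse = ", "), call. = FALSE)
    totals[zero] <- 1
  }
  sweep(x, 2, totals, "/")
}

#' Aggregate features into groups
#'
#' Sums member-feature rows into group rows (e.g., genera into phyla, AMR
#' genes into drug classes). Column mass is conserved.
#'
#' @param x count table.
#' @param groups named character vector or data.frame (`feature_id`,
#'   `group`) mapping features to group labels.
#' @param unassigned if TRUE, unmapped features are pooled into an
#'   "unassigned" group instead of raising an error.
#' @return group x sample table.
#' @export
aggregate_features <- function(x, groups, unassigned = FALSE) {
  validate_count_table(x)
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$feature_id))
  }
  g <- groups[rownames(x)]
  miss <- is.na(g)
  if (any(miss)) {
    if (!unassigned) {
      stop("unmapped feature(s): ",
           paste(utils::head(rownames(x)[miss], 10), collapse = ", "),
           call. = FALSE)
    }
    g[miss] <- "unassigned"
  }
  out <- rowsum(x, group = as.character(g))
  validate_count_table(out)
}
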