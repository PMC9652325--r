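#' Bins-by-columns score matrix
#'
#' Container for per-bin compartment scores across replicates and/or samples.
#' `NA` entries mark masked bins; quantile normalization drops any bin masked
#' in at least one column (intersection rule) rather than imputing it.
#'
#' @param bins a [genome_bins()] object (all chromosomes concatenated).
#' @param scores numeric matrix, `nrow(bins)` x columns.
#' @param sample character vector of sample labels, one per column.
#' @param replicate character vector of replicate labels, one per column.
#' @return A `score_matrix` object.
#' @export
score_matrix <- function(bins, scores, sample, replicate = sample) {
  scores <- as.matrix(scores)
  if (nrow(scores) != nrow(bins))
    stop_format("score rows (", nrow(scores), ") != bins (", nrow(bins), ")")
  if (length(sample) != ncol(scores) || length(replicate) != ncol(scores))
    stop_format("sample/replicate labels must match the number of columns")
  colnames(scores) <- if (all(sample == replicate)) make.unique(sample)
                      else make.unique(paste(sample, replicate, sep = "."))
  structure(list(bins = bins, scores = scores,
                 sample = as.character(sample),
                 replicate = as.character(replicate)),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d bins x %d columns (%d sample(s)); %d fully observed bins\n",
              nrow(x$scores), ncol(x$scores), length(unique(x$sample)),
              sum(stats::complete.cases(x$scores))))
  invisible(x)
}

#' Quantile-normalize compartment scores
#'
#' Makes score distributions identical across columns so samples and
#' replicates are directly comparable. Normalization is performed
#' independently within each chromosome, over all columns together (all
#' replicates of all samples at once). Each column is mapped to the
#' across-column mean of order statistics; ties within a column receive the
#' average of the tied reference quantiles. Bins masked (`NA`) in any column
#' are excluded for all columns.
#'
#' @param x a [score_matrix()] with >= 2 columns.
#' @return A [score_matrix()] with identical per-column value multisets on
#'   unmasked bins within each chromosome.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "score_matrix"))
  if (ncol(x$scores) < 2L) stop_config("quantile normalization needs >= 2 columns")
  out <- x$scores
  out[] <- NA_real_
  for (ch in unique(x$bins$chrom)) {
    rows <- which(x$bins$chrom == ch)
    block <- x$scores[rows, , drop = FALSE]
    keep <- stats::complete.cases(block)
    if (sum(keep) == 0L) next
    if (sum(keep) < 2L)
      stop_numeric("chromosome ", ch, " has < 2 fully observed bins")
    out[rows[keep], ] <- limma::normalizeQuantiles(block[keep, , drop = FALSE],
                                                   ties = TRUE)
  }
  score_matrix(x$bins, out, x$sample, x$replicate)
}

#' Average replicates into per-sample scores
#'
#' Per bin, the arithmetic mean of the (quantile-normalized) replicate columns
#' of each sample.
#'
#' @param x a [score_matrix()], normally the output of [quantile_normalize()].
#' @param design optional data frame with `sample` and `replicate` columns;
#'   when given, every column of `x` must appear in it.
#' @return A [score_matrix()] with one column per sample.
#' @export
average_replicates <- function(x, design = NULL) {
  stopifnot(inherits(x, "score_matrix"))
  if (!is.null(design)) {
    have <- paste(design$sample, design$replicate)
    want <- paste(x$sample, x$replicate)
    if (!all(want %in% have))
      stop_config("replicate not in design: ", want[!want %in% have][1L])
  }
  samples <- unique(x$sample)
  avg <- vapply(samples, function(s)
    rowMeans(x$scores[, x$sample == s, drop = FALSE]),
    numeric(nrow(x$scores)))
  score_matrix(x$bins, avg, samples, samples)
}

#' Load precomputed compartment scores
#'
#' Entry point for externally computed scores (one bedGraph per column, all on
#' the same bin grid), bypassing the Hi-C scoring stage: the result feeds
#' [quantile_normalize()] directly. Bins missing in any file are masked.
#'
#' @param paths character vector of bedGraph files, one per column.
#' @param bins the common [genome_bins()] grid.
#' @param sample,replicate labels, one per file.
#' @return A [score_matrix()].
#' @export
load_precomputed_scores <- function(paths, bins, sample, replicate = sample) {
  if (length(paths) != length(sample))
    stop_config("one sample label per file required")
  scores <- vapply(paths, read_scores_bedgraph, numeric(nrow(bins)),
                   bins = bins)
  sm <- score_matrix(bins, scores, sample, replicate)
  incomplete <- !stats::complete.cases(sm$scores)
  sm$scores[incomplete, ] <- NA_real_
  sm
}
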