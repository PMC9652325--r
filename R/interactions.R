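# Differential-interaction testing: log2(O/E) of user-supplied significant
# interactions (e.g. FitHiC2 calls), restricted to pairs anchored in
# differential compartments, scored with the same Mahalanobis machinery.

#' Read significant interactions (FitHiC2-style TSV)
#'
#' Columns `chr1 pos1 chr2 pos2 [count [qvalue]]` (header lines starting with
#' `chr` or `#` are skipped); positions are interval midpoints or starts and
#' are mapped to bins by integer division by the resolution. Several files
#' (e.g. one per replicate) are combined as the union of bin pairs — a pair
#' significant in at least one input is tested. Trans pairs are dropped with a
#' warning.
#'
#' @param paths one or more TSV files, already thresholded by the caller.
#' @param bins a [genome_bins()] object.
#' @return data frame with `chrom`, `binA`, `binB` (0-based bin indices,
#'   `binA <= binB`), one row per unique pair.
#' @export
read_interactions <- function(paths, bins) {
  res <- bin_resolution(bins)
  all <- NULL
  for (path in paths) {
    if (!file.exists(path)) stop_config("interactions file not found: ", path)
    df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                            comment.char = "#")
    if (suppressWarnings(is.na(as.numeric(df[1L, 2L]))))
      df <- df[-1L, , drop = FALSE]     # header row (non-numeric position)
    if (ncol(df) < 4L) stop_format("interactions file needs >= 4 columns: ", path)
    cis <- df[[1L]] == df[[3L]]
    if (!all(cis)) {
      warning("dropping ", sum(!cis), " trans interaction(s) from ", path)
      df <- df[cis, , drop = FALSE]
    }
    ba <- floor(as.numeric(df[[2L]]) / res)
    bb <- floor(as.numeric(df[[4L]]) / res)
    all <- rbind(all, data.frame(chrom = df[[1L]], binA = pmin(ba, bb),
                                 binB = pmax(ba, bb), stringsAsFactors = FALSE))
  }
  all <- unique(all)
  n_per_chrom <- table(bins$chrom)
  bad <- is.na(n_per_chrom[all$chrom]) |
    all$binB >= as.vector(n_per_chrom[all$chrom]) | all$binA < 0
  if (any(bad))
    stop_format("interaction outside the bin grid, e.g. ",
                all$chrom[bad][1L], ":", all$binA[bad][1L])
  rownames(all) <- NULL
  all
}

#' Restrict interactions to differential compartments
#'
#' Keeps the interactions with at least one anchor bin inside a significant
#' differential bin (either end or both; pairs with both anchors qualifying
#' are kept once).
#'
#' @param interactions data frame from [read_interactions()].
#' @param significant data frame with `chrom`, `start`, `end` (e.g. from
#'   [significant_bins()]) or with `chrom` and 0-based `index`.
#' @param bins the common [genome_bins()] grid; required when `significant`
#'   carries coordinates.
#' @return the qualifying subset of `interactions`.
#' @export
overlap_filter <- function(interactions, significant, bins = NULL) {
  if (!is.null(significant$index)) {
    key <- paste(significant$chrom, significant$index)
  } else {
    if (is.null(bins)) stop_config("bins required to resolve coordinates")
    res <- bin_resolution(bins)
    if (any(significant$start %% res != 0 & significant$start != 0))
      stop_format("significant bins not on the bin grid")
    key <- paste(significant$chrom, floor(significant$start / res))
  }
  keep <- paste(interactions$chrom, interactions$binA) %in% key |
    paste(interactions$chrom, interactions$binB) %in% key
  interactions[keep, , drop = FALSE]
}

#' Per-sample log2 observed/expected of interactions
#'
#' Expected counts come from the same per-distance mean model as the
#' compartment O/E transform, computed on this map; a pseudocount keeps pairs
#' absent in one sample finite: `log2((obs + c) / (exp + c))`.
#'
#' @param map a [contact_map()] for the interactions' chromosome.
#' @param records data frame with `binA`, `binB` (0-based indices into the
#'   map).
#' @param pseudocount added to observed and expected (default 1).
#' @param min_coverage_frac coverage filter for the expected model.
#' @return numeric vector of log2(O/E), one per record.
#' @export
interaction_oe <- function(map, records, pseudocount = 1,
                           min_coverage_frac = 0.01) {
  n <- nrow(map$counts)
  if (any(records$binA < 0) || any(records$binB >= n))
    stop_format("interaction record outside map bounds")
  oe <- oe_transform(map, min_coverage_frac)
  d <- records$binB - records$binA
  expd <- ifelse(d + 1L <= length(oe$expected), oe$expected[d + 1L], 0)
  obs <- map$counts[cbind(records$binA + 1L, records$binB + 1L)]
  log2((obs + pseudocount) / (expd + pseudocount))
}

#' Differential-interaction test
#'
#' Mahalanobis distance of each interaction's per-sample log2(O/E) vector
#' from the per-sample centers (mean over the tested set, optionally
#' trimmed), with a robust (MCD) covariance by default, chi-square p-values
#' and BH adjustment.
#'
#' @param oe interactions x samples matrix of log2(O/E) values.
#' @param cfg an [md_config()] (its `df` defaults to the number of samples).
#' @param robust use MCD covariance (default) or the classical estimate.
#' @param trim trimming fraction for the per-sample centers (default 0).
#' @return data frame with `dist`, `pvalue`, `padj`, one row per interaction.
#' @export
md_interactions <- function(oe, cfg = md_config(), robust = TRUE, trim = 0) {
  oe <- as.matrix(oe)
  if (ncol(oe) < 2L) stop_config("need >= 2 samples")
  if (nrow(oe) < 10L)
    stop_numeric("only ", nrow(oe),
                 " qualifying interactions; covariance unusable (need >= 10)")
  mu <- apply(oe, 2L, mean, trim = trim)
  sinv <- if (robust) robust_inverse_covariance(oe, cfg) else {
    cv <- stats::cov(oe)
    tryCatch(solve(cv),
             error = function(e) stop_numeric("singular covariance"))
  }
  df <- cfg$df %||% ncol(oe)
  md <- mahalanobis_dist(oe, mu, sinv)
  p <- stats::pchisq(md, df, lower.tail = FALSE)
  data.frame(dist = md, pvalue = p, padj = stats::p.adjust(p, "BH"))
}

#' Full differential-interaction analysis
#'
#' Convenience wrapper: filters interactions to those anchored in significant
#' differential compartments, computes per-sample log2(O/E) (replicate maps of
#' a sample are summed first), and tests with [md_interactions()].
#'
#' @param maps list of [contact_map()]s (one chromosome), with `sample` labels
#'   set; replicate maps of the same sample are summed.
#' @param interactions data frame from [read_interactions()].
#' @param significant significant differential bins (see [overlap_filter()]).
#' @param bins the [genome_bins()] grid.
#' @param cfg an [md_config()].
#' @param ... passed to [md_interactions()].
#' @return data frame: anchors, per-sample log2(O/E), `dist`, `pvalue`,
#'   `padj`.
#' @export
diff_interactions <- function(maps, interactions, significant, bins,
                              cfg = md_config(), ...) {
  qual <- overlap_filter(interactions, significant, bins)
  if (nrow(qual) == 0L) stop_numeric("no interactions overlap differential bins")
  samples <- unique(vapply(maps, function(m) m$sample, ""))
  oe <- vapply(samples, function(s) {
    ms <- maps[vapply(maps, function(m) m$sample == s, TRUE)]
    total <- Reduce(`+`, lapply(ms, function(m) m$counts))
    interaction_oe(contact_map(total, ms[[1L]]$chrom, s), qual)
  }, numeric(nrow(qual)))
  colnames(oe) <- samples
  cbind(qual, as.data.frame(oe), md_interactions(oe, cfg, ...))
}
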