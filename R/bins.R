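#' Fixed-width genomic bins
#'
#' Constructs the bin coordinate system used by every downstream step: an
#' ordered set of fixed-width intervals (0-based, half-open, BED convention)
#' per chromosome, with a dense 0-based `index` within each chromosome. The
#' terminal bin of a chromosome may be shorter than the common resolution.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors of 0-based half-open coordinates.
#' @param id optional per-bin identifiers (e.g. the 4th column of a HiC-Pro
#'   bins file) used to resolve integer bin ids in sparse triplet matrices.
#' @return A `genome_bins` data frame with columns `chrom`, `start`, `end`,
#'   `index` (and `id` if given) and a `resolution` attribute in bp.
#' @export
genome_bins <- function(chrom, start, end, id = NULL) {
  if (length(chrom) != length(start) || length(start) != length(end))
    stop_format("bins: chrom/start/end lengths differ")
  if (length(chrom) == 0L) stop_format("bins: empty")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end)) || any(end <= start))
    stop_format("bins: invalid interval coordinates")
  # bp coordinates fit in integers; keeps every writer free of 1e+05 notation
  start <- as.integer(start); end <- as.integer(end)
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(id)) df$id <- as.character(id)

  w <- df$end - df$start
  resolution <- max(w)
  idx <- integer(nrow(df))
  for (ch in unique(df$chrom)) {
    sel <- which(df$chrom == ch)
    if (is.unsorted(df$start[sel], strictly = TRUE))
      stop_format("bins: intervals on ", ch, " are not sorted")
    s <- df$start[sel]; e <- df$end[sel]
    if (length(sel) > 1L) {
      if (any(s[-1L] < e[-length(e)]))
        stop_format("bins: overlapping intervals on ", ch)
      if (any(s[-1L] > e[-length(e)]))
        stop_format("bins: gap between consecutive intervals on ", ch)
      if (any((e - s)[-length(sel)] != resolution))
        stop_format("bins: mixed bin widths on ", ch,
                    " (only the terminal bin may be short)")
    }
    if (e[length(sel)] - s[length(sel)] > resolution)
      stop_format("bins: mixed bin widths on ", ch)
    idx[sel] <- seq_along(sel) - 1L
  }
  df$index <- idx
  attr(df, "resolution") <- resolution
  class(df) <- c("genome_bins", "data.frame")
  df
}

#' Read a bins BED file
#'
#' Reads a BED3/BED4 bins file (HiC-Pro "abs" bed dialect: an optional 4th
#' column holds integer bin ids). Bin width (resolution) is inferred and
#' inconsistent widths, gaps or overlaps are rejected.
#'
#' @param path path to a whitespace-separated BED-like file.
#' @return A [genome_bins()] object.
#' @export
read_bins <- function(path) {
  if (!file.exists(path)) stop_config("bins file not found: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 3L) stop_format("bins file needs >= 3 columns: ", path)
  genome_bins(df[[1L]], df[[2L]], df[[3L]],
              id = if (ncol(df) >= 4L) df[[4L]] else NULL)
}

bin_resolution <- function(bins) attr(bins, "resolution")

#' @export
print.genome_bins <- function(x, ...) {
  cat(sprintf("genome_bins: %d bins, %d chromosome(s), resolution %g bp\n",
              nrow(x), length(unique(x$chrom)), bin_resolution(x)))
  invisible(x)
}

# rows of `bins` belonging to one chromosome, preserving order
bins_chrom <- function(bins, chrom) {
  sel <- bins$chrom == chrom
  if (!any(sel)) stop_format("chromosome not in bins: ", chrom)
  out <- bins[sel, , drop = FALSE]
  attr(out, "resolution") <- bin_resolution(bins)
  class(out) <- class(bins)
  out
}

bins_granges <- function(bins) {
  GenomicRanges::GRanges(bins$chrom,
                         IRanges::IRanges(start = bins$start + 1L, end = bins$end))
}

#' Write per-bin scores as bedGraph
#'
#' One 4-column line per unmasked bin; `NA` values (masked bins) are omitted.
#' Values are written at full double precision so that a write/read round trip
#' is lossless well below 1e-6.
#'
#' @param bins a [genome_bins()] object.
#' @param values numeric vector, one value per bin; `NA` = masked.
#' @param path output file.
#' @param header optional comment line (without leading `#`) written first.
#' @export
write_scores_bedgraph <- function(bins, values, path, header = NULL) {
  if (length(values) != nrow(bins))
    stop_format("values length (", length(values), ") != number of bins (",
                nrow(bins), ")")
  keep <- !is.na(values)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("#", header), con)
  if (any(keep)) {
    lines <- sprintf("%s\t%d\t%d\t%s", bins$chrom[keep],
                     as.integer(bins$start[keep]), as.integer(bins$end[keep]),
                     formatC(values[keep], digits = 15, format = "g"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a bedGraph of per-bin scores onto a bin grid
#'
#' Every record must coincide exactly with a bin of `bins` (same chromosome,
#' start and end); records on a different grid raise a format error. Bins
#' absent from the file come back as `NA` (masked).
#'
#' @param path bedGraph file (4 columns; `#` comments ignored).
#' @param bins a [genome_bins()] object.
#' @return numeric vector of length `nrow(bins)`.
#' @export
read_scores_bedgraph <- function(path, bins) {
  if (!file.exists(path)) stop_config("bedGraph not found: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 4L) stop_format("bedGraph needs 4 columns: ", path)
  key <- paste(bins$chrom, sprintf("%.0f", bins$start),
               sprintf("%.0f", bins$end))
  hit <- match(paste(df[[1L]], sprintf("%.0f", as.numeric(df[[2L]])),
                     sprintf("%.0f", as.numeric(df[[3L]]))), key)
  if (anyNA(hit))
    stop_format("bedGraph records not on the bin grid (", path, "), e.g. ",
                paste(df[is.na(hit), 1:3][1L, ], collapse = ":"))
  out <- rep(NA_real_, nrow(bins))
  out[hit] <- as.numeric(df[[4L]])
  out
}
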