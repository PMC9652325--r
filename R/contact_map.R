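#' Cis contact map for one chromosome
#'
#' A symmetric, nonnegative bin-pair count matrix for a single chromosome of a
#' single replicate. Counts need not be integers (model/expected matrices are
#' valid inputs).
#'
#' @param counts square symmetric numeric matrix, all entries >= 0.
#' @param chrom chromosome name.
#' @param sample,replicate labels carried through to outputs.
#' @return A `contact_map` object.
#' @export
contact_map <- function(counts, chrom = "chr", sample = NA_character_,
                        replicate = NA_character_) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts))
    stop_format("contact_map: counts must be a square matrix")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_format("contact_map: counts must be finite and nonnegative")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(abs(counts))))
    stop_format("contact_map: counts must be symmetric")
  structure(list(counts = counts, chrom = as.character(chrom),
                 sample = as.character(sample),
                 replicate = as.character(replicate)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %s, %d bins, total count %.4g (sample=%s, rep=%s)\n",
              x$chrom, nrow(x$counts), sum(x$counts), x$sample, x$replicate))
  invisible(x)
}

# Resolve triplet bin ids against the bins table. Integer-looking ids resolve
# through the bins file's id column when present (HiC-Pro 1-based "abs" ids),
# else as 1-based row numbers; "chrom_start" ids are matched literally.
resolve_bin_ids <- function(ids, bins) {
  ids <- as.character(ids)
  if (!is.null(bins$id)) {
    hit <- match(ids, bins$id)
    if (!anyNA(hit)) return(hit)
  }
  if (all(grepl("^[0-9]+$", ids))) {
    hit <- as.integer(ids)
    if (any(hit < 1L) || any(hit > nrow(bins)))
      stop_format("triplet bin id out of range (1..", nrow(bins), ")")
    return(hit)
  }
  hit <- match(ids, paste0(bins$chrom, "_", sprintf("%.0f", bins$start)))
  if (anyNA(hit))
    stop_format("triplet bin id not found in bins: ", ids[is.na(hit)][1L])
  hit
}

#' Read a sparse triplet contact matrix
#'
#' Reads a HiC-Pro-style whitespace-separated `binA binB count` file against a
#' bins table. Entries given once (either triangle) are mirrored; duplicate
#' `(i, j)` entries are summed. All records must fall on one chromosome (cis).
#'
#' @param path triplet file; an empty file yields an all-zero map.
#' @param bins a [genome_bins()] object covering the map.
#' @param chrom chromosome to extract; defaults to the single chromosome
#'   present in the file.
#' @param sample,replicate labels stored on the result.
#' @return A [contact_map()].
#' @export
read_contact_matrix <- function(path, bins, chrom = NULL,
                                sample = NA_character_,
                                replicate = NA_character_) {
  if (!file.exists(path)) stop_config("matrix file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L) {
    ch <- chrom %||% unique(bins$chrom)[1L]
    n <- nrow(bins_chrom(bins, ch))
    return(contact_map(matrix(0, n, n), ch, sample, replicate))
  }
  if (ncol(df) < 3L) stop_format("triplet file needs 3 columns: ", path)
  if (any(!is.finite(as.numeric(df[[3L]]))) || any(as.numeric(df[[3L]]) < 0))
    stop_format("negative or non-finite count in ", path)
  ia <- resolve_bin_ids(df[[1L]], bins)
  ib <- resolve_bin_ids(df[[2L]], bins)
  cha <- bins$chrom[ia]; chb <- bins$chrom[ib]
  cis <- cha == chb
  if (!all(cis)) {
    warning("dropping ", sum(!cis), " trans (inter-chromosomal) record(s)")
    ia <- ia[cis]; ib <- ib[cis]; df <- df[cis, , drop = FALSE]
    cha <- cha[cis]
  }
  if (is.null(chrom)) {
    chrom <- unique(cha)
    if (length(chrom) != 1L)
      stop_format("triplet file spans several chromosomes (",
                  paste(chrom, collapse = ", "), "); pass `chrom`")
  } else {
    keep <- cha == chrom
    ia <- ia[keep]; ib <- ib[keep]; df <- df[keep, , drop = FALSE]
  }
  cb <- bins_chrom(bins, chrom)
  first <- min(which(bins$chrom == chrom))
  li <- ia - first + 1L
  lj <- ib - first + 1L
  n <- nrow(cb)
  # sparseMatrix sums duplicated (i, j) entries
  lo <- pmin(li, lj); hi <- pmax(li, lj)
  m <- as.matrix(Matrix::sparseMatrix(i = lo, j = hi, x = as.numeric(df[[3L]]),
                                      dims = c(n, n)))
  m <- m + t(m)
  diag(m) <- diag(m) / 2
  contact_map(m, chrom, sample, replicate)
}

#' Write a contact map as sparse triplets
#'
#' Upper-triangle nonzero entries only, with 1-based ids matching the bins
#' table (its id column if present, else row numbers), so that
#' [read_contact_matrix()] round-trips exactly on integer counts.
#'
#' @param map a [contact_map()].
#' @param bins the [genome_bins()] the map was built on.
#' @param path output file.
#' @export
write_contact_matrix <- function(map, bins, path) {
  first <- min(which(bins$chrom == map$chrom))
  n <- nrow(map$counts)
  ut <- which(upper.tri(map$counts, diag = TRUE) & map$counts != 0,
              arr.ind = TRUE)
  gi <- ut[, 1L] + first - 1L
  gj <- ut[, 2L] + first - 1L
  ida <- if (!is.null(bins$id)) bins$id[gi] else gi
  idb <- if (!is.null(bins$id)) bins$id[gj] else gj
  utils::write.table(
    data.frame(ida, idb, map$counts[ut]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
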