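# Compartment-score computation for one chromosome: O/E transform of the raw
# cis map, Pearson correlation of O/E rows (the "plaid" matrix), exact top-k
# decomposition, and covariate-driven component selection/orientation.

# Mean count per diagonal offset over unmasked bins. `positions` are the
# original 0-based bin indices of the rows of `sub`, so offsets refer to
# genomic distance even after masked bins are dropped.
expected_by_distance <- function(sub, positions) {
  d <- abs(outer(positions, positions, "-"))
  sums <- rowsum(as.vector(sub), as.vector(d))
  cnts <- rowsum(rep(1, length(d)), as.vector(d))
  ed <- rep(0, max(d) + 1L)
  ed[as.integer(rownames(sums)) + 1L] <- sums / cnts
  ed
}

#' Observed/expected transform of a contact map
#'
#' Divides every entry by the mean count at its genomic distance, removing the
#' distance-decay trend. Bins with zero marginal count, or whose fraction of
#' nonzero cis entries falls below `min_coverage_frac`, are masked first;
#' expected values are computed over unmasked pairs only, and distances whose
#' expected value is 0 get O/E 0.
#'
#' @param map a [contact_map()].
#' @param min_coverage_frac minimum fraction of nonzero entries in a bin's row
#'   for the bin to be kept (default 0.01).
#' @return An `oe_matrix`: list with the full n x n `oe` matrix (masked
#'   rows/columns zero), logical `mask` (TRUE = filtered out), the per-distance
#'   `expected` vector, and `chrom`.
#' @export
oe_transform <- function(map, min_coverage_frac = 0.01) {
  counts <- map$counts
  n <- nrow(counts)
  marg <- rowSums(counts)
  nzfrac <- rowMeans(counts > 0)
  mask <- marg == 0 | nzfrac < min_coverage_frac
  if (all(mask))
    stop_numeric("all bins masked on ", map$chrom, "; chromosome degenerate")
  p <- which(!mask)
  sub <- counts[p, p, drop = FALSE]
  ed <- expected_by_distance(sub, p - 1L)
  d <- abs(outer(p - 1L, p - 1L, "-"))
  em <- matrix(ed[d + 1L], nrow(sub))
  oe_sub <- ifelse(em > 0, sub / em, 0)
  oe <- matrix(0, n, n)
  oe[p, p] <- oe_sub
  structure(list(oe = oe, mask = mask, expected = ed, chrom = map$chrom),
            class = "oe_matrix")
}

#' Correlation matrix of O/E rows
#'
#' Pearson correlation of every pair of O/E rows over unmasked columns — the
#' plaid-patterned matrix whose leading eigenvectors carry the compartment
#' signal. Rows with zero variance are masked (iterated until stable, since
#' removing a column can newly degenerate another row).
#'
#' @param oe an `oe_matrix` from [oe_transform()].
#' @return A `correlation_matrix`: list with the m x m `corr` matrix over
#'   unmasked bins, the full-length logical `mask`, and `chrom`.
#' @export
correlation_matrix <- function(oe) {
  mask <- oe$mask
  repeat {
    p <- which(!mask)
    if (length(p) < 3L)
      stop_numeric("fewer than 3 unmasked bins on ", oe$chrom)
    sub <- oe$oe[p, p, drop = FALSE]
    v <- apply(sub, 1L, stats::var)
    degen <- v <= 0 | !is.finite(v)
    if (!any(degen)) break
    mask[p[degen]] <- TRUE
  }
  corr <- stats::cor(t(sub))
  structure(list(corr = corr, mask = mask, chrom = oe$chrom),
            class = "correlation_matrix")
}

#' Top-k singular triplets of a correlation matrix
#'
#' Exact truncated decomposition of the symmetric correlation matrix: the
#' top-k eigenpairs give the singular triplets (singular values are the
#' absolute eigenvalues; left singular vectors differ from the right ones only
#' by the eigenvalue sign). Principal components are the projections
#' `corr %*% V`. A deterministic sign convention (largest-magnitude loading
#' positive) is applied so repeated runs are bit-identical.
#'
#' @param corr a `correlation_matrix`.
#' @param k number of components to retain (>= 2; default 2).
#' @return A `pc_result`: list with `u`, `d` (nonincreasing singular values),
#'   `v`, `pc` (m x k), `mask`, `chrom`.
#' @export
partial_svd <- function(corr, k = 2L) {
  if (k < 2L) stop_config("k must be >= 2")
  x <- corr$corr
  if (k > nrow(x)) stop_config("k exceeds matrix dimension")
  e <- tryCatch(eigen(x, symmetric = TRUE),
                error = function(err)
                  stop_numeric("decomposition failed on ", corr$chrom, ": ",
                               conditionMessage(err)))
  ord <- order(abs(e$values), decreasing = TRUE)[seq_len(k)]
  lam <- e$values[ord]
  v <- e$vectors[, ord, drop = FALSE]
  for (j in seq_len(k)) {              # deterministic sign of each column
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  u <- sweep(v, 2L, sign(lam + (lam == 0)), "*")
  structure(list(u = u, d = abs(lam), v = v, pc = x %*% v,
                 mask = corr$mask, chrom = corr$chrom),
            class = "pc_result")
}

#' Select and orient the compartment-tracking component
#'
#' Among the retained principal components, picks the one maximizing
#' `|r_GC| + |r_gene|` (Pearson correlations with the GC-content and
#' gene-density covariates over unmasked bins; ties go to the lower index) and
#' flips its sign if its GC correlation is negative, so that positive scores
#' mean the A (GC-rich, gene-dense) compartment. If the GC correlation is
#' exactly zero the gene-density correlation decides the sign.
#'
#' @param pcs a `pc_result` from [partial_svd()].
#' @param gc,genes full-length per-bin covariate vectors (`NA` allowed; pairs
#'   with `NA` covariates are dropped from the correlations).
#' @return list with `score` (full-length, `NA` at masked bins), `component`
#'   (1-based index of the selected PC), `sign`, and the `correlations` matrix
#'   (k x 2) of PC-vs-covariate Pearson correlations.
#' @export
select_and_orient <- function(pcs, gc, genes) {
  p <- which(!pcs$mask)
  gc_u <- gc[p]; gn_u <- genes[p]
  safe_cor <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      return(NA_real_)
    stats::cor(a[ok], b[ok])
  }
  k <- ncol(pcs$pc)
  rg <- vapply(seq_len(k), function(j) safe_cor(pcs$pc[, j], gc_u), 0)
  rn <- vapply(seq_len(k), function(j) safe_cor(pcs$pc[, j], gn_u), 0)
  if (all(is.na(rg)) && all(is.na(rn)))
    stop_numeric("cannot orient: both covariates constant on ", pcs$chrom)
  tot <- abs(rg) + abs(rn)
  tot[is.na(tot)] <- abs(ifelse(is.na(rg), 0, rg)) + abs(ifelse(is.na(rn), 0, rn))
  sel <- which.max(tot)               # which.max takes the lowest index on ties
  rgs <- if (is.na(rg[sel])) 0 else rg[sel]
  sgn <- if (rgs < 0) -1 else if (rgs > 0) 1 else {
    rns <- if (is.na(rn[sel])) 0 else rn[sel]
    if (rns < 0) -1 else 1
  }
  score <- rep(NA_real_, length(pcs$mask))
  score[p] <- sgn * pcs$pc[, sel]
  corrs <- cbind(gc = rg, gene_density = rn)
  rownames(corrs) <- paste0("PC", seq_len(k))
  list(score = score, component = sel, sign = sgn, correlations = corrs)
}

#' Compartment scores for one chromosome
#'
#' Full per-chromosome chain: O/E transform, row-correlation matrix, exact
#' top-k decomposition, covariate-driven selection and orientation.
#' Chromosomes with fewer than `min_bins` unmasked bins are skipped with a
#' warning (all-`NA` scores): correlation-matrix PCA is meaningless on tiny
#' systems.
#'
#' @param map a [contact_map()].
#' @param gc,genes per-bin covariates for this chromosome (see [gc_track()],
#'   [gene_density_track()]).
#' @param k number of candidate components (default 2).
#' @param min_coverage_frac coverage filter passed to [oe_transform()].
#' @param min_bins minimum unmasked bins required (default 20).
#' @return list with `score` (length n, `NA` at masked bins), `component`,
#'   `sign`, `correlations`, `mask`.
#' @export
compartment_scores <- function(map, gc, genes, k = 2L,
                               min_coverage_frac = 0.01, min_bins = 20L) {
  n <- nrow(map$counts)
  oe <- oe_transform(map, min_coverage_frac)
  if (sum(!oe$mask) < min_bins) {
    warning("skipping ", map$chrom, ": only ", sum(!oe$mask),
            " unmasked bins (< ", min_bins, ")")
    return(list(score = rep(NA_real_, n), component = NA_integer_,
                sign = NA_real_, correlations = NULL, mask = rep(TRUE, n)))
  }
  cm <- correlation_matrix(oe)
  if (sum(!cm$mask) < min_bins) {
    warning("skipping ", map$chrom, ": only ", sum(!cm$mask),
            " non-degenerate bins (< ", min_bins, ")")
    return(list(score = rep(NA_real_, n), component = NA_integer_,
                sign = NA_real_, correlations = NULL, mask = rep(TRUE, n)))
  }
  pcs <- partial_svd(cm, k)
  so <- select_and_orient(pcs, gc, genes)
  c(so, list(mask = cm$mask))
}

#' Score a set of contact maps into a score matrix
#'
#' Runs [compartment_scores()] on every map (one chromosome of one replicate
#' each) and assembles the per-bin scores into a replicate-level
#' [score_matrix()] ready for [diff_compartments()]. Columns are the unique
#' (sample, replicate) pairs found on the maps.
#'
#' @param maps list of [contact_map()]s with `sample`/`replicate` labels set.
#' @param bins the common [genome_bins()] grid.
#' @param gc,genes per-bin covariate vectors on that grid.
#' @param ... passed to [compartment_scores()].
#' @return A [score_matrix()].
#' @export
score_maps <- function(maps, bins, gc, genes, ...) {
  cols <- unique(data.frame(sample = vapply(maps, function(m) m$sample, ""),
                            replicate = vapply(maps, function(m) m$replicate, ""),
                            stringsAsFactors = FALSE))
  scores <- matrix(NA_real_, nrow(bins), nrow(cols))
  for (j in seq_len(nrow(cols))) {
    for (m in maps) {
      if (m$sample != cols$sample[j] || m$replicate != cols$replicate[j]) next
      rows <- which(bins$chrom == m$chrom)
      if (length(rows) != nrow(m$counts))
        stop_format("map on ", m$chrom, " does not match the bin grid")
      cs <- compartment_scores(m, gc[rows], genes[rows], ...)
      scores[rows, j] <- cs$score
    }
  }
  score_matrix(bins, scores, cols$sample, cols$replicate)
}
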