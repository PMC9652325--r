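# Differential-compartment statistics. Per-bin sample score vectors (post
# quantile normalization, replicates averaged) are scored with a weighted
# Mahalanobis distance under a robust (MCD) covariance, refined by a two-pass
# outlier-removal step, tested against a chi-square reference, and adjusted
# with covariate-weighted BH when replicate variability is available.

#' Differential-test configuration
#'
#' @param df chi-square degrees of freedom for the Mahalanobis test; `NULL`
#'   (default) means the number of samples M, the dimension of the score
#'   vector.
#' @param outlier_quantile chi-square quantile for first-pass outlier removal
#'   (default 0.90: bins with pass-1 MD above the 90% critical value are
#'   dropped from the second covariance fit).
#' @param fdr_threshold adjusted-p cutoff used when reporting significant
#'   bins (default 0.10).
#' @param weighting `"distant"` (default) weights centers so that bins whose
#'   samples disagree most keep the largest deviations
#'   (`mu_i = s_i * (1 - w_i)`); `"printed"` is the mirrored form
#'   (`mu_i = s_i * w_i`). See the methods vignette for why "distant" is the
#'   default.
#' @param mcd_support_fraction fraction of points in the MCD support subset;
#'   `NULL` uses the implementation default `floor((n + p + 1) / 2) / n`.
#' @param seed seed fixed immediately before each MCD subset search, making
#'   robust covariance estimates reproducible.
#' @param ihw_nbins number of covariate quantile strata for weighted BH
#'   (default 5).
#' @param ihw_nfolds number of cross-fitting folds for weight learning
#'   (default 5).
#' @return An `md_config` list.
#' @export
md_config <- function(df = NULL, outlier_quantile = 0.90, fdr_threshold = 0.10,
                      weighting = c("distant", "printed"),
                      mcd_support_fraction = NULL, seed = 1L,
                      ihw_nbins = 5L, ihw_nfolds = 5L) {
  weighting <- match.arg(weighting)
  if (outlier_quantile <= 0 || outlier_quantile >= 1)
    stop_config("outlier_quantile must be in (0, 1)")
  if (!is.null(df) && df < 1) stop_config("df must be >= 1")
  structure(list(df = df, outlier_quantile = outlier_quantile,
                 fdr_threshold = fdr_threshold, weighting = weighting,
                 mcd_support_fraction = mcd_support_fraction,
                 seed = as.integer(seed), ihw_nbins = as.integer(ihw_nbins),
                 ihw_nfolds = as.integer(ihw_nfolds)),
            class = "md_config")
}

#' Pairwise sample distances, z-scores and weights
#'
#' For each bin i and sample N, `d[i, N]` is the root-sum-square distance of
#' sample N's score to all samples' scores, divided by (M - 1); `z` is its
#' standardization across bins within sample; the per-bin weight is
#' `w_i = pnorm(max_N z[i, N])`, close to 1 for bins whose samples disagree
#' most and 0.5 for a bin at the average disagreement.
#'
#' @param q numeric matrix, bins x samples (M >= 2), fully observed.
#' @return list with matrices `d`, `z` (bins x M) and vector `w`.
#' @export
pairwise_distances <- function(q) {
  q <- as.matrix(q)
  m <- ncol(q)
  if (m < 2L) stop_config("need >= 2 sample columns")
  if (any(!is.finite(q))) stop_numeric("non-finite scores")
  d <- vapply(seq_len(m), function(n)
    sqrt(rowSums((q - q[, n])^2)) / (m - 1), numeric(nrow(q)))
  z <- d
  for (n in seq_len(m)) {
    s <- stats::sd(d[, n])
    if (s == 0) {
      warning("sample ", n, ": all pairwise distances identical; z set to 0")
      z[, n] <- 0
    } else {
      z[, n] <- (d[, n] - mean(d[, n])) / s
    }
  }
  w <- stats::pnorm(apply(z, 1L, max))
  dimnames(d) <- dimnames(z) <- dimnames(q)
  list(d = d, z = z, w = w)
}

weighted_centers <- function(q, w, weighting) {
  if (weighting == "printed") q * w else q * (1 - w)
}

#' Robust inverse covariance (MCD)
#'
#' Inverse of the minimum covariance determinant estimate of the column
#' covariance of `X`. The MCD subset search is randomized; the configured seed
#' is fixed immediately before it, so results are reproducible.
#'
#' @param X numeric matrix, rows (>= 5 x columns) are observations.
#' @param cfg an [md_config()].
#' @return inverse covariance matrix (columns x columns).
#' @export
robust_inverse_covariance <- function(X, cfg = md_config()) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 5L * p)
    stop_numeric("too few rows (", n, ") for a ", p, "-column covariance")
  dup <- duplicated(lapply(seq_len(p), function(j) X[, j]))
  if (any(dup))
    stop_numeric("singular covariance: identical columns ",
                 paste(which(dup), collapse = ", "))
  args <- list(x = X, method = "mcd")
  if (!is.null(cfg$mcd_support_fraction))
    args$quantile.used <- max(p + 1L, floor(cfg$mcd_support_fraction * n))
  set.seed(cfg$seed)
  cv <- do.call(MASS::cov.rob, args)$cov
  inv <- tryCatch(solve(cv), error = function(e) NULL)
  if (is.null(inv)) {
    r <- stats::cor(X)
    diag(r) <- 0
    bad <- which(abs(abs(r) - 1) < 1e-10, arr.ind = TRUE)
    stop_numeric("singular robust covariance",
                 if (nrow(bad)) paste0("; collinear columns ",
                                       paste(unique(sort(bad)), collapse = ", "))
                 else "")
  }
  inv
}

#' Per-point Mahalanobis distance (quadratic form)
#'
#' `MD_i = (s_i - mu_i)' Sigma^-1 (s_i - mu_i)`, evaluated row-wise with a
#' per-point center; chi-square distributed with M degrees of freedom when
#' `s_i - mu_i` is M-variate normal with covariance `Sigma`.
#'
#' @param s numeric matrix of points (rows) or a single vector.
#' @param mu centers: matrix conformable with `s`, a single vector, or 0.
#' @param sigma_inv inverse covariance matrix.
#' @return nonnegative numeric vector of squared distances.
#' @export
mahalanobis_dist <- function(s, mu, sigma_inv) {
  s <- if (is.matrix(s)) s else matrix(s, nrow = 1L)
  if (!is.matrix(mu)) mu <- matrix(mu, nrow = nrow(s), ncol = ncol(s),
                                   byrow = length(mu) == ncol(s))
  if (any(!is.finite(s)) || any(!is.finite(mu)) || any(!is.finite(sigma_inv)))
    stop_numeric("non-finite inputs to Mahalanobis distance")
  delta <- s - mu
  rowSums((delta %*% sigma_inv) * delta)
}

#' Two-pass weighted Mahalanobis test
#'
#' Pass 1 computes weighted Mahalanobis distances with an MCD covariance over
#' all bins, then removes bins exceeding the chi-square critical value at
#' `outlier_quantile` — extreme bins that would inflate the null covariance.
#' Pass 2 re-estimates the covariance on the survivors and recomputes the
#' distance for every bin (removed bins are still tested); p-values are the
#' upper-tail chi-square probabilities at `df` degrees of freedom.
#'
#' @param q bins x samples score matrix (fully observed).
#' @param cfg an [md_config()].
#' @return list with `md` (pass-2), `p`, `md_pass1`, `kept` (logical: survived
#'   pass 1), `w` (per-bin weights), `sigma_inv` (pass-2), `df`.
#' @export
two_pass_md <- function(q, cfg = md_config()) {
  q <- as.matrix(q)
  m <- ncol(q)
  df <- cfg$df %||% m
  pd <- pairwise_distances(q)
  mu <- weighted_centers(q, pd$w, cfg$weighting)
  sinv1 <- robust_inverse_covariance(q, cfg)
  md1 <- mahalanobis_dist(q, mu, sinv1)
  keep <- md1 <= stats::qchisq(cfg$outlier_quantile, df)
  if (mean(!keep) > 0.5)
    warning("more than 50% of bins removed in pass 1; null model suspect")
  sinv2 <- robust_inverse_covariance(q[keep, , drop = FALSE], cfg)
  md2 <- mahalanobis_dist(q, mu, sinv2)
  p <- stats::pchisq(md2, df, lower.tail = FALSE)
  list(md = md2, p = p, md_pass1 = md1, kept = keep, w = pd$w,
       sigma_inv = sinv2, df = df)
}

#' Replicate-variability covariate
#'
#' A per-bin Mahalanobis-type measure of how much replicates of the same
#' sample disagree, used as the independent covariate for weighted FDR
#' control. Distances are taken within replicates of the same sample only;
#' centers are `s_i^r * (1 - w_i)` with `w_i` from the maximum replicate
#' z-score; the inverse covariance is diagonal-masked (off-diagonal entries
#' zeroed) so each replicate contributes independently.
#'
#' @param r bins x replicates score matrix (quantile-normalized, fully
#'   observed), all replicates of all samples.
#' @param sample sample label of each column.
#' @param cfg an [md_config()].
#' @return numeric covariate vector, or `NULL` when any sample has fewer than
#'   2 replicates (the covariate is then unavailable and plain BH is used).
#' @export
replicate_covariate <- function(r, sample, cfg = md_config()) {
  r <- as.matrix(r)
  if (length(sample) != ncol(r)) stop_config("one sample label per column")
  tab <- table(sample)
  if (any(tab < 2L)) return(NULL)
  nrep <- ncol(r)
  d <- matrix(0, nrow(r), nrep)
  for (s in names(tab)) {
    cols <- which(sample == s)
    rs <- length(cols)
    for (cc in cols)
      d[, cc] <- sqrt(rowSums((r[, cols, drop = FALSE] - r[, cc])^2)) / (rs - 1)
  }
  z <- d
  for (cc in seq_len(nrep)) {
    sdd <- stats::sd(d[, cc])
    if (sdd == 0) {
      warning("replicate column ", cc,
              ": identical within-sample distances; z set to 0")
      z[, cc] <- 0
    } else {
      z[, cc] <- (d[, cc] - mean(d[, cc])) / sdd
    }
  }
  srw <- stats::pnorm(apply(z, 1L, max))
  dev <- r - r * (1 - srw)             # = r * srw
  sinv <- robust_inverse_covariance(r, cfg)
  rowSums(sweep(dev^2, 2L, diag(sinv), "*"))
}

# weighted BH: reject p_i <= w_i * k * alpha / n, i.e. BH on p / w
weighted_bh <- function(p, w) stats::p.adjust(pmin(p / w, 1), "BH")

# Iteratively learn per-stratum weights (mean 1 over hypotheses) maximizing
# BH discoveries at level alpha on the training split.
learn_stratum_weights <- function(p, g, nstrata, alpha, niter = 20L) {
  w <- rep(1, nstrata)
  ng <- pmax(tabulate(g, nbins = nstrata), 1L)
  n <- length(p)
  for (it in seq_len(niter)) {
    adj <- weighted_bh(p, w[g])
    r <- tabulate(g[adj <= alpha], nbins = nstrata)
    raw <- (r + 1) / ng
    w_new <- raw * n / sum(raw * tabulate(g, nbins = nstrata))
    if (max(abs(w_new - w)) < 1e-10) break
    w <- w_new
  }
  w
}

#' Multiple-testing adjustment, optionally covariate-weighted
#'
#' Without a covariate: Benjamini-Hochberg. With one: an
#' independent-hypothesis-weighting-style procedure — bins are stratified into
#' covariate quantile groups, per-group weights (budget: mean weight 1) are
#' learned by cross-fitting (weights applied to a fold are learned on the
#' other folds), and weighted BH is applied. A constant covariate degenerates
#' exactly to plain BH. Adjusted p-values are floored at the raw p-value.
#'
#' @param p p-values in `[0, 1]`.
#' @param covariate optional per-bin covariate, independent of p under the
#'   null (e.g. [replicate_covariate()]).
#' @param cfg an [md_config()].
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p, covariate = NULL, cfg = md_config()) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_numeric("p-values must be finite and in [0, 1]")
  if (is.null(covariate) || length(unique(covariate)) < 2L)
    return(stats::p.adjust(p, "BH"))
  if (length(covariate) != length(p))
    stop_config("covariate length != p length")
  breaks <- unique(stats::quantile(covariate,
                                   probs = seq(0, 1, length.out = cfg$ihw_nbins + 1L)))
  if (length(breaks) < 3L) return(stats::p.adjust(p, "BH"))
  g <- cut(covariate, breaks, include.lowest = TRUE, labels = FALSE)
  nstrata <- length(breaks) - 1L
  # deterministic fold striping along the covariate order: every fold spans
  # the covariate range and fold labels carry no RNG state
  fold <- (rank(covariate, ties.method = "first") - 1L) %% cfg$ihw_nfolds + 1L
  w <- rep(1, length(p))
  for (f in seq_len(cfg$ihw_nfolds)) {
    train <- fold != f
    wf <- learn_stratum_weights(p[train], g[train], nstrata,
                                alpha = cfg$fdr_threshold)
    w[!train] <- wf[g[!train]]
  }
  w <- w / mean(w)                      # enforce the unit budget exactly
  pmax(weighted_bh(p, w), p)
}

#' Label compartment transitions
#'
#' Two samples: `"A->B"` / `"B->A"` for sign flips; `"sA->wA"` / `"wA->sA"`
#' (and the B analogues) for strength changes without a flip, where strong (s)
#' vs weak (w) is the strict comparison of absolute scores (ties labelled as
#' rising). An exact zero score is boundary-inclusive A. More than two
#' samples: the per-sample A/B sign string plus the sample with the largest
#' absolute score, e.g. `"ABB:ESC"`.
#'
#' @param scores matrix of per-sample (post-normalization, replicate-averaged)
#'   scores, bins x samples, or a single vector for one bin.
#' @param samples sample names (defaults to column names).
#' @return character vector of labels.
#' @export
classify_transitions <- function(scores, samples = NULL) {
  scores <- if (is.matrix(scores)) scores else matrix(scores, nrow = 1L)
  samples <- samples %||% colnames(scores) %||%
    paste0("S", seq_len(ncol(scores)))
  m <- ncol(scores)
  if (m < 2L) stop_config("need >= 2 samples to classify transitions")
  comp <- ifelse(scores >= 0, "A", "B")
  if (m == 2L) {
    s1 <- scores[, 1L]; s2 <- scores[, 2L]
    out <- character(nrow(scores))
    flip <- comp[, 1L] != comp[, 2L]
    out[flip] <- paste0(comp[flip, 1L], "->", comp[flip, 2L])
    same <- !flip
    strong1 <- abs(s1) > abs(s2)
    out[same & strong1] <- paste0("s", comp[same & strong1, 1L], "->w",
                                  comp[same & strong1, 1L])
    out[same & !strong1] <- paste0("w", comp[same & !strong1, 1L], "->s",
                                   comp[same & !strong1, 1L])
    out
  } else {
    best <- samples[max.col(abs(scores), ties.method = "first")]
    paste0(apply(comp, 1L, paste, collapse = ""), ":", best)
  }
}

#' Fit the differential-compartment model
#'
#' The main entry point of the package. Takes replicate-level compartment
#' scores (from [compartment_scores()] per chromosome assembled with
#' [score_matrix()], or [load_precomputed_scores()]), quantile-normalizes all
#' columns together within each chromosome, averages replicates into sample
#' scores, and tests every fully observed bin genome-wide with the two-pass
#' weighted Mahalanobis statistic. When every sample has at least two
#' replicates, the replicate-variability covariate drives weighted FDR
#' control; otherwise plain BH is used.
#'
#' @param x a [score_matrix()] of per-replicate scores (`NA` = masked bins).
#' @param config an [md_config()].
#' @param design optional design data frame (`sample`, `replicate`) validated
#'   against the columns of `x`.
#' @param normalize set `FALSE` if `x` is already quantile-normalized.
#' @return A `compartment_diff` object: list with `results` (one row per
#'   tested bin: coordinates, per-sample scores, `dist`, `pvalue`, `padj`,
#'   `covariate`, `label`), `config`, `chisq_df`, `samples`, `mask`,
#'   `sample_scores`, `replicate_scores`, `kept`, `sigma_inv`, `call`.
#' @seealso [summary.compartment_diff()], [significant_bins()]
#' @export
diff_compartments <- function(x, config = md_config(), design = NULL,
                              normalize = TRUE) {
  stopifnot(inherits(x, "score_matrix"))
  qn <- if (normalize) quantile_normalize(x) else x
  avg <- average_replicates(qn, design)
  tested <- stats::complete.cases(avg$scores)
  if (sum(tested) < 5L * ncol(avg$scores))
    stop_numeric("too few fully observed bins (", sum(tested), ") to test")
  q <- avg$scores[tested, , drop = FALSE]
  tp <- two_pass_md(q, config)
  covariate <- replicate_covariate(qn$scores[tested, , drop = FALSE],
                                   qn$sample, config)
  padj <- adjust_pvalues(tp$p, covariate, config)
  labels <- classify_transitions(q, avg$sample)
  res <- data.frame(chrom = avg$bins$chrom[tested],
                    start = avg$bins$start[tested],
                    end = avg$bins$end[tested],
                    stringsAsFactors = FALSE)
  for (j in seq_along(avg$sample)) res[[avg$sample[j]]] <- q[, j]
  res$dist <- tp$md
  res$pvalue <- tp$p
  res$padj <- padj
  res$covariate <- if (is.null(covariate)) NA_real_ else covariate
  res$label <- labels
  structure(list(results = res, config = config, chisq_df = tp$df,
                 samples = avg$sample, mask = !tested,
                 sample_scores = avg, replicate_scores = qn,
                 kept = tp$kept, weights = tp$w, sigma_inv = tp$sigma_inv,
                 has_covariate = !is.null(covariate),
                 call = match.call()),
            class = "compartment_diff")
}

#' Significant differential bins
#'
#' @param fit a `compartment_diff` object.
#' @param fdr adjusted-p threshold (defaults to the fitted configuration's).
#' @return the rows of `fit$results` with `padj < fdr`.
#' @export
significant_bins <- function(fit, fdr = fit$config$fdr_threshold) {
  stopifnot(inherits(fit, "compartment_diff"))
  fit$results[fit$results$padj < fdr, , drop = FALSE]
}

#' @export
print.compartment_diff <- function(x, ...) {
  n <- nrow(x$results)
  sig <- sum(x$results$padj < x$config$fdr_threshold)
  cat("Differential compartment analysis\n")
  cat(sprintf("  samples: %s\n", paste(x$samples, collapse = ", ")))
  cat(sprintf("  bins tested: %d (%d masked)\n", n, sum(x$mask)))
  cat(sprintf("  chi-square df: %d; multiple testing: %s\n", x$chisq_df,
              if (x$has_covariate) "covariate-weighted BH (replicate covariate)"
              else "BH"))
  cat(sprintf("  significant at FDR %.2g: %d bin(s)\n",
              x$config$fdr_threshold, sig))
  invisible(x)
}

#' @export
summary.compartment_diff <- function(object, fdr = object$config$fdr_threshold,
                                     ...) {
  sig <- significant_bins(object, fdr)
  structure(list(n_tested = nrow(object$results), n_masked = sum(object$mask),
                 n_significant = nrow(sig), fdr = fdr,
                 transitions = if (nrow(sig)) table(sig$label) else table(character()),
                 samples = object$samples),
            class = "summary.compartment_diff")
}

#' @export
print.summary.compartment_diff <- function(x, ...) {
  cat(sprintf("%d bins tested (%d masked); %d significant at FDR %.2g\n",
              x$n_tested, x$n_masked, x$n_significant, x$fdr))
  if (length(x$transitions)) {
    cat("transitions among significant bins:\n")
    print(x$transitions)
  }
  invisible(x)
}

#' @export
as.data.frame.compartment_diff <- function(x, ...) x$results

#' @export
plot.compartment_diff <- function(x, ...) {
  r <- x$results
  sig <- r$padj < x$config$fdr_threshold
  if (length(x$samples) == 2L) {
    graphics::plot(r[[x$samples[1L]]], r[[x$samples[2L]]],
                   col = ifelse(sig, "red", "grey50"),
                   pch = 20, cex = 0.4,
                   xlab = paste(x$samples[1L], "score"),
                   ylab = paste(x$samples[2L], "score"), ...)
    graphics::abline(h = 0, v = 0, lty = 3)
  } else {
    graphics::plot(r$dist, col = ifelse(sig, "red", "grey50"), pch = 20,
                   cex = 0.4, xlab = "tested bin", ylab = "Mahalanobis distance",
                   ...)
  }
  invisible(x)
}
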