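# Synthetic Hi-C generator: distance-decay cis maps with plaid compartment
# structure, several conditions with replicates, and planted differential
# truth (sign flips and strength shifts), so every pipeline stage can be
# validated against known ground truth without external data.

#' Simulation specification
#'
#' Expected contact intensity between bins i and j is
#' `lambda_ij \propto |i - j|^(-decay_exponent) * (1 + affinity * a_i * a_j)`
#' (diagonal at the distance-1 intensity), scaled to `depth` expected reads
#' per map; counts are independent Poisson draws per pair, symmetrized.
#' `a` is a blockwise alternating-sign compartment track; differential bins
#' are planted as sign flips or absolute-value shifts in the last condition.
#'
#' @param n_bins bins per (single) chromosome.
#' @param resolution bin width in bp (default 100 kb).
#' @param decay_exponent power-law distance-decay exponent (> 0, default 1).
#' @param affinity plaid strength `delta >= 0` (default 1).
#' @param depth expected total reads per map (default 5e6).
#' @param n_conditions,n_replicates experimental design (defaults 2 x 2).
#' @param flip_fraction fraction of bins whose compartment sign flips in the
#'   altered condition (must be <= 0.5; exact count `round(flip_fraction *
#'   n_bins)`).
#' @param shift_fraction fraction of bins with a strength shift (no flip).
#' @param shift_factor multiplier in (0, 1] applied to `|a|` on shifted bins.
#' @param overdispersion optional negative-binomial overdispersion (counts
#'   drawn with `size = 1/overdispersion`); `NULL` = Poisson.
#' @param block_mean mean compartment block length in bins (blocks >= 5).
#' @param seed integer seed governing tracks and replicate draws.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_bins = 2000L, resolution = 1e5,
                            decay_exponent = 1, affinity = 1, depth = 5e6,
                            n_conditions = 2L, n_replicates = 2L,
                            flip_fraction = 0, shift_fraction = 0,
                            shift_factor = 0.5, overdispersion = NULL,
                            block_mean = 20, seed = 1L) {
  if (decay_exponent <= 0) stop_config("decay_exponent must be > 0")
  if (affinity < 0) stop_config("affinity must be >= 0")
  if (flip_fraction > 0.5)
    stop_config("flip_fraction > 0.5 would swamp the null")
  if (shift_factor <= 0 || shift_factor > 1)
    stop_config("shift_factor must be in (0, 1]")
  if (block_mean < 5) stop_config("block_mean must be >= 5")
  structure(list(n_bins = as.integer(n_bins), resolution = resolution,
                 decay_exponent = decay_exponent, affinity = affinity,
                 depth = depth, n_conditions = as.integer(n_conditions),
                 n_replicates = as.integer(n_replicates),
                 flip_fraction = flip_fraction,
                 shift_fraction = shift_fraction,
                 shift_factor = shift_factor,
                 overdispersion = overdispersion,
                 block_mean = block_mean, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate compartment tracks with planted truth
#'
#' Builds a blockwise alternating-sign base track. Block magnitudes are drawn
#' uniformly in `[0.05, 0.95]`: the upper cap keeps plaid intensities strictly
#' positive at affinity 1, and the continuous range emulates the broad,
#' hole-free distribution of real compartment scores (a bimodal track with no
#' weak compartments would be unrealistic and would break any robust
#' covariance estimate downstream).
#' then plants `round(flip_fraction * n)` sign-flipped bins and
#' `round(shift_fraction * n)` strength-shifted bins (contiguous runs drawn
#' from distinct blocks) in the last condition. The GC covariate is a
#' monotone function of the condition-average track plus noise — so
#' covariate-driven component orientation is testable — and gene density is
#' Poisson with a log-link on the same average.
#'
#' @param spec a [simulation_spec()].
#' @return list with `tracks` (bins x conditions), `truth` (`"null"`,
#'   `"flip"`, `"shift"` per bin), `gc`, `genes`, `bins` ([genome_bins()]),
#'   and `condition` names.
#' @export
simulate_tracks <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_bins
  sizes <- integer(0)
  while (sum(sizes) < n)
    sizes <- c(sizes, 5L + stats::rgeom(1L, 1 / (spec$block_mean - 4)))
  nb <- length(sizes)
  block <- rep(seq_len(nb), sizes)[seq_len(n)]
  sign0 <- rep_len(c(1, -1), nb)[block]
  mag <- stats::runif(nb, 0.05, 0.95)[block]
  base <- sign0 * mag

  m_flip <- round(spec$flip_fraction * n)
  m_shift <- round(spec$shift_fraction * n)
  ord <- sample.int(nb)
  truth <- rep("null", n)
  pick_bins <- function(budget, label) {
    for (b in ord) {
      if (budget <= 0L) break
      idx <- which(block == b & truth == "null")
      if (length(idx) == 0L) next
      take <- idx[seq_len(min(budget, length(idx)))]
      truth[take] <<- label
      budget <- budget - length(take)
    }
    if (budget > 0L) stop_config("not enough null bins to plant truth")
  }
  pick_bins(m_flip, "flip")
  pick_bins(m_shift, "shift")

  tracks <- matrix(rep(base, spec$n_conditions), ncol = spec$n_conditions)
  alt <- spec$n_conditions
  tracks[truth == "flip", alt] <- -tracks[truth == "flip", alt]
  tracks[truth == "shift", alt] <- tracks[truth == "shift", alt] * spec$shift_factor
  condition <- paste0("cond", seq_len(spec$n_conditions))
  colnames(tracks) <- condition

  avg <- rowMeans(tracks)
  gc <- pmin(1, pmax(0, 0.40 + 0.06 * avg + stats::rnorm(n, 0, 0.01)))
  genes <- stats::rpois(n, exp(0.7 + 0.7 * avg))
  starts <- (seq_len(n) - 1L) * spec$resolution
  bins <- genome_bins(rep("chrS", n), starts, starts + spec$resolution,
                      id = seq_len(n))
  list(tracks = tracks, truth = truth, gc = gc, genes = genes, bins = bins,
       condition = condition)
}

#' Simulate one contact map
#'
#' Poisson (or negative-binomial) draws around the plaid distance-decay
#' intensity for one condition track, symmetrized; the intensity matrix is
#' scaled so the expected total count (upper triangle with diagonal) equals
#' the target depth.
#'
#' @param track compartment track `a` for this condition.
#' @param spec a [simulation_spec()].
#' @param replicate_seed seed for this replicate's draws.
#' @param sample,replicate labels stored on the map.
#' @param noiseless return the (non-integer) expected intensity matrix itself
#'   instead of sampling — useful for exact invariance checks.
#' @return A [contact_map()].
#' @export
simulate_map <- function(track, spec, replicate_seed = spec$seed,
                         sample = NA_character_, replicate = NA_character_,
                         noiseless = FALSE) {
  n <- length(track)
  plaid <- 1 + spec$affinity * outer(track, track)
  if (any(plaid <= 0))
    stop_config("invalid affinity: 1 + affinity * a_i * a_j <= 0")
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  lam <- pmax(d, 1L)^(-spec$decay_exponent) * plaid
  ut <- upper.tri(lam, diag = TRUE)
  lam <- lam * (spec$depth / sum(lam[ut]))
  if (noiseless) {
    m <- lam
  } else {
    set.seed(replicate_seed)
    draws <- if (is.null(spec$overdispersion))
      stats::rpois(sum(ut), lam[ut])
    else
      stats::rnbinom(sum(ut), mu = lam[ut], size = 1 / spec$overdispersion)
    m <- matrix(0, n, n)
    m[ut] <- draws
    m <- m + t(m)
    diag(m) <- diag(m) / 2
  }
  contact_map(m, "chrS", sample, replicate)
}

replicate_seed <- function(spec, cond, rep)
  spec$seed + 7919L * ((cond - 1L) * spec$n_replicates + rep)

#' Simulate a full multi-condition experiment
#'
#' Generates tracks plus one map per condition and replicate; optionally
#' writes the exact on-disk formats the pipeline reads (bins BED, sparse
#' triplet matrices, design TSV, truth BED, covariate bedGraphs) to `dir`.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory, or `NULL` for in-memory only.
#' @return list with `tracks` (see [simulate_tracks()]), `maps` (list of
#'   [contact_map()]s), and — when written — `files` (named paths) and
#'   `design` (data frame `file`, `sample`, `replicate`).
#' @export
simulate_experiment <- function(spec, dir = NULL) {
  tr <- simulate_tracks(spec)
  maps <- list()
  design <- NULL
  for (ci in seq_len(spec$n_conditions)) {
    for (ri in seq_len(spec$n_replicates)) {
      map <- simulate_map(tr$tracks[, ci], spec, replicate_seed(spec, ci, ri),
                          sample = tr$condition[ci], replicate = paste0("rep", ri))
      maps[[length(maps) + 1L]] <- map
      design <- rbind(design, data.frame(
        file = sprintf("%s_rep%d.matrix", tr$condition[ci], ri),
        sample = tr$condition[ci], replicate = paste0("rep", ri),
        stringsAsFactors = FALSE))
    }
  }
  out <- list(tracks = tr, maps = maps, design = design)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    bins_path <- file.path(dir, "bins.bed")
    utils::write.table(data.frame(tr$bins$chrom, tr$bins$start, tr$bins$end,
                                  tr$bins$id),
                       bins_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    for (k in seq_along(maps))
      write_contact_matrix(maps[[k]], tr$bins, file.path(dir, design$file[k]))
    design_path <- file.path(dir, "design.tsv")
    utils::write.table(design, design_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    diffb <- tr$truth != "null"
    truth_path <- file.path(dir, "truth.bed")
    utils::write.table(data.frame(tr$bins$chrom[diffb], tr$bins$start[diffb],
                                  tr$bins$end[diffb], tr$truth[diffb]),
                       truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    gc_path <- file.path(dir, "gc.bedgraph")
    write_scores_bedgraph(tr$bins, tr$gc, gc_path)
    genes_path <- file.path(dir, "genes.bedgraph")
    write_scores_bedgraph(tr$bins, as.numeric(tr$genes), genes_path)
    out$files <- list(bins = bins_path, design = design_path,
                      truth = truth_path, gc = gc_path, genes = genes_path,
                      dir = dir)
  }
  out
}

#' Binomially thin a contact map
#'
#' Keeps each read independently with probability `fraction` — the standard
#' down-sampling model for sequencing depth.
#'
#' @param map a [contact_map()] with integer counts.
#' @param fraction retention probability in (0, 1].
#' @param seed RNG seed.
#' @return A [contact_map()] at reduced depth.
#' @export
thin_map <- function(map, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop_config("fraction must be in (0, 1]")
  set.seed(seed)
  n <- nrow(map$counts)
  ut <- upper.tri(map$counts, diag = TRUE)
  m <- matrix(0, n, n)
  m[ut] <- stats::rbinom(sum(ut), as.integer(round(map$counts[ut])), fraction)
  m <- m + t(m)
  diag(m) <- diag(m) / 2
  contact_map(m, map$chrom, map$sample, map$replicate)
}
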