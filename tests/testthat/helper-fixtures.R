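# Shared fixtures built in code at test time.

# small contiguous bin grid
make_bins <- function(n = 3L, res = 100000, chrom = "chr1", id = TRUE) {
  starts <- (seq_len(n) - 1L) * res
  genome_bins(rep(chrom, n), starts, starts + res,
              id = if (id) seq_len(n) else NULL)
}

# random symmetric nonnegative integer contact matrix
random_counts <- function(n, seed = 1L, lambda = 5) {
  set.seed(seed)
  m <- matrix(0, n, n)
  ut <- upper.tri(m, diag = TRUE)
  m[ut] <- stats::rpois(sum(ut), lambda)
  m <- m + t(m)
  diag(m) <- diag(m) / 2
  m
}

# wrap a raw symmetric matrix as an oe_matrix with nothing masked
as_oe <- function(m, chrom = "chr1") {
  structure(list(oe = m, mask = rep(FALSE, nrow(m)),
                 expected = NULL, chrom = chrom),
            class = "oe_matrix")
}

# score every replicate map of a simulated experiment
score_simulation <- function(sim, ...) {
  tr <- sim$tracks
  score_maps(sim$maps, tr$bins, tr$gc, as.numeric(tr$genes), ...)
}

# brute-force per-point quadratic form (s_i - mu_i)' Sinv (s_i - mu_i)
loop_quadform <- function(s, mu, sinv) {
  vapply(seq_len(nrow(s)), function(i) {
    d <- s[i, ] - mu[i, ]
    as.numeric(t(d) %*% sinv %*% d)
  }, 0)
}
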