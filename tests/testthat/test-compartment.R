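test_that("O/E transform divides by per-diagonal means", {
  m <- contact_map(matrix(c(4, 2, 2, 4), 2), "chr1")
  expect_equal(oe_transform(m)$oe, matrix(1, 2, 2))

  # hand oracle: diagonal mean 16/3, offset-1 mean 2, offset-2 mean 1
  m3 <- contact_map(matrix(c(4, 2, 1, 2, 8, 2, 1, 2, 4), 3), "chr1")
  oe <- oe_transform(m3)$oe
  expect_equal(diag(oe), c(0.75, 1.5, 0.75))
  expect_equal(oe[cbind(1:2, 2:3)], c(1, 1))
  expect_equal(oe[1, 3], 1)
})

test_that("bins with empty rows are masked and O/E computed on the rest", {
  counts <- matrix(c(4, 2, 0, 2, 4, 0, 0, 0, 0), 3)
  oe <- oe_transform(contact_map(counts, "chr1"))
  expect_equal(oe$mask, c(FALSE, FALSE, TRUE))
  expect_equal(oe$oe[1:2, 1:2], matrix(1, 2, 2))
  expect_error(oe_transform(contact_map(matrix(0, 3, 3), "chr1")),
               class = "hicomp_numeric_error")
})

test_that("correlation matrix equals a brute-force two-pass Pearson oracle", {
  m <- random_counts(5, seed = 3, lambda = 4)
  cm <- correlation_matrix(as_oe(m))
  oracle <- matrix(NA_real_, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    xi <- m[i, ]; xj <- m[j, ]
    oracle[i, j] <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
  }
  expect_equal(cm$corr, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(diag(cm$corr), rep(1, 5))
})

test_that("proportional rows correlate at 1, reflected rows at -1, constants are masked", {
  x <- c(1, 4, 2)
  m <- rbind(x, 3 * x, 2 * mean(x) - x)   # proportional / reflected around the mean
  got <- correlation_matrix(as_oe(m))$corr
  expect_equal(got[1, 2], 1)
  expect_equal(got[1, 3], -1)
  expect_true(all(got >= -1 - 1e-12 & got <= 1 + 1e-12))
  # constant rows get masked
  m2 <- random_counts(5, seed = 4)
  m2[3, ] <- 7; m2[, 3] <- 7
  cm2 <- correlation_matrix(as_oe(m2))
  expect_true(cm2$mask[3])
  expect_equal(dim(cm2$corr), c(4, 4))
})

test_that("partial SVD matches a dense eigendecomposition oracle", {
  set.seed(5)
  v <- rnorm(30); v <- v / sqrt(sum(v^2))
  x <- 4 * tcrossprod(v) + diag(30)
  corr <- structure(list(corr = x, mask = rep(FALSE, 30), chrom = "chr1"),
                    class = "correlation_matrix")
  ps <- partial_svd(corr, k = 2)
  # leading component parallel to the planted direction
  expect_gt(abs(sum(ps$v[, 1] * v)), 1 - 1e-6)
  # singular values match dense oracle, nonincreasing
  dense <- eigen(x, symmetric = TRUE)
  expect_equal(ps$d, abs(dense$values[1:2]), tolerance = 1e-8)
  expect_true(all(diff(ps$d) <= 1e-12))
  # orthonormal retained columns
  expect_lt(max(abs(crossprod(ps$v) - diag(2))), 1e-8)
  # top-k reconstruction agrees with the oracle's
  rec <- ps$u %*% diag(ps$d) %*% t(ps$v)
  rec_oracle <- dense$vectors[, 1:2] %*% diag(dense$values[1:2]) %*%
    t(dense$vectors[, 1:2])
  expect_equal(rec, rec_oracle, tolerance = 1e-8)
  # symmetric PSD input: U equals V
  expect_equal(ps$u, ps$v)
  # PC definition: projection of the matrix on the right singular vectors
  expect_equal(ps$pc, x %*% ps$v)
  expect_error(partial_svd(corr, k = 1), class = "hicomp_config_error")
})

test_that("component selection maximizes summed covariate correlation and GC sets the sign", {
  set.seed(8)
  n <- 60
  good <- sin(seq_len(n) / 3)
  noise <- rnorm(n)
  pcs <- structure(list(pc = cbind(noise, good), mask = rep(FALSE, n),
                        chrom = "chr1"), class = "pc_result")
  gc <- good * 0.05 + rnorm(n, 0, 0.005)
  genes <- good * 2 + rnorm(n, 0, 0.2)
  so <- select_and_orient(pcs, gc, genes)
  expect_equal(so$component, 2L)
  expect_equal(so$sign, 1)
  # negative GC correlation flips the component
  so2 <- select_and_orient(pcs, -gc, -genes)
  expect_equal(so2$sign, -1)
  expect_equal(so2$score, -so$score)
  # orientation contract: the returned score correlates nonnegatively with GC
  expect_gte(cor(so2$score, -gc), 0)
  expect_error(select_and_orient(pcs, rep(1, n), rep(2, n)),
               class = "hicomp_numeric_error")
})

test_that("compartment scores are invariant to sequencing depth scaling", {
  spec <- simulation_spec(n_bins = 120, depth = 2e6, affinity = 1, seed = 2)
  tr <- simulate_tracks(spec)
  map <- simulate_map(tr$tracks[, 1], spec, noiseless = TRUE)
  s1 <- compartment_scores(map, tr$gc, as.numeric(tr$genes))$score
  scaled <- contact_map(map$counts * 4.2, map$chrom)
  s2 <- compartment_scores(scaled, tr$gc, as.numeric(tr$genes))$score
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("scores are equivariant under bin permutation downstream of O/E", {
  set.seed(10)
  spec <- simulation_spec(n_bins = 80, depth = 2e6, affinity = 1, seed = 6)
  tr <- simulate_tracks(spec)
  map <- simulate_map(tr$tracks[, 1], spec, 77)
  oe <- oe_transform(map)
  score <- select_and_orient(partial_svd(correlation_matrix(oe)),
                             tr$gc, as.numeric(tr$genes))$score
  perm <- sample(nrow(map$counts))
  oe_p <- structure(list(oe = oe$oe[perm, perm], mask = oe$mask[perm],
                         expected = oe$expected, chrom = oe$chrom),
                    class = "oe_matrix")
  score_p <- select_and_orient(partial_svd(correlation_matrix(oe_p)),
                               tr$gc[perm], as.numeric(tr$genes)[perm])$score
  expect_equal(score_p[order(perm)], score, tolerance = 1e-8)
})

test_that("tiny chromosomes are skipped with a warning", {
  m <- contact_map(random_counts(6, seed = 1), "chr1")
  expect_warning(cs <- compartment_scores(m, runif(6), rpois(6, 2)),
                 "skipping")
  expect_true(all(is.na(cs$score)))
})
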