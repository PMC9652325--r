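test_that("pairwise distances follow the root-sum-square definition", {
  # two samples: d is symmetric and equals |q1 - q2|
  pd <- pairwise_distances(cbind(c(1, 0, 2), c(3, 0, 1)))
  expect_equal(unname(pd$d[1, ]), c(2, 2))
  # three samples, bin scores (0, 1, 2)
  pd3 <- pairwise_distances(rbind(c(0, 1, 2), c(0.1, 1, 2), c(0, 0.9, 2.2)))
  expect_equal(unname(pd3$d[1, ]), c(sqrt(5) / 2, sqrt(2) / 2, sqrt(5) / 2))
  # brute-force oracle on a random instance
  set.seed(1)
  q <- matrix(rnorm(40), 10)
  pd4 <- pairwise_distances(q)
  for (n in 1:4) for (i in 1:10)
    expect_equal(pd4$d[i, n],
                 sqrt(sum((q[i, ] - q[i, n])^2)) / 3)
  # a bin at the mean per-sample distance has weight pnorm(0) = 0.5
  zmax <- apply(pd4$z, 1, max)
  expect_equal(pd4$w, pnorm(zmax))
  expect_true(all(pd4$w > 0 & pd4$w < 1))
})

test_that("MCD inverse covariance matches the classical estimate on clean data and resists outliers", {
  set.seed(11)
  sigma <- matrix(c(2, 1.2, 1.2, 1.5), 2)
  l <- chol(sigma)
  x <- matrix(rnorm(10000), ncol = 2) %*% l
  inv_mcd <- robust_inverse_covariance(x, md_config(seed = 4))
  inv_cls <- solve(cov(x))
  expect_true(all(abs(inv_mcd - inv_cls) / abs(inv_cls) < 0.10))

  # 10% gross outliers: MCD covariance closer to the truth than classical
  xo <- x
  xo[1:500, ] <- matrix(rnorm(1000, mean = 12, sd = 0.5), ncol = 2)
  cov_mcd <- solve(robust_inverse_covariance(xo, md_config(seed = 4)))
  frob <- function(m) sqrt(sum(m^2))
  expect_lt(frob(cov_mcd - sigma), frob(cov(xo) - sigma))

  expect_error(robust_inverse_covariance(cbind(x[, 1], x[, 1]), md_config()),
               class = "hicomp_numeric_error")
  expect_error(robust_inverse_covariance(x[1:5, ], md_config()),
               class = "hicomp_numeric_error")
})

test_that("the Mahalanobis quadratic form matches a naive loop oracle", {
  set.seed(21)
  s <- matrix(rnorm(80), ncol = 4)
  mu <- matrix(rnorm(80), ncol = 4)
  a <- matrix(rnorm(16), 4)
  sinv <- crossprod(a) + diag(4)
  md <- mahalanobis_dist(s, mu, sinv)
  expect_equal(md, loop_quadform(s, mu, sinv), tolerance = 1e-8)
  expect_true(all(md >= 0))
  expect_equal(mahalanobis_dist(s, s, sinv), rep(0, 20))
  # verbatim-equation weighting with w = 1 centers every point on itself
  q <- matrix(rnorm(10), ncol = 2)
  expect_equal(unname(q * 1), hicomp:::weighted_centers(q, rep(1, 5), "printed"))
  expect_error(mahalanobis_dist(matrix(c(1, NA), 1), 0, diag(2)),
               class = "hicomp_numeric_error")
})

test_that("Mahalanobis distance is invariant under consistent affine recoding", {
  set.seed(31)
  s <- matrix(rnorm(60), ncol = 3)
  mu <- matrix(rnorm(60), ncol = 3)
  sigma <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  a <- matrix(rnorm(9), 3) + 2 * diag(3)   # invertible recoding
  b <- rnorm(3)
  md0 <- mahalanobis_dist(s, mu, solve(sigma))
  s2 <- sweep(s %*% t(a), 2, b, "+")
  mu2 <- sweep(mu %*% t(a), 2, b, "+")
  md1 <- mahalanobis_dist(s2, mu2, solve(a %*% sigma %*% t(a)))
  expect_equal(md0, md1, tolerance = 1e-6)
})

test_that("two-pass testing recomputes covariance without first-pass outliers", {
  set.seed(41)
  n <- 600
  base <- rnorm(n)
  q <- cbind(base + rnorm(n, sd = 0.1), base + rnorm(n, sd = 0.1))
  q[1:12, 2] <- q[1:12, 1] + 5     # planted extreme disagreement
  tp <- two_pass_md(q, md_config(seed = 4))
  expect_equal(tp$p, pchisq(tp$md, tp$df, lower.tail = FALSE))
  expect_equal(tp$df, 2L)
  # chi-square survival closed form at df = 2: p = exp(-MD/2)
  expect_equal(tp$p, exp(-tp$md / 2), tolerance = 1e-12)
  expect_false(any(tp$kept[1:12]))
  # removing the planted outliers tightens the null: their pass-2 MD grows
  expect_true(all(tp$md[1:12] >= tp$md_pass1[1:12]))
  # MD = 0 would give p = 1
  expect_equal(pchisq(0, 2, lower.tail = FALSE), 1)
})

test_that("replicate covariate equals a direct evaluation of its defining formulas", {
  set.seed(51)
  n <- 200
  r <- cbind(rnorm(n), rnorm(n), rnorm(n), rnorm(n))
  sample <- c("a", "a", "b", "b")
  cfg <- md_config(seed = 9)
  got <- replicate_covariate(r, sample, cfg)

  # oracle: within-sample distances, per-column z, max-z weight, diag-masked form
  d <- matrix(0, n, 4)
  for (cc in 1:4) {
    cols <- which(sample == sample[cc])
    for (i in 1:n)
      d[i, cc] <- sqrt(sum((r[i, cols] - r[i, cc])^2)) / (length(cols) - 1)
  }
  z <- scale(d)
  srw <- pnorm(apply(z, 1, max))
  sinv <- robust_inverse_covariance(r, cfg)
  oracle <- sapply(1:n, function(i) {
    dev <- r[i, ] - r[i, ] * (1 - srw[i])
    sum(dev^2 * diag(sinv))           # off-diagonal entries contribute nothing
  })
  expect_equal(got, oracle, tolerance = 1e-8)
  expect_true(all(got >= 0))

  # all replicate scores zero at a bin -> zero covariate
  r2 <- r; r2[7, ] <- 0
  expect_equal(replicate_covariate(r2, sample, cfg)[7], 0)

  # any sample without >= 2 replicates: covariate unavailable
  expect_null(replicate_covariate(r[, 1:3], c("a", "a", "b"), cfg))
})

test_that("BH adjustment reproduces the step-up computation and degrades gracefully", {
  p <- c(0.01, 0.03, 0.04, 0.5)
  expect_equal(adjust_pvalues(p), c(0.04, 0.0533, 0.0533, 0.5),
               tolerance = 1e-3)
  # constant covariate falls back to plain BH exactly
  expect_identical(adjust_pvalues(p, covariate = rep(3, 4)),
                   stats::p.adjust(p, "BH"))
  expect_error(adjust_pvalues(c(0.5, 1.2)), class = "hicomp_numeric_error")
})

test_that("an informative covariate never loses discoveries and keeps padj >= p", {
  set.seed(61)
  n <- 4000
  covariate <- runif(n)
  signal <- covariate < 0.2 & runif(n) < 0.5    # signal enriched at low covariate
  p <- ifelse(signal, rbeta(n, 0.05, 1), runif(n))
  cfg <- md_config(seed = 2)
  adj_w <- adjust_pvalues(p, covariate, cfg)
  adj_bh <- stats::p.adjust(p, "BH")
  expect_gte(sum(adj_w < 0.1), sum(adj_bh < 0.1))
  expect_true(all(adj_w >= p - 1e-12))
})

test_that("transition labels follow the strong/weak sign taxonomy", {
  expect_equal(classify_transitions(c(2, -1)), "A->B")
  expect_equal(classify_transitions(c(-1, 2)), "B->A")
  expect_equal(classify_transitions(c(2, 0.5)), "sA->wA")
  expect_equal(classify_transitions(c(0.5, 2)), "wA->sA")
  expect_equal(classify_transitions(c(-0.2, -1.5)), "wB->sB")
  expect_equal(classify_transitions(c(-1.5, -0.2)), "sB->wB")
  # exact zero is boundary-inclusive A
  expect_equal(classify_transitions(c(0, -1)), "A->B")
  # multi-sample: sign string plus strongest sample
  lab <- classify_transitions(matrix(c(2, -1, 0.5), 1),
                              samples = c("x", "y", "z"))
  expect_equal(lab, "ABA:x")
})

test_that("the fitted differential object exposes results, summary and labels", {
  set.seed(71)
  spec <- simulation_spec(n_bins = 150, depth = 2e6, affinity = 1,
                          flip_fraction = 0.1, seed = 13)
  sim <- simulate_experiment(spec)
  fit <- diff_compartments(score_simulation(sim), md_config(seed = 3))
  expect_s3_class(fit, "compartment_diff")
  res <- as.data.frame(fit)
  expect_true(all(c("chrom", "start", "end", "cond1", "cond2", "dist",
                    "pvalue", "padj", "covariate", "label") %in% names(res)))
  expect_equal(nrow(res), sum(!fit$mask))
  expect_true(all(res$padj >= res$pvalue - 1e-12))
  expect_true(fit$has_covariate)       # 2 replicates per condition
  s <- summary(fit)
  expect_s3_class(s, "summary.compartment_diff")
  expect_output(print(fit), "Differential compartment")
  sig <- significant_bins(fit)
  expect_true(all(sig$padj < fit$config$fdr_threshold))
})
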