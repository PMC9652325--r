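make_records <- function() {
  data.frame(chrom = "chr1", binA = c(0L, 2L, 5L), binB = c(3L, 4L, 6L),
             stringsAsFactors = FALSE)
}

test_that("interactions are kept when either anchor hits a differential bin", {
  rec <- make_records()
  sig <- data.frame(chrom = "chr1", index = c(3L, 5L))
  kept <- overlap_filter(rec, sig)
  expect_equal(kept$binA, c(0L, 5L))        # record 2 has no anchor in {3, 5}
  # both anchors overlapping -> kept once
  sig2 <- data.frame(chrom = "chr1", index = c(5L, 6L))
  expect_equal(nrow(overlap_filter(rec, sig2)), 1L)
  # subset + idempotence
  expect_equal(overlap_filter(kept, sig), kept)
  expect_true(all(rownames(kept) %in% rownames(rec)))
})

test_that("overlap filtering accepts coordinate-based significant bins", {
  rec <- make_records()
  bins <- make_bins(8)
  sig <- data.frame(chrom = "chr1", start = 3e5, end = 4e5)
  expect_equal(overlap_filter(rec, sig, bins)$binB, 3L)
})

test_that("interaction log2(O/E) uses the shared per-distance expected model", {
  counts <- random_counts(30, seed = 7, lambda = 8)
  map <- contact_map(counts, "chr1")
  rec <- data.frame(binA = c(0L, 3L, 10L), binB = c(5L, 3L, 22L))
  got <- interaction_oe(map, rec, pseudocount = 0)
  # oracle: per-diagonal mean over the full (unmasked) matrix
  oracle <- sapply(seq_len(nrow(rec)), function(k) {
    dd <- rec$binB[k] - rec$binA[k]
    pairs <- which(abs(row(counts) - col(counts)) == dd)
    log2(counts[rec$binA[k] + 1, rec$binB[k] + 1] / mean(counts[pairs]))
  })
  expect_equal(got, oracle, tolerance = 1e-10)
  # obs == exp -> 0; obs = 2 exp -> 1 (pseudocount-free on positive values)
  flat <- contact_map(matrix(3, 4, 4), "chr1")
  rec2 <- data.frame(binA = 0L, binB = 2L)
  expect_equal(interaction_oe(flat, rec2, pseudocount = 0), 0)
  doubled <- flat$counts; doubled[1, 3] <- doubled[3, 1] <- 6
  expect_equal(interaction_oe(contact_map(doubled, "chr1"), rec2,
                              pseudocount = 0),
               log2(6 / mean(doubled[abs(row(doubled) - col(doubled)) == 2])))
  expect_error(interaction_oe(flat, data.frame(binA = 0L, binB = 9L)),
               class = "hicomp_format_error")
})

test_that("interaction MD matches the quadratic-form oracle and respects relabeling", {
  set.seed(17)
  oe <- matrix(rnorm(60 * 3), ncol = 3)
  cfg <- md_config(seed = 5)
  res <- md_interactions(oe, cfg, robust = FALSE)
  mu <- colMeans(oe)
  sinv <- solve(cov(oe))
  oracle <- loop_quadform(oe, matrix(mu, nrow(oe), 3, byrow = TRUE), sinv)
  expect_equal(res$dist, oracle, tolerance = 1e-8)
  expect_equal(res$pvalue, pchisq(res$dist, 3, lower.tail = FALSE))
  # a record at the centers scores zero
  oe2 <- rbind(oe, mu)
  res2 <- md_interactions(oe2, cfg, robust = FALSE)
  expect_lt(res2$dist[61], 1e-8)
  expect_equal(res2$pvalue[61], 1)
  # sample relabeling: distances unchanged
  res3 <- md_interactions(oe[, c(2, 3, 1)], cfg, robust = FALSE)
  expect_equal(res3$dist, res$dist, tolerance = 1e-10)
  expect_error(md_interactions(oe[1:5, ], cfg), class = "hicomp_numeric_error")
})

test_that("near-identical samples yield no differential interactions", {
  set.seed(19)
  base <- rnorm(80)
  eps <- 1e-3
  oe <- cbind(base, base + rnorm(80, sd = eps), base + rnorm(80, sd = eps))
  res <- md_interactions(oe, md_config(seed = 5), robust = FALSE)
  expect_equal(sum(res$padj < 0.05), 0L)
})

test_that("FitHiC-style interaction lists load as the union of bin pairs", {
  bins <- make_bins(10)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeLines(c("chr1\t50000\t chr1\t350000\t10\t0.001",
               "chr1\t250000\tchr1\t450000\t8\t0.01"), f1)
  writeLines(c("chr1\t50000\tchr1\t350000\t12\t0.002",
               "chr1\t550000\tchr1\t650000\t5\t0.04"), f2)
  rec <- read_interactions(c(f1, f2), bins)
  expect_equal(nrow(rec), 3L)          # shared pair counted once
  expect_true(all(rec$binA <= rec$binB))
  f3 <- withr::local_tempfile()
  writeLines("chr1\t50000\tchr1\t5000000\t3\t0.2", f3)  # beyond the grid
  expect_error(read_interactions(f3, bins), class = "hicomp_format_error")
})

test_that("the full differential-interaction wrapper ties the pieces together", {
  set.seed(23)
  spec <- simulation_spec(n_bins = 60, depth = 1e6, affinity = 1, seed = 29)
  tr <- simulate_tracks(spec)
  maps <- list(simulate_map(tr$tracks[, 1], spec, 1, "s1", "r1"),
               simulate_map(tr$tracks[, 1], spec, 2, "s2", "r1"))
  rec <- data.frame(chrom = "chrS", binA = 0:49, binB = 5:54)
  sig <- data.frame(chrom = "chrS", index = seq(0L, 50L, 5L))
  out <- diff_interactions(maps, rec, sig, tr$bins)
  expect_true(all(c("binA", "binB", "s1", "s2", "dist", "pvalue", "padj")
                  %in% names(out)))
  expect_true(nrow(out) >= 10)
  expect_true(all(out$padj >= out$pvalue - 1e-12))
})
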