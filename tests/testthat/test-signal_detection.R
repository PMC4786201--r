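test_that("call_dimps thresholds the fitted null tail", {
  set.seed(21)
  spec <- sim_spec(n_sites = 10000, seed = 21)
  pair <- simulate_pair(spec)
  mat <- build_matrix(list(pair$reference, pair$query))
  calls <- call_dimps(mat, "reference", "query", kind = "HD", alpha = 0.01)
  expect_true(all(calls$is_dimp == (calls$p_exceed < 0.01)))
  expect_true(all(calls$p_exceed >= 0 & calls$p_exceed <= 1))
  # sites below the fitted location are never DIMPs
  mu_hat <- attr(calls, "null_fit")$params[["mu"]]
  expect_true(all(!calls$is_dimp[calls$d0 <= mu_hat]))
  expect_true(all(calls$p_exceed[calls$d0 <= mu_hat] == 1))

  # spiked recall >= 95/100 at effect mu + 5*lambda, alpha = 0.01
  tt <- merge(calls, pair$truth, by = c("chrom", "pos", "strand"))
  expect_gte(sum(tt[tt$spiked == TRUE, ]$is_dimp), 95)

  # monotonicity in alpha: DIMP set nests
  calls5 <- call_dimps(mat, "reference", "query", kind = "HD", alpha = 0.05,
                       null_fit = attr(calls, "null_fit"))
  expect_true(all(calls5$is_dimp[calls$is_dimp]))
  # p_exceed nonincreasing in d0
  o <- order(calls$d0)
  expect_true(all(diff(calls$p_exceed[o]) <= 1e-12))
})

test_that("DIMP false-call rate on pure noise is near alpha", {
  spec <- sim_spec(n_sites = 10000, seed = 77,
                   signal = list(n_sites = 0))
  pair <- simulate_pair(spec)
  mat <- build_matrix(list(pair$reference, pair$query))
  for (alpha in c(0.01, 0.05)) {
    calls <- call_dimps(mat, "reference", "query", kind = "HD",
                        alpha = alpha)
    rate <- mean(calls$is_dimp)
    # band fixed a priori: ECDF-fit approximation + count quantization
    expect_gte(rate, alpha / 2)
    expect_lte(rate, alpha * 2)
  }
})

test_that("kind mismatch and unconverged nulls are refused", {
  m <- matrix_from_levels(runif(300), runif(300))
  calls <- call_dimps(m, "s1", "s2", kind = "HD")
  nf <- attr(calls, "null_fit")
  expect_error(call_dimps(m, "s1", "s2", kind = "TV", null_fit = nf),
               "kind")
  bad <- nf; bad$converged <- FALSE
  expect_error(call_dimps(m, "s1", "s2", kind = "HD", null_fit = bad),
               "converge")
  expect_error(call_dimps(m, "s1", "s2", kind = "HD", alpha = 1.5),
               "alpha")
})

test_that("fisher_dmp matches the enumeration oracle on small tables", {
  # margins <= 7 here; the full <= 12 sweep runs in test-acceptance.R
  for (n1 in 1:7) for (n2 in 1:7) {
    for (x1 in 0:n1) {
      x2 <- 0:n2
      got <- fisher_dmp(rep(x1, length(x2)), rep(n1, length(x2)),
                        x2, rep(n2, length(x2)))$p_value
      want <- vapply(x2, function(b)
        oracle_fisher(x1, n1 - x1, b, n2 - b), numeric(1))
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("fisher_dmp worked examples and skip flag", {
  r <- fisher_dmp(10, 10, 0, 10)
  expect_equal(r$p_value, 2 / choose(20, 10), tolerance = 1e-10)
  expect_true(r$called)
  expect_equal(fisher_dmp(5, 10, 5, 10)$p_value, 1)
  r2 <- fisher_dmp(1, 10, 2, 10)
  expect_gt(r2$p_value, 0.5)
  expect_false(r2$called)
  r3 <- fisher_dmp(0, 0, 5, 10)
  expect_true(r3$skipped)
  expect_true(is.na(r3$p_value))
  expect_false(r3$called)
  expect_error(fisher_dmp(7, 5, 1, 10), "exceed")
})

test_that("call_dimrs thresholds same-size regions", {
  set.seed(31)
  # synthetic tile divergences: Weibull noise + 10 spiked far in the tail
  n <- 2000
  d <- 0.05 + 1.2 * rweibull(n, 1.3)
  spike_idx <- sample(n, 10)
  d[spike_idx] <- 0.05 + 1.2 * qweibull(1 - 1e-5, 1.3)
  tiles <- data.frame(chrom = "chr1", start = seq(1, by = 3000, length = n),
                      end = seq(3000, by = 3000, length = n),
                      width = 3000, partial = FALSE, HD = d)
  calls <- call_dimrs(tiles, "HD", alpha = 0.01)
  expect_gte(sum(calls$is_dimr[spike_idx]), 9)
  expect_true(all(calls$is_dimr == (calls$p_exceed < 0.01)))
  # mixed sizes are refused
  tiles2 <- tiles; tiles2$width[1] <- 2000
  expect_error(call_dimrs(tiles2, "HD"), "same nominal size")
})

test_that("spiked-region recall over 20 seeds (median >= 9/10)", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 2000
    d <- 0.05 + 1.2 * rweibull(n, 1.3)
    idx <- sample(n, 10)
    d[idx] <- quantile(d, 0.999) + 1.2 * 2    # far upper tail
    tiles <- data.frame(chrom = "c", start = 1:n, end = 1:n, width = 1,
                        partial = FALSE, HD = d)
    sum(call_dimrs(tiles, "HD", alpha = 0.01)$is_dimr[idx])
  }, numeric(1))
  expect_gte(median(hits), 9)
})

test_that("density_profile centers, orients and normalizes", {
  anchors <- data.frame(chrom = "chr1", pos = 5000, strand = "+")
  calls <- data.frame(chrom = "chr1", pos = 5000)
  pr <- density_profile(calls, anchors, window = 1000, bin = 100)
  expect_equal(sum(pr$count), 1L)
  expect_equal(pr$bin_start[pr$count == 1], 0)   # center bin [0, 100)
  expect_equal(pr$density[pr$count == 1], 1)

  # minus-strand anchor mirrors coordinates
  am <- data.frame(chrom = "chr1", pos = 5000, strand = "-")
  cm <- data.frame(chrom = "chr1", pos = 5300)   # 300 bp downstream of pos
  prm <- density_profile(cm, am, window = 1000, bin = 100)
  expect_equal(prm$bin_start[prm$count == 1], -300)

  # uniform calls over many anchors -> flat profile
  set.seed(8)
  anchors2 <- data.frame(chrom = "chr1",
                         pos = seq(10000, 90000, by = 4000), strand = "+")
  calls2 <- data.frame(chrom = "chr1", pos = sample.int(1e5, 20000))
  pr2 <- density_profile(calls2, anchors2, window = 2000, bin = 200)
  expect_lt(sd(pr2$count) / mean(pr2$count), 0.2)
  expect_error(density_profile(calls2, anchors2[0, ], 2000, 200), "anchor")
  expect_error(density_profile(calls2, anchors2, 100, 100), "window")
})

test_that("Fisher and divergence call densities correlate on strong signal", {
  # clustered-signal pair: query equals reference up to binomial sampling
  # noise, except in 8 signal windows where levels are flipped; both callers
  # should then concentrate their calls in those windows
  set.seed(13)
  spec <- sim_spec(n_sites = 8000, seed = 13, zero_coverage_frac = 0)
  ref <- simulate_methylome(spec, "ref")
  p <- ifelse(ref$n_total > 0, ref$n_meth / ref$n_total, 0)
  q <- p
  in_win <- rep(FALSE, nrow(ref))
  for (k in 1:8)
    in_win <- in_win | (ref$pos >= k * 1e5 & ref$pos < k * 1e5 + 1e4)
  q[in_win] <- 1 - p[in_win]
  q_meth <- rbinom(nrow(ref), ref$n_total, q)
  qt <- data.table::data.table(
    chrom = ref$chrom, pos = ref$pos, strand = ref$strand,
    context = ref$context, n_meth = q_meth, n_total = ref$n_total)
  qpath <- tempfile(fileext = ".tsv")
  data.table::fwrite(qt, qpath, sep = "\t")
  query <- read_counts_table(qpath, "generic", sample_id = "query")

  mat <- build_matrix(list(ref, query))
  calls <- call_dimps(mat, "ref", "query", kind = "HD", alpha = 0.01)
  fis <- fisher_dmp(ref$n_meth, ref$n_total, qt$n_meth, qt$n_total,
                    alpha = 0.01)
  breaks <- seq(0, 1e6, by = 2.5e4)
  fb <- tapply(fis$called, cut(ref$pos, breaks), sum, default = 0)
  key <- merge(data.table::data.table(pos = ref$pos),
               calls[, c("pos", "is_dimp")], by = "pos", all.x = TRUE)
  db <- tapply(!is.na(key$is_dimp) & key$is_dimp,
               cut(key$pos, breaks), sum, default = 0)
  expect_gt(cor(as.numeric(fb), as.numeric(db)), 0.5)
})
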