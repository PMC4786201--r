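test_that("binarize follows the any-positive rule", {
  m <- matrix_from_levels(c(0, 0, 0.3), c(0.2, NA, 0))
  b <- binarize(m)
  expect_equal(b$digit, c(1L, 0L, 1L))     # (0,0.2)->1, (0,NA)->0, (0.3,0)->1
  m0 <- matrix_from_levels(c(0, 0, 0))
  expect_equal(binarize(m0)$digit, c(0L, 0L, 0L))
})

test_that("partition_pwf reproduces the printed worked examples", {
  s28 <- "1001100000010000011100000011"
  p7 <- partition_pwf(s28, 7)
  expect_equal(nrow(p7), 1L)
  expect_equal(p7$length_digits, 28L)
  p6 <- partition_pwf(s28, 6)
  expect_equal(p6$length_digits, c(5L, 9L, 2L))
  expect_equal(p6$digits, c("10011", "100000111", "11"))

  p11 <- partition_pwf("11010000011", 6)
  expect_equal(p11$length_digits, 11L)
  expect_equal(p11$max_zero_run, 5L)
  p11b <- partition_pwf("11010000011", 5)
  expect_equal(p11b$digits, c("1101", "11"))
  expect_error(partition_pwf(s28, 0), "d")
})

test_that("PWF coordinates map to site positions", {
  m <- matrix_from_levels(c(0.5, 0, 0, 0.2, 0, 0.9))  # sites at 10..60
  b <- binarize(m)                                     # digits 100101
  p <- partition_pwf(b, 2)
  # d = 2: runs of >= 2 zeros split -> words "1" (pos 10), "101" (pos 40-60)
  expect_equal(p$digits, c("1", "101"))
  expect_equal(p$start_pos, c(10L, 40L))
  expect_equal(p$end_pos, c(10L, 60L))
  expect_equal(p$span_bp, c(1L, 21L))
  expect_equal(p$row_start, c(1L, 4L))
  p3 <- partition_pwf(b, 3)
  expect_equal(p3$digits, c("100101"))
})

test_that("sentence decomposition matches the printed example", {
  p7 <- partition_pwf("1001100000010000011100000011", 7)
  dec <- decompose_sentence(p7[1, ])
  expect_equal(dec$type, c("word", "zeros", "word", "zeros", "word"))
  expect_equal(dec$length, c(5L, 6L, 9L, 6L, 2L))
  expect_equal(dec$k[dec$type == "word"], c(3L, 6L, 1L))
  expect_equal(sum(dec$type == "zeros"), 2L)
  expect_true(all(dec$length[dec$type == "zeros"] == 6L))
  # concatenation reproduces the parent digits
  expect_equal(paste(dec$digits, collapse = ""), p7$digits)

  # no internal run of d-1: single component
  expect_equal(nrow(decompose_sentence("10011", 7)), 1L)
  d2 <- decompose_sentence("11", 4)
  expect_equal(d2$k, 1L)
  expect_error(decompose_sentence("011", 3), "start and end")
})

test_that("reconstruction and validity hold exhaustively (strings <= 9)", {
  # brute force over every binary string of length 1..9 and d in 1..6;
  # the full <= 12 sweep runs in test-acceptance.R
  for (len in 1:9) {
    grid <- as.matrix(expand.grid(rep(list(0:1), len)))
    for (r in seq_len(nrow(grid))) {
      v <- as.integer(grid[r, ])
      for (d in 1:6) {
        p <- partition_pwf(v, d)
        w_oracle <- oracle_pwfs(v, d)
        expect_identical(p$length_digits,
                         vapply(w_oracle, length, integer(1)))
        if (nrow(p)) {
          # validity: starts/ends with 1, internal zero runs <= d - 1
          for (i in seq_len(nrow(p))) {
            dg <- as.integer(strsplit(p$digits[i], "")[[1]])
            expect_identical(dg[1], 1L)
            expect_identical(dg[length(dg)], 1L)
            expect_lte(p$max_zero_run[i], d - 1L)
          }
          # reconstruction: digits outside PWFs are all zero
          covered <- unlist(lapply(seq_len(nrow(p)), function(i)
            p$start_idx[i]:p$end_idx[i]))
          expect_true(all(v[setdiff(seq_len(len), covered)] == 0L))
          expect_identical(
            paste(v[sort(covered)], collapse = ""),
            paste(p$digits, collapse = ""))
        } else {
          expect_true(all(v == 0L))
        }
      }
    }
  }
})

test_that("every PWF at d nests inside exactly one PWF at d + 1", {
  set.seed(4)
  v <- as.integer(runif(4000) < 0.35)
  for (d in 1:5) {
    pd <- partition_pwf(v, d)
    pd1 <- partition_pwf(v, d + 1L)
    parents <- vapply(seq_len(nrow(pd)), function(i)
      sum(pd1$start_idx <= pd$start_idx[i] & pd1$end_idx >= pd$end_idx[i]),
      numeric(1))
    expect_true(all(parents == 1))
  }
})

test_that("length_spectrum counts and conserves", {
  sp <- length_spectrum(c(2L, 2L, 5L))
  expect_equal(sp$l, c(2L, 5L))
  expect_equal(sp$f, c(2L, 1L))
  expect_equal(sum(sp$f), 3L)
  expect_warning(length_spectrum(integer(0)), "empty")
})

test_that("fit_decay recovers exact exponential spectra and deltaF", {
  l <- 4:60
  sp <- data.frame(l = l, f = 1000 * exp(-0.05 * l))
  fit <- fit_decay(sp, min_l = 4, max_l = 60)
  expect_lt(abs(fit$phi - 1000) / 1000, 1e-6)
  expect_lt(abs(fit$gamma - 0.05) / 0.05, 1e-6)
  expect_true(fit$decaying)
  # deltaF arithmetic: N0 = e * phi -> deltaF = R*T
  fit2 <- fit_decay(sp, 4, 60, temperature_K = 298.15)
  expect_equal(fit2$deltaF,
               8.314 * 298.15 * log(fit2$N0 / fit2$phi))
  expect_equal(8.314 * 298.15, 2478.8, tolerance = 1e-3)
  # too few lengths
  expect_error(fit_decay(sp[1:3, ], 4, 60), ">= 4")
  # increasing spectrum flagged non-decaying
  spu <- data.frame(l = 4:20, f = exp(0.1 * (4:20)))
  expect_warning(fitu <- fit_decay(spu, 4, 20), "non-decaying")
  expect_false(fitu$decaying)
})

test_that("decay recovery under Poisson noise: gamma within 10%", {
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    l <- 1:80
    f <- rpois(length(l), 1500 * exp(-0.08 * l))   # N0 ~ 10^4
    sp <- data.frame(l = l, f = f)[f > 0, ]
    fit <- fit_decay(sp, min_l = 4, max_l = 80)
    abs(fit$gamma - 0.08) / 0.08
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("pwf_information pools I by length and feeds persistence", {
  # synthetic end-to-end: per-length I values from Weibull with
  # lambda(l) = 0.5 * exp(0.03 * (0.34 * l)) -> Lp = 50 nm via 3/(2d)
  lp_errs <- vapply(1:20, function(s) {
    set.seed(s)
    lens <- seq(10, 150, by = 20)
    fits <- data.table::rbindlist(lapply(lens, function(l) {
      lam <- 0.5 * exp(0.03 * 0.34 * l)
      x <- 0.01 + lam * rweibull(400, 1.3)
      f <- fit_cdf(x, "weibull")
      data.table::data.table(l = l, lambda = f$params[["lambda"]],
                             converged = f$converged)
    }))
    tr <- trend_to_nm(lambda_trend(fits, unit = "bp"))
    abs(persistence_exponential(tr)$Lp_nm - 50) / 50
  }, numeric(1))
  expect_lt(median(lp_errs), 0.10)
})

test_that("pwf_information computes I over matrix rows correctly", {
  set.seed(2)
  lv1 <- ifelse(runif(60) < 0.5, 0, runif(60))
  lv2 <- ifelse(runif(60) < 0.5, 0, runif(60))
  m <- matrix_from_levels(lv1, lv2)
  b <- binarize(m)
  p <- partition_pwf(b, 3)
  expect_gt(nrow(p), 0)
  out <- pwf_information(p, m, reference = "s1", min_count = 1)
  expect_named(out, c("values", "fits", "skipped", "trend"))
  # oracle: direct region_information on the matrix levels, PWF by PWF
  want <- vapply(seq_len(nrow(p)), function(j) {
    r <- p$row_start[j]:p$row_end[j]
    region_information(m$levels[r, "s1"], m$levels[r, "s2"])
  }, numeric(1))
  expect_equal(out$values$I, want, tolerance = 1e-12)
  expect_equal(out$values$l, p$length_digits)
  expect_equal(sort(unique(p$length_digits)),
               sort(unique(c(out$fits$l, out$skipped))))
  # lengths below min_count are skipped
  out20 <- pwf_information(p, m, reference = "s1", min_count = 1e6)
  expect_equal(nrow(out20$fits), 0L)
  expect_null(out20$trend)
})
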