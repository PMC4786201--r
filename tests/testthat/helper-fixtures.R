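# fixtures built in code; no binary files

write_generic_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("chrom\tpos\tstrand\tcontext\tn_meth\tn_total", lines), path)
  path
}

make_sample <- function(chrom, pos, strand = "+", context = "CG",
                        n_meth, n_total, id = "s") {
  dt <- data.table::data.table(chrom = chrom, pos = as.integer(pos),
                               strand = strand, context = context,
                               n_meth = as.integer(n_meth),
                               n_total = as.integer(n_total))
  data.table::setorder(dt, chrom, pos, strand)
  p <- write_generic_tsv(do.call(sprintf,
    c(list("%s\t%d\t%s\t%s\t%d\t%d"), as.list(dt))))
  # simplest valid constructor path: write + read (also exercises the reader)
  read_counts_table(p, "generic", sample_id = id)
}

# MethylMatrix straight from level vectors (coverage 100, NA = missing)
matrix_from_levels <- function(...) {
  levs <- list(...)
  n <- length(levs[[1]])
  samples <- lapply(seq_along(levs), function(i) {
    lv <- levs[[i]]
    total <- ifelse(is.na(lv), 0L, 100L)
    meth <- ifelse(is.na(lv), 0L, as.integer(round(lv * 100)))
    make_sample("chr1", seq_len(n) * 10L, "+", "CG", meth, total,
                id = paste0("s", i))
  })
  build_matrix(samples)
}

# independent brute-force PWF oracle: O(n^2) scan over a digit vector
oracle_pwfs <- function(digits, d) {
  n <- length(digits)
  words <- list()
  i <- 1L
  while (i <= n) {
    if (digits[i] == 1L) {
      j <- i; last1 <- i; k <- i + 1L
      zeros <- 0L
      while (k <= n) {
        if (digits[k] == 1L) { last1 <- k; zeros <- 0L }
        else { zeros <- zeros + 1L; if (zeros >= d) break }
        k <- k + 1L
      }
      words[[length(words) + 1L]] <- digits[i:last1]
      i <- last1 + 1L
    } else i <- i + 1L
  }
  words
}

# independent two-sided Fisher oracle by hypergeometric enumeration
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
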