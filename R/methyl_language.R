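#' Binarize a multi-sample methylation matrix
#'
#' Builds the pooled binary methylation string: a site gets digit 1 when its
#' methylation level is greater than zero in at least one sample, 0 otherwise
#' (missing levels provide no positive evidence). Sites keep the matrix
#' ordering (chrom, pos, strand).
#'
#' @param mat A `MethylMatrix`.
#' @return A `BinaryMethylome`: `data.table` with `chrom, pos, strand, digit,
#'   row` (`row` = row index into `mat`).
#' @export
binarize <- function(mat) {
  stopifnot(inherits(mat, "MethylMatrix"))
  pos_any <- rowSums(mat$levels > 0, na.rm = TRUE) > 0
  out <- data.table::data.table(
    chrom = mat$sites$chrom, pos = mat$sites$pos,
    strand = mat$sites$strand,
    digit = as.integer(pos_any), row = seq_len(nrow(mat$levels)))
  data.table::setattr(out, "class",
                      c("BinaryMethylome", class(data.table::data.table())))
  out[]
}

# digits of one chromosome as integer vector -> clusters of 1s whose internal
# zero-runs are all <= d-1; returns start/end indices (into the digit vector)
pwf_clusters <- function(digits, d) {
  ones <- which(digits == 1L)
  if (length(ones) == 0L)
    return(data.table::data.table(start_idx = integer(), end_idx = integer(),
                                  max_zero_run = integer()))
  gaps <- diff(ones) - 1L                  # zeros between consecutive 1s
  brk <- which(gaps >= d)                  # a run of >= d zeros separates
  starts <- ones[c(1L, brk + 1L)]
  ends <- ones[c(brk, length(ones))]
  # max internal zero-run per cluster, O(n): cluster id per "one", then a
  # grouped max over the internal (< d) gaps
  cl <- cumsum(c(1L, gaps >= d))
  mzr <- integer(length(starts))
  internal <- which(gaps < d)
  if (length(internal)) {
    agg <- tapply(gaps[internal], cl[internal], max)
    mzr[as.integer(names(agg))] <- as.integer(agg)
  }
  data.table::data.table(start_idx = starts, end_idx = ends,
                         max_zero_run = mzr)
}

#' Partition a binary methylome into potential word frameworks
#'
#' Splits each chromosome's binary string into *potential word frameworks*
#' (PWFs): maximal substrings that start and end with 1 and whose internal
#' maximal runs of 0s are all shorter than the threshold `d`. Runs of `d` or
#' more 0s (and leading/trailing 0s) separate PWFs and belong to none. The
#' set of PWFs at threshold `d` is the partition \eqn{S_d}.
#'
#' @param binary A `BinaryMethylome` from [binarize()], or for convenience a
#'   plain 0/1 integer vector / digit string (treated as one chromosome with
#'   positions 1..n).
#' @param d Zero-run threshold (>= 1).
#' @return A `data.table`, one row per PWF: `chrom, start_idx, end_idx`
#'   (indices into the chromosome's site sequence), `row_start, row_end`
#'   (matrix rows, when available), `start_pos, end_pos` (genomic positions
#'   of the first/last 1), `length_digits`, `span_bp`
#'   (`end_pos - start_pos + 1`), `max_zero_run`, `d`, and the digit string
#'   `digits`.
#' @export
partition_pwf <- function(binary, d) {
  if (!is.numeric(d) || length(d) != 1L || d < 1 || d != floor(d))
    stop("`d` must be a single integer >= 1", call. = FALSE)
  d <- as.integer(d)
  binary <- as_binary_methylome(binary)
  out <- binary[, {
    cl <- pwf_clusters(digit, d)
    if (nrow(cl)) {
      data.table::data.table(
        start_idx = cl$start_idx, end_idx = cl$end_idx,
        row_start = row[cl$start_idx], row_end = row[cl$end_idx],
        start_pos = pos[cl$start_idx], end_pos = pos[cl$end_idx],
        length_digits = cl$end_idx - cl$start_idx + 1L,
        span_bp = pos[cl$end_idx] - pos[cl$start_idx] + 1L,
        max_zero_run = cl$max_zero_run,
        digits = vapply(seq_len(nrow(cl)), function(i)
          paste(digit[cl$start_idx[i]:cl$end_idx[i]], collapse = ""),
          character(1)))
    } else NULL
  }, by = chrom]
  if (nrow(out) == 0L)
    out <- data.table::data.table(
      chrom = character(), start_idx = integer(), end_idx = integer(),
      row_start = integer(), row_end = integer(), start_pos = integer(),
      end_pos = integer(), length_digits = integer(), span_bp = integer(),
      max_zero_run = integer(), digits = character())
  data.table::set(out, j = "d", value = d)
  out[]
}

as_binary_methylome <- function(binary) {
  if (inherits(binary, "BinaryMethylome")) return(binary)
  if (is.character(binary) && length(binary) == 1L)
    binary <- as.integer(strsplit(binary, "")[[1]])
  if (is.numeric(binary)) {
    if (!all(binary %in% c(0, 1)))
      stop("binary string may contain only 0s and 1s", call. = FALSE)
    return(data.table::data.table(chrom = "chr", pos = seq_along(binary),
                                  strand = "*",
                                  digit = as.integer(binary),
                                  row = seq_along(binary)))
  }
  stop("cannot interpret `binary` as a binary methylome", call. = FALSE)
}

#' Decompose a long PWF into its sentence components
#'
#' A PWF from partition \eqn{S_d} (d >= 2) reads as a "sentence": sub-words
#' from finer partitions \eqn{S_{k}} with \eqn{k < d - 1} or \eqn{k = d - 1},
#' separated by zero-strings of length exactly \eqn{d - 1}. Each sub-word's
#' partition index is \eqn{k = }(its maximal internal zero-run)\eqn{ + 1}
#' (so a run of 1s has \eqn{k = 1}).
#'
#' @param digits A PWF digit string (or one row of [partition_pwf()] output,
#'   from which `digits` and `d` are taken).
#' @param d The threshold of the partition the PWF came from.
#' @return A `data.table`, one row per component in order: `type`
#'   (`"word"`/`"zeros"`), `digits`, `length`, `k` (`NA` for zero-strings).
#'   At `d = 1` the decomposition is the PWF itself.
#' @export
decompose_sentence <- function(digits, d = NULL) {
  if (is.data.frame(digits)) {
    if (nrow(digits) != 1L)
      stop("pass a single PWF row", call. = FALSE)
    d <- d %||% digits$d
    digits <- digits$digits
  }
  if (is.null(d)) stop("`d` must be supplied", call. = FALSE)
  v <- as.integer(strsplit(digits, "")[[1]])
  if (length(v) == 0L || v[1] != 1L || v[length(v)] != 1L)
    stop("not a valid PWF: must start and end with 1", call. = FALSE)
  comp_k <- function(w) {
    r <- rle(w)
    zr <- r$lengths[r$values == 0L]
    if (length(zr)) max(zr) + 1L else 1L
  }
  if (d <= 1L || !any(v == 0L)) {
    return(data.table::data.table(
      type = "word", digits = paste(v, collapse = ""),
      length = length(v), k = comp_k(v)))
  }
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sep <- which(r$values == 0L & r$lengths == d - 1L)
  # boundaries: word segments between separator zero-runs
  comps <- list(); cursor <- 1L
  for (s in sep) {
    if (starts[s] > cursor)
      comps[[length(comps) + 1L]] <- list(type = "word",
                                          v = v[cursor:(starts[s] - 1L)])
    comps[[length(comps) + 1L]] <- list(type = "zeros",
                                        v = v[starts[s]:ends[s]])
    cursor <- ends[s] + 1L
  }
  if (cursor <= length(v))
    comps[[length(comps) + 1L]] <- list(type = "word",
                                        v = v[cursor:length(v)])
  data.table::rbindlist(lapply(comps, function(cp)
    data.table::data.table(
      type = cp$type, digits = paste(cp$v, collapse = ""),
      length = length(cp$v),
      k = if (cp$type == "word") comp_k(cp$v) else NA_integer_)))
}

#' Length spectrum of a PWF set
#'
#' Counts PWFs per distinct length (in digits).
#'
#' @param pwfs Output of [partition_pwf()] (or an integer vector of lengths).
#' @return A `data.table` sorted by `l`: columns `l`, `f` (frequency);
#'   `sum(f)` equals the number of input PWFs.
#' @export
length_spectrum <- function(pwfs) {
  lens <- if (is.data.frame(pwfs)) pwfs$length_digits else as.integer(pwfs)
  if (length(lens) == 0L) {
    warning("empty PWF set: empty spectrum")
    return(data.table::data.table(l = integer(), f = integer()))
  }
  tab <- table(lens)
  data.table::data.table(l = as.integer(names(tab)),
                         f = as.integer(tab))[order(l)]
}

#' Fit the exponential decay law of the PWF length spectrum
#'
#' Nonlinear least-squares fit of \eqn{f_l = \phi e^{-\gamma l}} to the PWF
#' frequency-vs-length spectrum, restricted to `[min_l, max_l]`. Treating
#' lengths as energy costs under a Boltzmann (maximum-entropy) distribution,
#' \eqn{\phi = N_0/Z} where \eqn{N_0} is the total number of PWFs and
#' \eqn{Z} the partition function, giving the Helmholtz free energy
#' \eqn{\Delta F = R T \ln(N_0/\phi)} (J/mol) at the stated temperature.
#'
#' @param spectrum Output of [length_spectrum()].
#' @param min_l,max_l Length range used in the fit (defaults 4 and 100
#'   digits); at least 4 distinct lengths must remain.
#' @param temperature_K Temperature for \eqn{\Delta F} (default 298.15 K).
#' @return A `DecayFit`: list with `phi`, `gamma`, `N0` (total PWFs in the
#'   full spectrum), `Z = N0/phi`, `deltaF` (J/mol), `temperature_K`, `r2`,
#'   `n_lengths`, `decaying` (FALSE when \eqn{\hat\gamma \le 0}).
#' @export
fit_decay <- function(spectrum, min_l = 4, max_l = 100,
                      temperature_K = 298.15) {
  spectrum <- data.table::as.data.table(spectrum)
  N0 <- sum(spectrum$f)
  sp <- spectrum[l >= min_l & l <= max_l & f > 0]
  if (nrow(sp) < 4L)
    stop("need >= 4 distinct lengths with positive counts in [min_l, max_l]",
         call. = FALSE)
  lf <- lm(log(f) ~ l, data = sp)
  start <- list(phi = exp(unname(coef(lf)[1])), gamma = -unname(coef(lf)[2]))
  fit <- tryCatch(
    nls(f ~ phi * exp(-gamma * l), data = sp, start = start,
        control = list(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    phi <- start$phi; gamma <- start$gamma
    resid <- sp$f - phi * exp(-gamma * sp$l)
  } else {
    phi <- unname(coef(fit)[["phi"]]); gamma <- unname(coef(fit)[["gamma"]])
    resid <- stats::residuals(fit)
  }
  r2 <- 1 - sum(resid^2) / sum((sp$f - mean(sp$f))^2)
  decaying <- gamma > 0
  if (!decaying) warning("non-decaying spectrum: gamma-hat <= 0")
  structure(list(phi = phi, gamma = gamma, N0 = N0, Z = N0 / phi,
                 deltaF = .R_GAS * temperature_K * log(N0 / phi),
                 temperature_K = temperature_K, r2 = r2,
                 n_lengths = nrow(sp), decaying = decaying),
            class = "DecayFit")
}

#' @export
print.DecayFit <- function(x, ...) {
  cat(sprintf("DecayFit: f_l = %.6g * exp(-%.6g l); N0 = %d, Z = %.6g\n",
              x$phi, x$gamma, x$N0, x$Z))
  cat(sprintf("  deltaF = %.6g J/mol at %.2f K; R2 = %.5f over %d lengths%s\n",
              x$deltaF, x$temperature_K, x$r2, x$n_lengths,
              if (x$decaying) "" else "  [non-decaying]"))
  invisible(x)
}

#' Per-length information fits over PWFs
#'
#' Computes the region information \eqn{I} of every PWF between a reference
#' sample and each other sample of the matrix, pools the values by PWF length
#' (digits), fits the Weibull null CDF per length with enough pooled values,
#' and returns the fitted scale trend \eqn{\hat\lambda(l)} that feeds the
#' exponential (entropic-spring) persistence-length estimate.
#'
#' @param pwfs Output of [partition_pwf()] built from `mat`'s sites.
#' @param mat The `MethylMatrix` the PWFs were derived from.
#' @param reference Sample id used as the "before" state.
#' @param min_count Minimum pooled values per length to attempt a fit
#'   (default 20); sparser lengths are skipped and listed.
#' @param min_value Floor passed to [fit_cdf()].
#' @return List with `values` (the pooled per-PWF information values:
#'   `query, l, I`), `fits` (a `data.table`: `l, alpha, lambda, mu, n,
#'   converged, r2`), `skipped` (lengths with too few values), and `trend`
#'   (a `lambda_trend` over converged fits, lengths in digits/bp units;
#'   convert with [trend_to_nm()] before persistence estimation). `trend` is
#'   `NULL` when fewer than two lengths converge.
#' @export
pwf_information <- function(pwfs, mat, reference, min_count = 20,
                            min_value = 1e-8) {
  stopifnot(inherits(mat, "MethylMatrix"))
  if (!reference %in% mat$sample_ids)
    stop("reference sample not in matrix: ", reference, call. = FALSE)
  if (nrow(pwfs) == 0L) stop("no PWFs supplied", call. = FALSE)
  H <- mat$levels
  H[] <- site_entropy(c(mat$levels))
  Hc <- H
  for (j in seq_len(ncol(H))) Hc[, j] <- cumsum(H[, j])
  Hc0 <- rbind(0, Hc)                            # 1-padded cumulative sums
  seg_sum <- function(col, s, e) Hc0[e + 1L, col] - Hc0[s, col]
  queries <- setdiff(mat$sample_ids, reference)
  if (length(queries) == 0L)
    stop("matrix must contain at least one non-reference sample",
         call. = FALSE)
  href <- seg_sum(reference, pwfs$row_start, pwfs$row_end)
  vals <- data.table::rbindlist(lapply(queries, function(qid)
    data.table::data.table(
      query = qid, l = pwfs$length_digits,
      I = abs(seg_sum(qid, pwfs$row_start, pwfs$row_end) - href))))

  counts <- vals[, .N, by = l]
  fit_ls <- counts[N >= min_count][order(l)]
  skipped <- counts[N < min_count]$l
  fits <- data.table::rbindlist(lapply(fit_ls$l, function(li) {
    v <- vals[l == li, I]
    fr <- tryCatch(fit_cdf(v, "weibull", min_value = min_value),
                   error = function(e) NULL)
    if (is.null(fr))
      return(data.table::data.table(l = li, alpha = NA_real_,
                                    lambda = NA_real_, mu = NA_real_,
                                    n = length(v), converged = FALSE,
                                    r2 = NA_real_))
    data.table::data.table(l = li, alpha = fr$params[["alpha"]],
                           lambda = fr$params[["lambda"]],
                           mu = fr$params[["mu"]], n = fr$n_points,
                           converged = fr$converged, r2 = fr$r2)
  }))
  trend <- NULL
  if (nrow(fits) && sum(fits$converged, na.rm = TRUE) >= 2L)
    trend <- lambda_trend(fits[converged == TRUE], unit = "bp")
  list(values = vals, fits = fits, skipped = skipped, trend = trend)
}
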