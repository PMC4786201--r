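#' Call differentially informative methylated positions (DIMPs)
#'
#' Signal-detection calling of DMPs: the fitted Weibull/GG null CDF of the
#' site-level divergence between a reference and a query methylome gives, for
#' each observed divergence \eqn{d_0}, the false-positive probability
#' \eqn{P(D > d_0) = 1 - F(d_0)} that a divergence at least this large arises
#' from thermal-noise methylation background. A site is a DIMP at level
#' \eqn{\alpha} iff that probability is below \eqn{\alpha}. No
#' multiple-testing adjustment is applied: the threshold is on the
#' false-positive probability itself, not on a p-value family.
#'
#' @param mat A `MethylMatrix` containing both samples.
#' @param ref,query Sample ids in `mat`.
#' @param kind Divergence measure: `"HD"` (default), `"TV"`, `"KL"`, or
#'   `"I"` (site information change).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param null_fit Optional `FitResult` fitted on the site divergences of
#'   this same sample pair (the per-individual null). When `NULL`, the null
#'   is fitted here with [fit_cdf()] (Weibull). If the supplied fit carries a
#'   `kind` attribute it must match `kind`.
#' @param min_value Floor passed to [fit_cdf()] when fitting internally.
#' @return A `data.table` of co-observed sites: `chrom, pos, strand, context,
#'   d0, p_exceed, is_dimp`, with the null fit attached as attribute
#'   `null_fit`. Sites missing in either sample are skipped.
#' @export
call_dimps <- function(mat, ref, query, kind = c("HD", "TV", "KL", "I"),
                       alpha = 0.05, null_fit = NULL, min_value = 1e-8) {
  kind <- match.arg(kind)
  stopifnot(inherits(mat, "MethylMatrix"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  p <- mat$levels[, ref]; q <- mat$levels[, query]
  if (kind == "I") {
    d <- abs(site_entropy(q) - site_entropy(p))
    d[is.na(p) | is.na(q)] <- NA_real_
  } else {
    d <- as.numeric(site_divergence(p, q, kind))
  }
  keep <- !is.na(d)
  out <- data.table::data.table(mat$sites[keep], d0 = d[keep])

  if (is.null(null_fit)) {
    null_fit <- fit_cdf(out$d0, model = "weibull", min_value = min_value)
    attr(null_fit, "kind") <- kind
  }
  fit_kind <- attr(null_fit, "kind")
  if (!is.null(fit_kind) && !identical(fit_kind, kind))
    stop(sprintf("null fit was made for kind '%s', not '%s'",
                 fit_kind, kind), call. = FALSE)
  if (!isTRUE(null_fit$converged))
    stop("null fit did not converge; cannot threshold", call. = FALSE)

  out[, p_exceed := 1 - fit_result_cdf(null_fit, d0)]
  out[, is_dimp := p_exceed < alpha]
  data.table::setattr(out, "null_fit", null_fit)
  data.table::setattr(out, "alpha", alpha)
  out[]
}

#' Fisher exact test comparator for differential methylation
#'
#' Classical per-site comparator: a two-sided Fisher exact test on the 2x2
#' table of methylated/unmethylated read counts in the two samples, called at
#' unadjusted `p < alpha` (optionally Benjamini-Hochberg adjusted).
#'
#' @param n_meth_a,n_total_a,n_meth_b,n_total_b Integer vectors of methylated
#'   and total read counts in samples A and B (recycled to common length).
#' @param alpha Significance level.
#' @param adjust `"none"` (default, mirroring its use as a plain comparator)
#'   or `"BH"`.
#' @return A `data.table`: `p_value, called, skipped` (skipped = a sample had
#'   zero total reads; its p is `NA` and it is never called).
#' @export
fisher_dmp <- function(n_meth_a, n_total_a, n_meth_b, n_total_b,
                       alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  n <- max(length(n_meth_a), length(n_total_a),
           length(n_meth_b), length(n_total_b))
  args <- lapply(list(n_meth_a, n_total_a, n_meth_b, n_total_b),
                 rep_len, n)
  if (any(args[[1]] > args[[2]]) || any(args[[3]] > args[[4]]))
    stop("n_meth cannot exceed n_total", call. = FALSE)
  skipped <- args[[2]] == 0L | args[[4]] == 0L
  p <- rep(NA_real_, n)
  for (i in which(!skipped)) {
    tab <- matrix(c(args[[1]][i], args[[2]][i] - args[[1]][i],
                    args[[3]][i], args[[4]][i] - args[[3]][i]),
                  nrow = 2, byrow = TRUE)
    p[i] <- fisher.test(tab)$p.value
  }
  p_use <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  data.table::data.table(p_value = p,
                         called = !is.na(p_use) & p_use < alpha,
                         skipped = skipped)
}

#' Call differentially informative methylated regions (DIMRs)
#'
#' Region-level analogue of [call_dimps()]: among genomic regions of the same
#' nominal size, the summed divergence \eqn{D_R} is thresholded against the
#' null CDF fitted on the \eqn{D_R} of that same partition.
#'
#' @param tile_divs A data frame with columns `chrom, start, end, width` and
#'   the region divergence column named by `column` (e.g. the output of
#'   [tile_info()]). Partial terminal tiles (column `partial`) are excluded.
#' @param column Which divergence column to threshold (default `"HD"`).
#' @param alpha Significance level.
#' @param null_fit Optional `FitResult` on the same partition's divergences;
#'   fitted here when `NULL`.
#' @param min_value Floor passed to [fit_cdf()].
#' @return A `data.table`: region coordinates, `D_R`, `p_exceed`, `is_dimr`;
#'   null fit attached as attribute `null_fit`.
#' @export
call_dimrs <- function(tile_divs, column = "HD", alpha = 0.05,
                       null_fit = NULL, min_value = 1e-8) {
  tile_divs <- data.table::as.data.table(tile_divs)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if ("partial" %in% names(tile_divs)) tile_divs <- tile_divs[partial == FALSE]
  if ("width" %in% names(tile_divs) &&
      length(unique(tile_divs$width)) > 1L)
    stop("regions must all have the same nominal size", call. = FALSE)
  if (!column %in% names(tile_divs))
    stop("no divergence column '", column, "' in `tile_divs`", call. = FALSE)
  out <- tile_divs[, c("chrom", "start", "end")]
  out[, D_R := tile_divs[[column]]]
  if (is.null(null_fit)) {
    null_fit <- fit_cdf(out$D_R, model = "weibull", min_value = min_value)
    attr(null_fit, "kind") <- column
  }
  if (!isTRUE(null_fit$converged))
    stop("null fit did not converge; cannot threshold", call. = FALSE)
  out[, p_exceed := 1 - fit_result_cdf(null_fit, D_R)]
  out[, is_dimr := p_exceed < alpha]
  data.table::setattr(out, "null_fit", null_fit)
  out[]
}

#' Density profile of calls around stranded genomic anchors
#'
#' Bins call positions in anchor-centered, strand-oriented coordinates
#' (upstream negative, downstream positive; minus-strand anchors are
#' mirrored) and normalizes by the number of anchors, as used for DIMP
#' density around transcription start/end sites.
#'
#' @param calls A data frame with columns `chrom, pos` (called positions).
#' @param anchors A data frame with columns `chrom, pos, strand` (anchor
#'   points, e.g. TSS); strand `+`/`-`.
#' @param window Half-window around each anchor, bp.
#' @param bin Bin width, bp (must divide into the window; `window > bin > 0`).
#' @return A `data.table`: `bin_start, bin_end, bin_mid` (anchor-relative),
#'   `count`, `density` (= count / n_anchors).
#' @export
density_profile <- function(calls, anchors, window = 4000, bin = 100) {
  if (!(window > bin && bin > 0))
    stop("need window > bin > 0", call. = FALSE)
  anchors <- data.table::as.data.table(anchors)
  if (nrow(anchors) == 0L) stop("no anchors supplied", call. = FALSE)
  if (!all(c("chrom", "pos", "strand") %in% names(anchors)))
    stop("anchors need chrom/pos/strand columns", call. = FALSE)
  calls <- data.table::as.data.table(calls)

  breaks <- seq(-window, window, by = bin)
  if (tail(breaks, 1) < window) breaks <- c(breaks, window)
  rel_all <- vector("list", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i]
    rel <- calls[chrom == a$chrom, pos] - a$pos
    if (a$strand == "-") rel <- -rel
    rel_all[[i]] <- rel[rel >= -window & rel <= window]
  }
  rel <- unlist(rel_all)
  idx <- findInterval(rel, breaks, rightmost.closed = TRUE,
                      left.open = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  data.table::data.table(
    bin_start = head(breaks, -1L), bin_end = tail(breaks, -1L),
    bin_mid = (head(breaks, -1L) + tail(breaks, -1L)) / 2,
    count = counts, density = counts / nrow(anchors))
}
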