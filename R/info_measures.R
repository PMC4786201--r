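#' Shannon entropy of a methylation level
#'
#' Binary (Bernoulli) entropy in bits of the methylation level
#' \eqn{p = n_{meth}/n_{total}} at a cytosine site:
#' \eqn{H(p) = -p \log_2 p - (1-p)\log_2(1-p)}, with the conventions
#' \eqn{0 \log_2 0 = 0} and — following the missing-data rule used for
#' multi-methylome matrices — `NA` (site not observed) contributing zero
#' entropy.
#'
#' @param p Methylation level(s) in \[0, 1\]; `NA` allowed (missing site).
#' @return Entropy in bits, in \[0, 1\]; vectorized over `p`.
#' @examples
#' site_entropy(0.5)   # 1 bit
#' site_entropy(c(0, 1, NA))  # all 0
#' @export
site_entropy <- function(p) {
  if (is.logical(p) && all(is.na(p))) p <- as.numeric(p)  # bare NA
  if (!is.numeric(p)) stop("`p` must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("methylation levels must lie in [0, 1]", call. = FALSE)
  h <- numeric(length(p))
  xlog2x <- function(x) ifelse(x > 0, x * log2(x), 0)
  h[ok] <- -xlog2x(p[ok]) - xlog2x(1 - p[ok])
  h[!ok] <- 0
  h
}

#' Information processed in a genomic region between two states
#'
#' The absolute amount of information associated with a methylation change in
#' a region is the absolute difference of the summed site entropies between
#' the two states:
#' \eqn{I_R = |\sum_{i \in R} H(p_i^{after}) - \sum_{i \in R} H(p_i^{before})|}.
#' For a single site this is the site-level information change \eqn{I_k};
#' note that a site flipping from level 0 to level 1 carries zero
#' information change (both states are certain).
#'
#' @param before,after Numeric vectors of methylation levels over the same
#'   sites (`NA` = missing, contributing zero entropy). If both are named,
#'   names must agree.
#' @return Information in bits (non-negative scalar).
#' @export
region_information <- function(before, after) {
  if (length(before) != length(after))
    stop("`before` and `after` must index the same sites", call. = FALSE)
  if (!is.null(names(before)) && !is.null(names(after)) &&
      !identical(names(before), names(after)))
    stop("site keys of `before` and `after` differ", call. = FALSE)
  abs(sum(site_entropy(after)) - sum(site_entropy(before)))
}

#' Landauer energy equivalent of an information change
#'
#' Minimum energy dissipated to process `bits` of information at absolute
#' temperature `temperature_K`, per Landauer's principle:
#' \eqn{E = I \, k_B T \ln 2} with \eqn{k_B = 1.380649 \times 10^{-23}} J/K.
#'
#' @param bits Non-negative information in bits (vectorized).
#' @param temperature_K Absolute temperature in kelvin (default 298.15).
#' @return Energy in joules, with the temperature attached as attribute
#'   `temperature_K`.
#' @examples
#' landauer_energy(1, 298)  # ~ 3e-21 J
#' @export
landauer_energy <- function(bits, temperature_K = 298.15) {
  stop_if_not_scalar_number(temperature_K, "temperature_K")
  if (temperature_K <= 0) stop("temperature must be positive", call. = FALSE)
  if (any(bits < 0, na.rm = TRUE))
    stop("`bits` must be non-negative", call. = FALSE)
  structure(bits * .kB * temperature_K * log(2),
            temperature_K = temperature_K)
}

#' Information divergence between two methylation levels
#'
#' Site-level divergences between methylation levels `p` and `q` of two
#' samples:
#' * `TV` — total variation, \eqn{|p - q|};
#' * `KL` — Kullback-Leibler divergence in bits,
#'   \eqn{p \log_2(p/q) + (1-p)\log_2((1-p)/(1-q))}, with
#'   \eqn{0 \log 0 = 0}; divergence against a degenerate `q` (0 or 1) with
#'   `p` off that boundary is `Inf`, returned as a sentinel (callers exclude
#'   non-finite values before distribution fitting);
#' * `HD` — squared Hellinger divergence,
#'   \eqn{(\sqrt{p}-\sqrt{q})^2 + (\sqrt{1-p}-\sqrt{1-q})^2}, bounded by 2.
#'
#' `NA` in either level yields `NA` (a divergence needs both samples
#' observed).
#'
#' @param p,q Methylation levels in \[0, 1\] (vectorized, recycled).
#' @param kind `"HD"` (default, the conservative choice), `"TV"` or `"KL"`.
#' @return Numeric divergence vector; attribute `kind` records the measure.
#' @export
site_divergence <- function(p, q, kind = c("HD", "TV", "KL")) {
  kind <- match.arg(kind)
  ok <- !is.na(p) & !is.na(q)
  if (any(p[ok] < 0 | p[ok] > 1 | q[ok] < 0 | q[ok] > 1))
    stop("methylation levels must lie in [0, 1]", call. = FALSE)
  d <- switch(kind,
    TV = abs(p - q),
    HD = (sqrt(p) - sqrt(q))^2 + (sqrt(1 - p) - sqrt(1 - q))^2,
    KL = {
      term <- function(a, b) {
        # a*log2(a/b) with 0*log(0/.) := 0 and a>0, b=0 -> Inf
        out <- ifelse(a > 0, a * (log2(a) - log2(b)), 0)
        out
      }
      term(p, q) + term(1 - p, 1 - q)
    })
  d[!ok] <- NA_real_
  structure(d, kind = kind)
}

#' Region divergence as the sum of site divergences
#'
#' \eqn{D_R = \sum_{k \in R} D_k}. Missing sites (`NA`) are excluded; an
#' empty region sums to 0; infinite KL sentinels propagate.
#'
#' @param site_divs Numeric vector of same-kind site divergences (as produced
#'   by [site_divergence()]).
#' @return Scalar region divergence, carrying the `kind` attribute if present.
#' @export
region_divergence <- function(site_divs) {
  if (is.list(site_divs)) {
    kinds <- unique(unlist(lapply(site_divs, attr, "kind")))
    if (length(kinds) > 1L)
      stop("cannot sum divergences of mixed kinds: ",
           paste(kinds, collapse = ", "), call. = FALSE)
    site_divs <- structure(unlist(site_divs), kind = kinds)
  }
  structure(sum(site_divs, na.rm = TRUE), kind = attr(site_divs, "kind"))
}

#' Per-tile information and divergence summaries for a sample pair
#'
#' For each genome tile, sums site entropies into the region information
#' \eqn{I_R} between a reference and a query sample, converts to Landauer
#' energy, and accumulates the three site divergences into region divergences
#' \eqn{D_R}. Sites missing in either sample are excluded from divergences;
#' missing entropies count as zero.
#'
#' @param mat A `MethylMatrix` containing both samples.
#' @param tiles Tiles from [tile_genome()].
#' @param ref,query Sample ids (columns of `mat`); `ref` is the "before"
#'   state.
#' @param temperature_K Temperature for the Landauer conversion.
#' @return A `data.table`: `chrom, start, end, width, partial, n_sites, I, E,
#'   TV, KL, HD` (one row per tile; `E` in joules). Infinite KL sums are
#'   possible and flagged by `is.finite(KL)`.
#' @export
tile_info <- function(mat, tiles, ref, query, temperature_K = 298.15) {
  stopifnot(inherits(mat, "MethylMatrix"))
  for (id in c(ref, query))
    if (!id %in% mat$sample_ids)
      stop("sample not in matrix: ", id, call. = FALSE)
  p <- mat$levels[, ref]
  q <- mat$levels[, query]
  site_dt <- data.table::data.table(
    chrom = mat$sites$chrom, pos = mat$sites$pos,
    h_ref = site_entropy(p), h_query = site_entropy(q),
    tv = as.numeric(site_divergence(p, q, "TV")),
    kl = as.numeric(site_divergence(p, q, "KL")),
    hd = as.numeric(site_divergence(p, q, "HD")))

  tiles <- data.table::as.data.table(tiles)
  tiles[, tile_id := .I]
  hits <- site_dt[tiles, on = .(chrom, pos >= start, pos <= end),
                  .(tile_id = i.tile_id, h_ref = x.h_ref,
                    h_query = x.h_query, tv = x.tv, kl = x.kl, hd = x.hd)]
  agg <- hits[, .(
    n_sites = sum(!is.na(tv)),
    I = abs(sum(h_query) - sum(h_ref)),
    TV = sum(tv, na.rm = TRUE),
    KL = sum(kl, na.rm = TRUE),
    HD = sum(hd, na.rm = TRUE)), by = tile_id]
  out <- agg[tiles, on = "tile_id"]
  for (col in c("I", "TV", "KL", "HD")) {
    v <- out[[col]]
    v[is.na(v)] <- 0
    data.table::set(out, j = col, value = v)
  }
  out[is.na(n_sites), n_sites := 0L]
  out[, E := as.numeric(landauer_energy(I, temperature_K))]
  out[, tile_id := NULL]
  data.table::setcolorder(out, c("chrom", "start", "end", "width", "partial",
                                 "n_sites", "I", "E", "TV", "KL", "HD"))
  out[]
}
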