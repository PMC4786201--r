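#' Specification for a synthetic methylome
#'
#' Collects the generator's stated world: genome geometry, context mixture,
#' read-coverage law, per-context methylation-level law, the Weibull
#' background-divergence ("methylation noise") law, and the spiked-signal
#' specification. Defaults emulate a plant-like methylome: bimodal CG
#' methylation, low CHG/CHH methylation, negative-binomial coverage around
#' 30x.
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param n_sites Total cytosine sites, allocated across chromosomes
#'   proportionally to size.
#' @param context_props Mixture proportions for CG/CHG/CHH (must sum to 1).
#' @param coverage_mean,coverage_dispersion Negative-binomial coverage mean
#'   and size parameter.
#' @param zero_coverage_frac Fraction of sites forced to zero coverage
#'   (missing observations).
#' @param level_beta Named list of `c(shape1, shape2)` Beta parameters per
#'   context.
#' @param noise Weibull parameters (`alpha`, `lambda`, `mu`) of the
#'   background site-divergence (squared Hellinger) law for sample pairs.
#' @param signal List: `n_sites` spiked sites and `effect` divergence
#'   (default `mu + 5*lambda`, deep in the background's upper tail).
#' @param seed Integer seed; every generator is fully deterministic given it.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(chrom_sizes = c(chr1 = 1e6),
                     n_sites = 20000,
                     context_props = c(CG = 0.25, CHG = 0.25, CHH = 0.5),
                     coverage_mean = 30, coverage_dispersion = 5,
                     zero_coverage_frac = 0.02,
                     level_beta = list(CG = c(0.8, 0.2),
                                       CHG = c(0.3, 1.2),
                                       CHH = c(0.2, 1.8)),
                     noise = list(alpha = 1, lambda = 0.3, mu = 0.01),
                     signal = list(n_sites = 100, effect = NULL),
                     seed = 1) {
  stopifnot(all(chrom_sizes >= 1), n_sites >= 1,
            abs(sum(context_props) - 1) < 1e-8,
            coverage_mean > 0, coverage_dispersion > 0,
            zero_coverage_frac >= 0, zero_coverage_frac < 1,
            noise$alpha > 0, noise$lambda > 0, noise$mu >= 0)
  if (n_sites > sum(chrom_sizes))
    stop("more sites requested than genome positions", call. = FALSE)
  structure(list(chrom_sizes = chrom_sizes, n_sites = n_sites,
                 context_props = context_props,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 zero_coverage_frac = zero_coverage_frac,
                 level_beta = level_beta, noise = noise, signal = signal,
                 seed = seed),
            class = "sim_spec")
}

#' Simulate one methylome sample
#'
#' Draws sorted unique site positions, contexts from the mixture, coverage
#' from the negative-binomial law (with a forced zero-coverage fraction), a
#' methylation level per site from the context's Beta law, and methylated
#' read counts binomially given level and coverage. Byte-identical under a
#' fixed seed.
#'
#' @param spec A [sim_spec()].
#' @param sample_id Sample identifier.
#' @return A `MethylomeSample`; the true latent levels are attached as
#'   attribute `true_levels`.
#' @export
simulate_methylome <- function(spec, sample_id = "sim") {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, simulate_methylome_impl(spec, sample_id))
}

simulate_methylome_impl <- function(spec, sample_id) {
  alloc <- round(spec$n_sites * spec$chrom_sizes / sum(spec$chrom_sizes))
  alloc[1] <- alloc[1] + spec$n_sites - sum(alloc)
  parts <- lapply(seq_along(alloc), function(i) {
    n <- alloc[[i]]
    if (n == 0L) return(NULL)
    data.table::data.table(
      chrom = names(spec$chrom_sizes)[i],
      pos = sort(sample.int(spec$chrom_sizes[[i]], n)),
      strand = sample(c("+", "-"), n, replace = TRUE))
  })
  sites <- data.table::rbindlist(parts)
  n <- nrow(sites)
  sites[, context := sample(names(spec$context_props), n, replace = TRUE,
                            prob = spec$context_props)]
  n_total <- rnbinom(n, size = spec$coverage_dispersion,
                     mu = spec$coverage_mean)
  n_zero <- round(spec$zero_coverage_frac * n)
  if (n_zero > 0) n_total[sample.int(n, n_zero)] <- 0L
  level <- numeric(n)
  for (ctx in names(spec$level_beta)) {
    idx <- which(sites$context == ctx)
    ab <- spec$level_beta[[ctx]]
    level[idx] <- rbeta(length(idx), ab[1], ab[2])
  }
  sites[, n_total := as.integer(n_total)]
  sites[, n_meth := rbinom(n, n_total, level)]
  data.table::setorder(sites, chrom, pos, strand)
  out <- new_methylome_sample(sites, sample_id)
  data.table::setattr(out, "true_levels", level)
  out
}

# Bhattacharyya-angle inversion of the squared Hellinger divergence:
# HD(p,q) = 2 - 2 cos(theta_p - theta_q) with theta = asin(sqrt(level)).
# Returns NA when no q in [0,1] attains divergence h from p in direction dir.
invert_hd <- function(p, h, dir) {
  theta_p <- asin(sqrt(p))
  delta <- acos(pmin(pmax(1 - h / 2, -1), 1))
  theta_q <- theta_p + dir * delta
  ifelse(theta_q >= 0 & theta_q <= pi / 2, sin(theta_q)^2, NA_real_)
}

hd_max <- function(p) pmax(2 - 2 * sqrt(p), 2 - 2 * sqrt(1 - p))

#' Simulate a reference/query methylome pair with known truth
#'
#' The reference is drawn by [simulate_methylome()]. Query levels are then
#' constructed so that the site-level squared Hellinger divergences follow
#' the specified Weibull background law, by inverting the divergence at the
#' observed reference level (a redraw — up to `redraw_cap` per site — handles
#' boundary reference levels where a drawn divergence is unattainable).
#' Spiked signal sites receive a fixed divergence `effect` in the extreme
#' upper tail, placed at sites whose reference level can attain it. Query
#' read counts are the rounded product of level and coverage, so observed
#' divergences track the target law up to coverage quantization.
#'
#' @param spec A [sim_spec()].
#' @param redraw_cap Max redraws per site for infeasible background draws.
#' @return List with `reference` and `query` (`MethylomeSample`s) and
#'   `truth`: a `data.table` keyed like the sites with `spiked` flags and
#'   `target_divergence` (NA where either sample is unobserved).
#' @export
simulate_pair <- function(spec, redraw_cap = 100) {
  stopifnot(inherits(spec, "sim_spec"))
  ref <- simulate_methylome(spec, "reference")
  with_seed(spec$seed + 1L, {
    n <- nrow(ref)
    p_obs <- ifelse(ref$n_total > 0, ref$n_meth / ref$n_total, NA_real_)
    no <- spec$noise
    h <- no$mu + no$lambda * (-log(runif(n)))^(1 / no$alpha)  # Weibull draw

    n_spike <- spec$signal$n_sites %||% 0
    effect <- spec$signal$effect %||% (no$mu + 5 * no$lambda)
    spiked <- rep(FALSE, n)
    if (n_spike > 0) {
      if (effect <= no$lambda)
        warning("signal effect size <= background scale: ",
                "spikes are undetectable by construction")
      feasible <- which(!is.na(p_obs) & hd_max(p_obs) >= effect)
      if (length(feasible) < n_spike)
        stop(sprintf(paste0("only %d sites can attain the spike divergence ",
                            "%.3g; lower signal$n_sites or effect"),
                     length(feasible), effect), call. = FALSE)
      spiked[sample(feasible, n_spike)] <- TRUE
      h[spiked] <- effect
    }

    dir <- sample(c(-1, 1), n, replace = TRUE)
    q <- invert_hd(p_obs, h, dir)
    q2 <- invert_hd(p_obs, h, -dir)           # try the other direction
    q[is.na(q)] <- q2[is.na(q)]
    redraws <- 0L
    for (iter in seq_len(redraw_cap)) {
      bad <- which(is.na(q) & !is.na(p_obs) & !spiked)
      if (length(bad) == 0L) break
      redraws <- redraws + length(bad)
      hb <- no$mu + no$lambda * (-log(runif(length(bad))))^(1 / no$alpha)
      db <- sample(c(-1, 1), length(bad), replace = TRUE)
      qb <- invert_hd(p_obs[bad], hb, db)
      qb2 <- invert_hd(p_obs[bad], hb, -db)
      qb[is.na(qb)] <- qb2[is.na(qb)]
      q[bad] <- qb
      h[bad] <- hb
    }
    still <- is.na(q) & !is.na(p_obs)
    if (any(still)) q[still] <- p_obs[still]   # give up: zero divergence

    q_total <- rnbinom(n, size = spec$coverage_dispersion,
                       mu = spec$coverage_mean)
    n_zero <- round(spec$zero_coverage_frac * n)
    if (n_zero > 0) q_total[sample.int(n, n_zero)] <- 0L
    # unobserved reference sites: query level from its own context law
    miss <- is.na(p_obs)
    if (any(miss)) {
      q[miss] <- runif(sum(miss))
      h[miss] <- NA_real_
    }
    qsites <- data.table::data.table(
      chrom = ref$chrom, pos = ref$pos, strand = ref$strand,
      context = ref$context, n_total = as.integer(q_total))
    qsites[, n_meth := as.integer(round(q * n_total))]
    query <- new_methylome_sample(qsites, "query")
    truth <- data.table::data.table(
      chrom = ref$chrom, pos = ref$pos, strand = ref$strand,
      spiked = spiked,
      target_divergence = ifelse(is.na(p_obs) | q_total == 0, NA_real_, h))
    data.table::setattr(truth, "n_redraws", redraws)
    list(reference = ref, query = query, truth = truth)
  })
}

#' Simulate a scale-parameter trend
#'
#' Forward model of the persistence-length regressions: the linear
#' (long-fragment) form \eqn{\lambda(l) = (1-b)/\ln 2 + b\,l/(L_p \ln 2)} or
#' the exponential (entropic-spring) form \eqn{\lambda(l) = a e^{3l/(2L_p)}},
#' optionally perturbed by multiplicative Gaussian noise.
#'
#' @param model `"linear"` or `"exponential"`.
#' @param l_grid Lengths (same unit as `unit`).
#' @param Lp Persistence length (same unit as `l_grid`).
#' @param b Linear-model mixing coefficient in (0, 1).
#' @param a Exponential-model prefactor.
#' @param noise_sd Multiplicative noise standard deviation (0 = exact).
#' @param unit `"nm"` or `"bp"`.
#' @param seed Seed for the noise.
#' @return A `lambda_trend`.
#' @export
simulate_lambda_trend <- function(model = c("linear", "exponential"),
                                  l_grid, Lp = 50, b = 0.3, a = 1,
                                  noise_sd = 0, unit = "nm", seed = 1) {
  model <- match.arg(model)
  stopifnot(Lp > 0, length(l_grid) >= 2)
  lam <- switch(model,
    linear = (1 - b) / log(2) + b * l_grid / (Lp * log(2)),
    exponential = a * exp(1.5 * l_grid / Lp))
  if (noise_sd > 0)
    lam <- with_seed(seed, lam * (1 + rnorm(length(lam), 0, noise_sd)))
  trend <- data.table::data.table(l = as.numeric(l_grid), lambda_bar = lam,
                                  n_samples = 1L, sd = NA_real_)
  data.table::setorder(trend, l)
  data.table::setattr(trend, "unit", unit)
  data.table::setattr(trend, "class", c("lambda_trend", class(trend)))
  trend[]
}

#' Simulate a binary methylome with a known PWF length spectrum
#'
#' Concatenates words whose lengths follow the exponential decay law
#' \eqn{f_l = \phi e^{-\gamma l}} (counts Poisson-perturbed unless
#' `poisson = FALSE`), separated by zero-runs of length at least `d`, so that
#' [partition_pwf()] at threshold `d` recovers exactly the generated words.
#' Word interiors are random digits with zero-runs capped at `d - 1`.
#'
#' @param phi Spectrum prefactor (expected count at l = 0).
#' @param gamma Decay rate per digit (> 0).
#' @param d Separation threshold; at `d = 1` words are pure runs of 1s.
#' @param seed Seed.
#' @param max_l Longest word length considered (default: where the expected
#'   count drops below 0.5).
#' @param poisson Draw counts per length from Poisson (TRUE) or use rounded
#'   expected counts (FALSE).
#' @return A `BinaryMethylome` with attribute `truth_lengths` (the generated
#'   word-length multiset, sorted).
#' @export
simulate_pwf_string <- function(phi, gamma, d, seed = 1, max_l = NULL,
                                poisson = TRUE) {
  stopifnot(gamma > 0, phi > 0, d >= 1)
  max_l <- max_l %||% max(4L, ceiling(log(2 * phi) / gamma))
  with_seed(seed, {
    ls <- seq_len(max_l)
    f_exp <- phi * exp(-gamma * ls)
    f <- if (poisson) rpois(length(ls), f_exp) else round(f_exp)
    lengths <- rep(ls, f)
    if (length(lengths) == 0L)
      stop("spectrum produced no words; increase phi", call. = FALSE)
    lengths <- sample(lengths)               # shuffle word order
    words <- lapply(lengths, function(l) make_word(l, d))
    seps <- lapply(seq_along(words), function(i)
      integer(d + rpois(1, 2)))              # >= d zeros between words
    digits <- c(integer(sample.int(d, 1)),   # leading zeros
                unlist(Map(c, words, seps)))
    out <- data.table::data.table(chrom = "chr1",
                                  pos = seq_along(digits), strand = "*",
                                  digit = as.integer(digits),
                                  row = seq_along(digits))
    data.table::setattr(out, "class",
                        c("BinaryMethylome",
                          class(data.table::data.table())))
    data.table::setattr(out, "truth_lengths", sort(lengths))
    out[]
  })
}

# one word: starts/ends with 1, internal zero-runs <= d - 1
make_word <- function(l, d) {
  if (l <= 2L) return(rep(1L, l))
  w <- c(1L, rbinom(l - 2L, 1L, 0.5), 1L)
  run <- 0L
  for (i in seq_along(w)) {
    if (w[i] == 0L) {
      run <- run + 1L
      if (run >= d) { w[i] <- 1L; run <- 0L }
    } else run <- 0L
  }
  w
}
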