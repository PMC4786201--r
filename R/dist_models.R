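#' Three-parameter Weibull CDF
#'
#' \eqn{F(x) = 1 - \exp\{-((x-\mu)/\lambda)^\alpha\}} for \eqn{x > \mu},
#' 0 otherwise. This is the null model for region information \eqn{I_R} and
#' region divergences \eqn{D_R}; \eqn{\lambda} is the scale (in bits for
#' information), \eqn{\mu} the location, \eqn{\alpha} the shape.
#'
#' @param x Quantiles (vectorized).
#' @param alpha Shape (> 0).
#' @param lambda Scale (> 0).
#' @param mu Location (>= 0).
#' @return CDF values in \[0, 1).
#' @export
weibull_cdf <- function(x, alpha, lambda, mu = 0) {
  if (alpha <= 0 || lambda <= 0 || mu < 0)
    stop("invalid Weibull parameters (need alpha>0, lambda>0, mu>=0)",
         call. = FALSE)
  stats::pweibull(pmax(x - mu, 0), shape = alpha, scale = lambda)
}

#' Generalized-gamma CDF with location parameter
#'
#' Regularized lower-incomplete-gamma form
#' \eqn{F(x) = P(\psi, ((x-\mu)/\lambda)^\alpha)} for \eqn{\alpha > 0}
#' (and \eqn{1 - P(\cdot)} for \eqn{\alpha < 0}), where
#' \eqn{P(\psi, z) = \gamma(\psi, z)/\Gamma(\psi)}. Reduces exactly to the
#' Weibull CDF at \eqn{\psi = 1} since \eqn{\gamma(1, z) = 1 - e^{-z}}.
#'
#' @inheritParams weibull_cdf
#' @param psi Second shape parameter (> 0).
#' @return CDF values in \[0, 1).
#' @export
gg_cdf <- function(x, alpha, lambda, mu = 0, psi = 1) {
  if (alpha == 0) stop("alpha = 0 is not a valid generalized-gamma shape",
                       call. = FALSE)
  if (lambda <= 0 || mu < 0 || psi <= 0)
    stop("invalid generalized-gamma parameters", call. = FALSE)
  z <- pmax(x - mu, 0) / lambda
  if (alpha > 0) {
    stats::pgamma(z^alpha, shape = psi)
  } else {
    # negative-shape branch: F decreasing argument, complement form
    out <- 1 - stats::pgamma(z^alpha, shape = psi)
    out[x <= mu] <- 0
    out
  }
}

#' Stein's adjusted R-squared
#'
#' Estimator of average cross-validated predictive power:
#' \deqn{R^2_{adj} = 1 - \frac{n-1}{n-k-1}\cdot\frac{n-2}{n-k-2}\cdot
#'   \frac{n+1}{n}\,(1 - R^2)}
#'
#' @param r2 Ordinary R-squared.
#' @param n Number of data points.
#' @param k Number of free model parameters.
#' @return Stein-adjusted R-squared.
#' @export
stein_r2 <- function(r2, n, k) {
  if (n <= k + 2) stop("need n > k + 2 for Stein's formula", call. = FALSE)
  1 - ((n - 1) / (n - k - 1)) * ((n - 2) / (n - k - 2)) * ((n + 1) / n) *
    (1 - r2)
}

# least-squares information criteria: self-consistent across models fitted to
# the same ECDF, so only differences are meaningful
ls_aic <- function(n, rss, k) n * log(rss / n) + 2 * (k + 1)
ls_bic <- function(n, rss, k) n * log(rss / n) + log(n) * (k + 1)

#' Fit a Weibull or generalized-gamma CDF to an empirical CDF
#'
#' Nonlinear least squares of the model CDF against the pointwise empirical
#' CDF of the sorted values, using Hazen plotting positions
#' \eqn{u_i = (i - 0.5)/n}. Minimization uses bounded Gauss-Newton
#' (`nls(algorithm = "port")`) with an `optim(L-BFGS-B)` fallback on the same
#' objective. \eqn{\mu} is a fitted parameter bounded to
#' \eqn{[0, \min(values))}; \eqn{\alpha} is constrained positive. Values
#' below `min_value` (near-zero information artifacts) and non-finite values
#' (infinite KL sentinels) are excluded before fitting.
#'
#' @param values Positive observations (region \eqn{I_R} or \eqn{D_R}).
#' @param model `"weibull"` or `"gg"`.
#' @param init Optional named list/vector overriding starting values
#'   (`alpha`, `lambda`, `mu`, and `psi` for `"gg"`).
#' @param bounds Optional list with `lower`/`upper` named vectors overriding
#'   default box constraints.
#' @param min_value Exclusion floor (default `1e-8`).
#' @return A `FitResult`: list with `model`, `params` (named vector),
#'   `n_points`, `rss`, `r2`, `r2_adj_stein`, `aic`, `bic`, `converged`.
#'   Degenerate inputs yield `converged = FALSE`, never an uncaught error.
#' @export
fit_cdf <- function(values, model = c("weibull", "gg"), init = NULL,
                    bounds = NULL, min_value = 1e-8) {
  model <- match.arg(model)
  k <- if (model == "weibull") 3L else 4L
  x <- sort(values[is.finite(values) & values > min_value])
  n <- length(x)
  if (n < k + 2L)
    stop(sprintf("need at least %d finite values above the floor, got %d",
                 k + 2L, n), call. = FALSE)
  u <- (seq_len(n) - 0.5) / n

  start <- list(alpha = 1, lambda = max(stats::median(x) - 0.9 * min(x),
                                        1e-6),
                mu = 0.9 * min(x))
  if (model == "gg") start$psi <- 1
  if (!is.null(init)) start <- modifyList(start, as.list(init))
  lower <- c(alpha = 1e-3, lambda = 1e-9, mu = 0)
  upper <- c(alpha = 50, lambda = 1e6, mu = min(x) * (1 - 1e-9))
  if (model == "gg") {
    lower <- c(lower, psi = 1e-3); upper <- c(upper, psi = 100)
  }
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }
  # clamp starts into the box
  for (nm in names(start))
    start[[nm]] <- min(max(start[[nm]], lower[[nm]]), upper[[nm]])

  model_fun <- function(par) {
    if (model == "weibull")
      weibull_cdf(x, par[["alpha"]], par[["lambda"]], par[["mu"]])
    else
      gg_cdf(x, par[["alpha"]], par[["lambda"]], par[["mu"]], par[["psi"]])
  }

  try_fit <- function(st) {
    fit <- tryCatch({
      if (model == "weibull")
        nls(u ~ weibull_cdf(x, alpha, lambda, mu), start = st,
            lower = lower, upper = upper, algorithm = "port",
            control = list(maxiter = 200, warnOnly = FALSE))
      else
        nls(u ~ gg_cdf(x, alpha, lambda, mu, psi), start = st,
            lower = lower, upper = upper, algorithm = "port",
            control = list(maxiter = 200, warnOnly = FALSE))
    }, error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(est = coef(fit), conv = fit$convInfo$isConv %||% TRUE,
         rss = sum((model_fun(coef(fit)) - u)^2))
  }

  # multi-start over (alpha0, mu0): the (mu, lambda) trade-off creates
  # local optima near the support boundary
  starts <- list(start)
  if (is.null(init)) {
    for (a0 in c(0.5, 2)) {
      s <- start; s$alpha <- a0; starts <- c(starts, list(s))
    }
    s <- start; s$mu <- 0; starts <- c(starts, list(s))
  }

  est <- NULL; converged <- FALSE; best_rss <- Inf
  if (stats::sd(x) > 0) {
    for (st in starts) {
      res <- try_fit(st)
      if (!is.null(res) && res$rss < best_rss) {
        est <- res$est; converged <- res$conv; best_rss <- res$rss
      }
    }
    if (is.null(est)) {
      obj <- function(par) {
        par <- setNames(par, names(start))
        sum((model_fun(par) - u)^2)
      }
      opt <- tryCatch(
        optim(unlist(start), obj, method = "L-BFGS-B",
              lower = lower[names(start)], upper = upper[names(start)]),
        error = function(e) NULL)
      if (!is.null(opt)) {
        est <- setNames(opt$par, names(start))
        converged <- opt$convergence == 0
      }
    }
  }

  if (is.null(est)) {
    est <- setNames(rep(NA_real_, length(start)), names(start))
    rss <- NA_real_; r2 <- NA_real_; r2s <- NA_real_
    aic <- NA_real_; bic <- NA_real_
  } else {
    resid <- model_fun(est) - u
    rss <- sum(resid^2)
    tss <- sum((u - mean(u))^2)
    r2 <- 1 - rss / tss
    r2s <- stein_r2(r2, n, k)
    aic <- ls_aic(n, rss, k)
    bic <- ls_bic(n, rss, k)
  }
  structure(list(model = model, params = est, n_points = n, rss = rss,
                 r2 = r2, r2_adj_stein = r2s, aic = aic, bic = bic,
                 converged = isTRUE(converged)),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult [%s]%s: n = %d\n", x$model,
              if (x$converged) "" else " (NOT converged)", x$n_points))
  if (!anyNA(x$params))
    cat("  ", paste(sprintf("%s = %.6g", names(x$params), x$params),
                    collapse = ", "), "\n")
  cat(sprintf("  RSS = %.4g, R2 = %.5f, Stein R2 = %.5f, AIC = %.2f, BIC = %.2f\n",
              x$rss, x$r2, x$r2_adj_stein, x$aic, x$bic))
  invisible(x)
}

# evaluate a FitResult's CDF at new points
fit_result_cdf <- function(fit, x) {
  p <- fit$params
  if (fit$model == "weibull")
    weibull_cdf(x, p[["alpha"]], p[["lambda"]], p[["mu"]])
  else
    gg_cdf(x, p[["alpha"]], p[["lambda"]], p[["mu"]], p[["psi"]])
}

#' Rank fitted null models and flag physically implausible scales
#'
#' Ranks converged fits by AIC. Independently of the ranking, a fit whose
#' scale estimate \eqn{\hat\lambda} falls outside `lambda_bounds` is flagged
#' implausible — near-zero scales are meaningless as an average energy
#' contribution per molecule and indicate a failed physical model even when
#' the AIC looks good.
#'
#' @param fits A list of `FitResult` objects (at least one converged).
#' @param lambda_bounds Plausible interval for \eqn{\hat\lambda}
#'   (default `c(1e-6, 1e6)` bits).
#' @return A `data.table` ranked by AIC: `rank, model, aic, bic, r2,
#'   r2_adj_stein, lambda, plausible`, with the fit objects in the
#'   list-column `fit`.
#' @export
select_model <- function(fits, lambda_bounds = c(1e-6, 1e6)) {
  if (inherits(fits, "FitResult")) fits <- list(fits)
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0L)
    stop("no converged fits to rank", call. = FALSE)
  tab <- data.table::data.table(
    model = vapply(conv, `[[`, character(1), "model"),
    aic = vapply(conv, `[[`, numeric(1), "aic"),
    bic = vapply(conv, `[[`, numeric(1), "bic"),
    r2 = vapply(conv, `[[`, numeric(1), "r2"),
    r2_adj_stein = vapply(conv, `[[`, numeric(1), "r2_adj_stein"),
    lambda = vapply(conv, function(f) f$params[["lambda"]], numeric(1)),
    fit = conv)
  data.table::setorder(tab, aic)
  tab[, rank := .I]
  tab[, plausible := lambda >= lambda_bounds[1] & lambda <= lambda_bounds[2]]
  data.table::setcolorder(tab, c("rank", "model", "aic", "bic", "r2",
                                 "r2_adj_stein", "lambda", "plausible"))
  tab[]
}
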