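#' Aggregate fitted scale parameters across region lengths
#'
#' Collects per-(sample, length) Weibull/GG scale estimates
#' \eqn{\hat\lambda(l)} into the empirical mean trend \eqn{\bar\lambda(l)}
#' used for persistence-length regression. Only converged (and, if the column
#' is present, plausible) fits enter the averages.
#'
#' @param fits A data frame with columns `l` (region length), `lambda`
#'   (fitted scale), optionally `sample`, `converged`, `plausible`.
#' @param unit Unit of `l`: `"bp"` or `"nm"`.
#' @return A `lambda_trend`: `data.table` with `l, lambda_bar, n_samples,
#'   sd` (NA sd when a single sample), unit stored as attribute.
#' @export
lambda_trend <- function(fits, unit = c("bp", "nm")) {
  unit <- match.arg(unit)
  fits <- data.table::as.data.table(fits)
  if ("converged" %in% names(fits)) fits <- fits[converged == TRUE]
  if ("plausible" %in% names(fits)) fits <- fits[plausible == TRUE]
  if (!all(c("l", "lambda") %in% names(fits)))
    stop("`fits` needs columns l and lambda", call. = FALSE)
  if (any(fits$l <= 0) || any(fits$lambda <= 0))
    stop("lengths and scales must be positive", call. = FALSE)
  trend <- fits[, .(lambda_bar = mean(lambda), n_samples = .N,
                    sd = if (.N > 1L) stats::sd(lambda) else NA_real_),
                by = l]
  if (nrow(trend) < 2L)
    stop("need fits at >= 2 distinct region lengths", call. = FALSE)
  data.table::setorder(trend, l)
  data.table::setattr(trend, "unit", unit)
  data.table::setattr(trend, "class", c("lambda_trend", class(trend)))
  trend[]
}

#' Convert a lambda trend's lengths from bp to nm
#'
#' Uses the B-DNA rise of 0.34 nm per bp (so 100 bp ~ 34 nm). For trends
#' built from binary-word lengths measured in cytosine digits, the same
#' factor applies under the approximation that consecutive digits are
#' adjacent base pairs.
#'
#' @param trend A `lambda_trend` in bp.
#' @return The trend with `l` in nm.
#' @export
trend_to_nm <- function(trend) {
  stopifnot(inherits(trend, "lambda_trend"))
  if (attr(trend, "unit") == "nm") return(trend)
  out <- data.table::copy(trend)
  out[, l := l * .NM_PER_BP]
  data.table::setattr(out, "unit", "nm")
  out[]
}

new_persistence_estimate <- function(model, coeffs, Lp_nm, r2, valid,
                                     note = NULL) {
  structure(list(model = model, coeffs = coeffs, Lp_nm = Lp_nm,
                 fit_r2 = r2, valid = valid, note = note),
            class = "persistence_estimate")
}

#' @export
print.persistence_estimate <- function(x, ...) {
  cat(sprintf("Persistence length (%s model): Lp = %.4g nm%s\n", x$model,
              x$Lp_nm, if (x$valid) "" else "  [INVALID]"))
  cat("  coefficients:",
      paste(sprintf("%s = %.6g", names(x$coeffs), x$coeffs), collapse = ", "),
      sprintf("; R2 = %.5f\n", x$fit_r2))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

check_nm <- function(trend) {
  if (!inherits(trend, "lambda_trend"))
    stop("`trend` must be a lambda_trend", call. = FALSE)
  if (attr(trend, "unit") != "nm")
    stop("persistence length is only meaningful in nm; convert with ",
         "trend_to_nm()", call. = FALSE)
  if (nrow(trend) < 3L)
    stop("need >= 3 distinct lengths for a persistence regression",
         call. = FALSE)
  invisible(trend)
}

#' Persistence length from the linear (long-fragment) scale trend
#'
#' For regions much longer than the persistence length, the scale trend is
#' linear: \eqn{\lambda(l) = (1-b)/\ln 2 + b\,l/(L_p \ln 2)}. An ordinary
#' least-squares line \eqn{\hat\lambda(l) = a' + b' l} then gives
#' \eqn{\hat L_p = (1 - a' \ln 2)/(b' \ln 2)}.
#'
#' @param trend A `lambda_trend` with lengths in nm (see [trend_to_nm()]).
#' @return A `persistence_estimate` with coefficients `a_prime, b_prime`;
#'   flagged invalid when the slope is non-positive or the implied
#'   \eqn{L_p} is not positive.
#' @export
persistence_linear <- function(trend) {
  check_nm(trend)
  fit <- lm(lambda_bar ~ l, data = trend)
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  # manual R2: summary.lm warns on noiseless (exact) trends
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((trend$lambda_bar - mean(trend$lambda_bar))^2)
  coeffs <- c(a_prime = a, b_prime = b)
  if (b <= 0)
    return(new_persistence_estimate("linear", coeffs, NA_real_, r2, FALSE,
                                    "non-positive slope"))
  Lp <- (1 - a * log(2)) / (b * log(2))
  valid <- is.finite(Lp) && Lp > 0
  new_persistence_estimate("linear", coeffs, Lp, r2, valid,
                           if (!valid) "implied Lp <= 0")
}

#' Persistence length from the exponential (entropic-spring) scale trend
#'
#' Short DNA fragments (lengths up to ~ the persistence length) behave as a
#' linear entropic spring, which makes the scale trend exponential:
#' \eqn{\lambda(l) = a\,e^{3l/(2 L_p)}}. A nonlinear fit
#' \eqn{\hat\lambda(l) = \hat a\,e^{\hat d l}} gives
#' \eqn{\hat L_p = 3/(2\hat d)}. The estimate is scale-consistent: rescaling
#' all \eqn{\bar\lambda} changes \eqn{\hat a} only.
#'
#' @inheritParams persistence_linear
#' @return A `persistence_estimate` with coefficients `a, d`; flagged invalid
#'   when \eqn{\hat d \le 0} (no decaying stiffness scale).
#' @export
persistence_exponential <- function(trend) {
  check_nm(trend)
  # log-linear start, then nonlinear refinement on the original scale
  lf <- lm(log(lambda_bar) ~ l, data = trend)
  start <- list(a = exp(unname(coef(lf)[1])), d = unname(coef(lf)[2]))
  fit <- tryCatch(
    nls(lambda_bar ~ a * exp(d * l), data = trend, start = start,
        control = list(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    a <- start$a; d <- start$d
    resid <- trend$lambda_bar - a * exp(d * trend$l)
  } else {
    a <- unname(coef(fit)[["a"]]); d <- unname(coef(fit)[["d"]])
    resid <- stats::residuals(fit)
  }
  r2 <- 1 - sum(resid^2) / sum((trend$lambda_bar - mean(trend$lambda_bar))^2)
  coeffs <- c(a = a, d = d)
  if (d <= 0)
    return(new_persistence_estimate("exponential", coeffs, NA_real_, r2,
                                    FALSE, "non-positive exponent"))
  new_persistence_estimate("exponential", coeffs, 3 / (2 * d), r2, TRUE)
}
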