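## Logistic truth-state distribution: (mu, s) location-scale family with the
## equivalent (intercept, slope) = (-mu/s, 1/s) parameterization, and its
## maximum-likelihood / grid-posterior fitting.

#' Logistic truth-state distribution
#'
#' A location--scale logistic distribution in driver units, carrying both the
#' natural \code{(mu, s)} parameters and the derived \code{(-mu/s, 1/s)}
#' intercept/slope parameterization used when the CDF is written as a logit
#' that is linear in the driver.
#'
#' @param mu location (median) in driver units.
#' @param s scale in driver units, strictly positive. The standard deviation
#'   is \code{s * pi / sqrt(3)}.
#' @return Object of class \code{"logis_dist"}.
#' @export
logis_dist <- function(mu, s) {
  stopifnot(is.finite(mu), is.finite(s))
  if (s <= 0) stop("logistic scale must be > 0")
  structure(list(mu = mu, s = s, intercept_param = -mu / s,
                 slope_param = 1 / s),
            class = "logis_dist")
}

#' @export
print.logis_dist <- function(x, ...) {
  cat(sprintf("logistic(mu = %.4g, s = %.4g)  [intercept %.4g, slope %.4g]\n",
              x$mu, x$s, x$intercept_param, x$slope_param))
  invisible(x)
}

#' Cumulative distribution of a logistic truth-state distribution
#'
#' @param dist a [logis_dist()].
#' @param x driver value(s).
#' @return \code{P(X <= x)}, i.e. \code{1 / (1 + exp(-(x - mu)/s))}.
#' @export
logistic_cdf <- function(dist, x) stats::plogis(x, dist$mu, dist$s)

#' Density of a logistic truth-state distribution
#'
#' @inheritParams logistic_cdf
#' @return Density per driver unit; maximum \code{1/(4 s)} at \code{x = mu}.
#' @export
logistic_pdf <- function(dist, x) stats::dlogis(x, dist$mu, dist$s)

logis_loglik <- function(mu, s, values) sum(stats::dlogis(values, mu, s, log = TRUE))

#' Fit a logistic distribution to driver values
#'
#' Default method \code{"mle"} maximizes the logistic log-likelihood over
#' \code{(mu, log s)} by quasi-Newton optimization from a method-of-moments
#' start (sample median; scale from the sample SD via
#' \code{s = sd * sqrt(3)/pi}). Method \code{"bayes_grid"} computes the
#' posterior of the \code{(-mu/s, 1/s)} parameterization on a bounded grid
#' under weakly informative priors -- normal(0, 10^2) on the intercept and
#' half-normal(10) on the slope -- and reports marginal posterior medians.
#' Groups with fewer than 5 distinct values, or zero spread, are refused.
#'
#' @param values numeric driver values.
#' @param method \code{"mle"} or \code{"bayes_grid"}.
#' @param grid_n per-dimension grid resolution for \code{"bayes_grid"}.
#' @return A [logis_dist()] with attributes \code{method}, \code{n},
#'   \code{loglik} and (for mle) the observed-information standard errors
#'   \code{se}.
#' @export
fit_logistic <- function(values, method = c("mle", "bayes_grid"),
                         grid_n = 201) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) < 5L)
    stop("fit refused: need at least 5 values, got ", length(values))
  if (length(unique(values)) < 5L)
    stop("fit refused: need at least 5 distinct values")
  if (stats::sd(values) == 0) stop("fit refused: zero spread")

  s0 <- stats::sd(values) * sqrt(3) / pi
  if (method == "mle") {
    nll <- function(p) {
      v <- -logis_loglik(p[1], exp(p[2]), values)
      if (!is.finite(v)) return(.Machine$double.xmax / 2)
      v
    }
    # analytic gradient in (mu, log s): with z = (x - mu)/s,
    # d loglik/d mu = sum(2 plogis(z) - 1)/s, d loglik/d log s =
    # sum((2 plogis(z) - 1) z) - n
    ngr <- function(p) {
      s <- exp(p[2]); z <- (values - p[1]) / s
      w <- 2 * stats::plogis(z) - 1
      -c(sum(w) / s, sum(w * z) - length(values))
    }
    opt <- stats::optim(c(stats::median(values), log(s0)), nll, gr = ngr,
                        method = "BFGS",
                        control = list(reltol = 1e-12, maxit = 500))
    if (opt$convergence != 0) {  # fall back to Nelder-Mead on a stall
      opt2 <- stats::optim(opt$par, nll,
                           control = list(reltol = 1e-12, maxit = 2000))
      if (opt2$value < opt$value) opt <- opt2
    }
    d <- logis_dist(opt$par[1], exp(opt$par[2]))
    h <- stats::optimHess(opt$par, nll)
    se <- tryCatch(sqrt(diag(solve(h))), error = function(e) c(NA, NA))
    attr(d, "se") <- c(mu = se[1], log_s = se[2])
    attr(d, "loglik") <- -opt$value
  } else {
    d <- fit_logistic_bayes(values, s0, grid_n)
  }
  attr(d, "method") <- method
  attr(d, "n") <- length(values)
  d
}

# Grid posterior over (intercept, slope) = (-mu/s, 1/s). The grid is centred
# on the MLE and spans +/- 6 approximate standard errors (bounded below at
# slope > 0); posterior mass outside the box is negligible for n >= 5.
fit_logistic_bayes <- function(values, s0, grid_n) {
  mle <- stats::optim(c(stats::median(values), log(s0)),
                      function(p) -logis_loglik(p[1], exp(p[2]), values),
                      method = "BFGS", control = list(reltol = 1e-12))
  mu_hat <- mle$par[1]; s_hat <- exp(mle$par[2])
  n <- length(values)
  a_hat <- -mu_hat / s_hat; b_hat <- 1 / s_hat
  half_a <- 6 * max(3 / (s_hat * sqrt(n)) * max(1, abs(a_hat)), 0.05)
  half_b <- 6 * max(b_hat / sqrt(n), 0.01 * b_hat)
  a_grid <- seq(a_hat - half_a, a_hat + half_a, length.out = grid_n)
  b_grid <- seq(max(b_hat - half_b, b_hat / 20), b_hat + half_b,
                length.out = grid_n)
  logpost <- outer(a_grid, b_grid, Vectorize(function(a, b) {
    logis_loglik(-a / b, 1 / b, values) +
      stats::dnorm(a, 0, 10, log = TRUE) +
      stats::dnorm(b, 0, 10, log = TRUE)  # half-normal: b > 0 on the grid
  }))
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  marg_med <- function(grid, p) {
    cm <- cumsum(p / sum(p))
    grid[which(cm >= 0.5)[1]]
  }
  a_med <- marg_med(a_grid, rowSums(w))
  b_med <- marg_med(b_grid, colSums(w))
  d <- logis_dist(-a_med / b_med, 1 / b_med)
  attr(d, "posterior") <- list(intercept_grid = a_grid, slope_grid = b_grid,
                               intercept_median = a_med, slope_median = b_med)
  d
}
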