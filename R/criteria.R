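## ROC accuracy (double-logit linearization), likelihood-ratio utility
## curves, and unbiased / expected-value-optimal decision criteria.

LOGIT_EPS <- 1e-12

clamp_logit <- function(p) {
  p <- pmin(pmax(p, LOGIT_EPS), 1 - LOGIT_EPS)
  log(p / (1 - p))
}

#' ROC accuracy of a decision model
#'
#' A positive decision corresponds to the driver exceeding a criterion c, so
#' \code{P_TP(c) = 1 - CDF_pos(c)} and \code{P_FP(c) = 1 - CDF_neg(c)}. For
#' logistic truth-state distributions the logits of these probabilities are
#' exactly affine in each other:
#' \deqn{logit P_{TP} = (s^-/s^+)\, logit P_{FP} + (\mu^+ - \mu^-)/s^+}
#' The slope \code{s_neg/s_pos} is the truth-state scale ratio and the
#' intercept measures accuracy (0 with slope 1 is chance performance).
#'
#' @param model a \code{"uvsdt"} model.
#' @param grid criterion values; defaults to the model's driver grid.
#' @return List of class \code{"roc_accuracy"}: \code{roc_slope},
#'   \code{roc_intercept} and a \code{curve} data frame with columns
#'   \code{criterion}, \code{p_fp}, \code{p_tp}, \code{logit_fp},
#'   \code{logit_tp}.
#' @export
roc_accuracy <- function(model, grid = NULL) {
  stopifnot(inherits(model, "uvsdt"))
  g <- if (is.null(grid)) model$spec$grid else grid
  p_tp <- 1 - logistic_cdf(model$dist_pos, g)
  p_fp <- 1 - logistic_cdf(model$dist_neg, g)
  structure(list(
    roc_slope = model$dist_neg$s / model$dist_pos$s,
    roc_intercept = (model$dist_pos$mu - model$dist_neg$mu) / model$dist_pos$s,
    curve = data.frame(criterion = g, p_fp = p_fp, p_tp = p_tp,
                       logit_fp = clamp_logit(p_fp),
                       logit_tp = clamp_logit(p_tp))),
    class = "roc_accuracy")
}

#' @export
print.roc_accuracy <- function(x, ...) {
  cat(sprintf("ROC accuracy: slope %.4f, intercept %.4f (%d criteria)\n",
              x$roc_slope, x$roc_intercept, nrow(x$curve)))
  invisible(x)
}

#' Likelihood-ratio curve of a decision model
#'
#' The likelihood ratio at driver value x is the ratio of the positive to
#' negative truth-state densities, \code{f_pos(x)/f_neg(x)}
#' (mode \code{"density_ratio"}); mode \code{"posterior_odds"} additionally
#' multiplies by the prior odds \code{P(T+)/P(T-)}. Grid points where the
#' denominator underflows (the division can explode in the far tails) are
#' flagged and excluded from downstream summaries.
#'
#' @param model a \code{"uvsdt"} model.
#' @param grid driver values; defaults to the model's grid.
#' @param mode \code{"density_ratio"} or \code{"posterior_odds"}.
#' @return List of class \code{"lr_curve"}: \code{grid}, \code{lr},
#'   logical \code{flagged}, and \code{mode}.
#' @export
likelihood_ratio <- function(model, grid = NULL,
                             mode = c("density_ratio", "posterior_odds")) {
  stopifnot(inherits(model, "uvsdt"))
  mode <- match.arg(mode)
  g <- if (is.null(grid)) model$spec$grid else grid
  num <- logistic_pdf(model$dist_pos, g)
  den <- logistic_pdf(model$dist_neg, g)
  flagged <- den < .Machine$double.xmin * 1e4 | !is.finite(num / den)
  lr <- ifelse(flagged, NA_real_, num / den)
  if (mode == "posterior_odds")
    lr <- lr * model$prior_pos / model$prior_neg
  structure(list(grid = g, lr = lr, flagged = flagged, mode = mode),
            class = "lr_curve")
}

#' @export
print.lr_curve <- function(x, ...) {
  cat(sprintf("Likelihood-ratio curve (%s): %d points, %d flagged; range [%.3g, %.3g]\n",
              x$mode, length(x$grid), sum(x$flagged),
              min(x$lr, na.rm = TRUE), max(x$lr, na.rm = TRUE)))
  invisible(x)
}

# All roots of lr(x) = target on the driver axis: scan the grid for sign
# changes of log(lr) - log(target), refine each bracket by uniroot.
lr_roots <- function(model, target, tol = 1e-6) {
  g <- model$spec$grid
  f <- function(x) log(logistic_pdf(model$dist_pos, x)) -
    log(logistic_pdf(model$dist_neg, x)) - log(target)
  fg <- f(g)
  ok <- is.finite(fg)
  g <- g[ok]; fg <- fg[ok]
  if (length(g) < 2L) return(numeric(0))
  sgn <- sign(fg)
  roots <- g[fg == 0]
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    r <- stats::uniroot(f, c(g[i], g[i + 1]), tol = tol * 1e-3)$root
    roots <- c(roots, r)
  }
  sort(unique(roots))
}

#' Unbiased decision criterion
#'
#' The driver value at which the likelihood ratio equals 1 (density-ratio
#' mode), found by bracketed root-finding over the driver grid and refined
#' to \code{|L - 1| < 1e-6}. With equal truth-state scales this is the
#' midpoint \code{(mu_pos + mu_neg)/2}. Unequal-variance models can have no
#' crossing on the axis (an error) or two crossings (both are returned, with
#' a warning).
#'
#' @param model a \code{"uvsdt"} model.
#' @return Driver value(s) where the likelihood ratio is 1.
#' @export
unbiased_criterion <- function(model) {
  if (isTRUE(all.equal(model$dist_pos$mu, model$dist_neg$mu)) &&
      isTRUE(all.equal(model$dist_pos$s, model$dist_neg$s)))
    stop("no unbiased criterion: identical truth-state distributions (L = 1 everywhere)")
  r <- lr_roots(model, 1)
  if (length(r) == 0L)
    stop("no unbiased criterion: likelihood ratio does not cross 1 on the driver axis")
  if (length(r) > 1L)
    warning("multiple unbiased criteria (unequal-variance model): returning all")
  r
}

#' Payoff matrix for expected-value analysis
#'
#' Benefits attach to truth-state/decision agreements, costs to
#' disagreements, all in arbitrary common utility units.
#'
#' @param benefit_pos benefit of a positive decision under T+ (hit).
#' @param benefit_neg benefit of a negative decision under T- (correct rejection).
#' @param cost_miss cost of a negative decision under T+ (miss).
#' @param cost_fa cost of a positive decision under T- (false alarm).
#' @return List of class \code{"payoff_matrix"}.
#' @export
payoff_matrix <- function(benefit_pos = 1, benefit_neg = 1,
                          cost_miss = 1, cost_fa = 1) {
  vals <- c(benefit_pos, benefit_neg, cost_miss, cost_fa)
  if (any(vals < 0)) stop("payoffs must be non-negative")
  if (benefit_pos + cost_miss <= 0)
    stop("benefit_pos + cost_miss must be > 0")
  structure(list(benefit_pos = benefit_pos, benefit_neg = benefit_neg,
                 cost_miss = cost_miss, cost_fa = cost_fa),
            class = "payoff_matrix")
}

#' Expected-value-optimal decision criterion
#'
#' The criterion maximizing expected value places the decision threshold
#' where the likelihood ratio equals
#' \deqn{\beta = \frac{P(T^-)}{P(T^+)} \cdot
#'   \frac{B(T^-\&D^-) + C(T^-\&D^+)}{B(T^+\&D^+) + C(T^+\&D^-)}}
#' With equal priors and equal payoffs \eqn{\beta = 1} and the optimal
#' criterion coincides with the unbiased one.
#'
#' @param model a \code{"uvsdt"} model (its priors supply the prior odds).
#' @param payoffs a [payoff_matrix()].
#' @return List with \code{beta} and \code{criterion} (driver value(s) with
#'   \code{L(c) = beta} to 1e-6).
#' @export
optimal_criterion <- function(model, payoffs = payoff_matrix()) {
  stopifnot(inherits(payoffs, "payoff_matrix"))
  beta <- (model$prior_neg / model$prior_pos) *
    (payoffs$benefit_neg + payoffs$cost_fa) /
    (payoffs$benefit_pos + payoffs$cost_miss)
  r <- lr_roots(model, beta)
  if (length(r) == 0L) {
    lr <- likelihood_ratio(model)
    stop(sprintf(
      "target likelihood ratio %.4g unattainable on the driver axis (range [%.4g, %.4g])",
      beta, min(lr$lr, na.rm = TRUE), max(lr$lr, na.rm = TRUE)))
  }
  list(beta = beta, criterion = r)
}

#' Classify a decision criterion from its likelihood-ratio value
#'
#' A criterion with likelihood ratio above 1 is strict (positive decisions
#' are reserved for driver values where success is the more likely state),
#' below 1 lenient, and near 1 unbiased.
#'
#' @param lr_value likelihood ratio(s) at the criterion, > 0.
#' @param tol half-width of the unbiased band around 1.
#' @return Character vector: \code{"strict"}, \code{"lenient"} or
#'   \code{"unbiased"}.
#' @export
classify_criterion <- function(lr_value, tol = 0.05) {
  if (any(lr_value <= 0, na.rm = TRUE)) stop("likelihood ratio must be > 0")
  ifelse(lr_value > 1 + tol, "strict",
         ifelse(lr_value < 1 - tol, "lenient", "unbiased"))
}
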