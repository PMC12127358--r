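## The unequal-variance signal-detection model of a treatment decision:
## a pair of logistic truth-state distributions on the driver axis plus
## prior truth-state probabilities.

#' Construct an unequal-variance signal-detection model directly
#'
#' Assembles a truth-state model from known parameters, without fitting.
#' Useful for analytic work and for ground-truth models from the synthetic
#' cohort generator.
#'
#' @param dist_pos [logis_dist()] of the driver under the positive truth
#'   state (treatment success).
#' @param dist_neg [logis_dist()] under the negative truth state.
#' @param prior_pos prior probability of the positive truth state, in (0,1).
#' @param spec a [driver_spec()]; defaults to the SEDEP pairing.
#' @return Object of class \code{"uvsdt"}.
#' @export
uvsdt_model <- function(dist_pos, dist_neg, prior_pos = 0.5,
                        spec = driver_spec("sedep")) {
  stopifnot(inherits(dist_pos, "logis_dist"), inherits(dist_neg, "logis_dist"))
  if (prior_pos <= 0 || prior_pos >= 1) stop("prior_pos must be in (0, 1)")
  structure(list(dist_pos = dist_pos, dist_neg = dist_neg,
                 prior_pos = prior_pos, prior_neg = 1 - prior_pos,
                 spec = spec, n_pos = NA_integer_, n_neg = NA_integer_,
                 method = "analytic", call = sys.call()),
            class = "uvsdt")
}

#' Fit the unequal-variance signal-detection model to a cohort
#'
#' The model assumes the decision driver (hearing loss for the SEDEP
#' decision, baseline THI for the PCU decision) is logistically distributed
#' within each truth state, with state-specific location and scale. Records
#' are labelled by THI improvement (> \code{threshold} points = positive
#' truth state) and the driver values of each state are fitted with
#' [fit_logistic()]. The prior positive-state probability defaults to the
#' labelled-state fraction. At least 5 labelled records per state are
#' required.
#'
#' @param x a [cohort()].
#' @param pairing \code{"sedep"} or \code{"pcu"} (see [driver_spec()]).
#' @param method fitting method, passed to [fit_logistic()].
#' @param threshold THI improvement threshold in points.
#' @param prior_pos optional override of the positive-state prior.
#' @param grid_n criterion grid resolution for downstream curves.
#' @return Object of class \code{"uvsdt"}: the two fitted [logis_dist()]
#'   objects, priors, state counts and the driver specification.
#' @examples
#' co <- simulate_cohort(synthetic_config(seed = 1))$cohort
#' fit <- uvsdt(co, pairing = "sedep")
#' coef(fit)
#' @export
uvsdt <- function(x, pairing = c("sedep", "pcu"),
                  method = c("mle", "bayes_grid"), threshold = 7,
                  prior_pos = NULL, grid_n = 512) {
  stopifnot(inherits(x, "cohort"))
  pairing <- match.arg(pairing)
  method <- match.arg(method)
  spec <- driver_spec(pairing, grid_n)
  st <- driver_by_state(x, spec, threshold)
  for (state in c("pos", "neg"))
    if (length(st[[state]]) < 5L)
      stop(sprintf("fit refused: fewer than 5 labelled records in state T_%s (%d)",
                   state, length(st[[state]])))
  dist_pos <- fit_logistic(st$pos, method)
  dist_neg <- fit_logistic(st$neg, method)
  if (is.null(prior_pos))
    prior_pos <- length(st$pos) / (length(st$pos) + length(st$neg))
  out <- uvsdt_model(dist_pos, dist_neg, prior_pos, spec)
  out$n_pos <- length(st$pos)
  out$n_neg <- length(st$neg)
  out$n_unlabelled <- st$n_unlabelled
  out$method <- method
  out$call <- match.call()
  out
}

#' @export
print.uvsdt <- function(x, ...) {
  cat(sprintf("Unequal-variance SDT model (%s, driver %s)\n",
              x$spec$decision_name, x$spec$driver_name))
  cat(sprintf("  T+: mu = %8.3f  s = %7.3f%s\n", x$dist_pos$mu, x$dist_pos$s,
              if (is.na(x$n_pos)) "" else sprintf("  (n = %d)", x$n_pos)))
  cat(sprintf("  T-: mu = %8.3f  s = %7.3f%s\n", x$dist_neg$mu, x$dist_neg$s,
              if (is.na(x$n_neg)) "" else sprintf("  (n = %d)", x$n_neg)))
  cat(sprintf("  P(T+) = %.3f\n", x$prior_pos))
  invisible(x)
}

#' Model coefficients
#'
#' @param object a fitted \code{"uvsdt"} model.
#' @param ... unused.
#' @return Named vector: truth-state locations and scales, the prior, and
#'   the derived ROC accuracy parameters \code{roc_slope = s_neg/s_pos} and
#'   \code{roc_intercept = (mu_pos - mu_neg)/s_pos}.
#' @export
coef.uvsdt <- function(object, ...) {
  c(mu_pos = object$dist_pos$mu, s_pos = object$dist_pos$s,
    mu_neg = object$dist_neg$mu, s_neg = object$dist_neg$s,
    prior_pos = object$prior_pos,
    roc_slope = object$dist_neg$s / object$dist_pos$s,
    roc_intercept = (object$dist_pos$mu - object$dist_neg$mu) / object$dist_pos$s)
}

#' @export
summary.uvsdt <- function(object, ...) {
  cf <- coef(object)
  acc <- roc_accuracy(object)
  ub <- tryCatch(unbiased_criterion(object), error = function(e) NA_real_)
  structure(list(model = object, coef = cf,
                 roc_slope = acc$roc_slope, roc_intercept = acc$roc_intercept,
                 unbiased = ub,
                 classification = if (all(is.na(ub))) NA_character_ else
                   "criterion where likelihood ratio = 1"),
            class = "summary.uvsdt")
}

#' @export
print.summary.uvsdt <- function(x, ...) {
  print(x$model)
  cat(sprintf("  ROC: slope = %.4f, intercept = %.4f\n",
              x$roc_slope, x$roc_intercept))
  if (!all(is.na(x$unbiased)))
    cat(sprintf("  unbiased criterion (L = 1) at %s %s\n",
                paste(sprintf("%.3f", x$unbiased), collapse = ", "),
                x$model$spec$driver_name))
  invisible(x)
}

#' Model predictions along the driver axis
#'
#' @param object a \code{"uvsdt"} model.
#' @param newdata driver values; defaults to the criterion grid.
#' @param type \code{"lr"} for the likelihood ratio, \code{"posterior"} for
#'   the posterior probability of the positive truth state, \code{"tp"} /
#'   \code{"fp"} for the true/false-positive probabilities of a criterion
#'   placed at each value.
#' @param ... unused.
#' @return Numeric vector, one value per element of \code{newdata}.
#' @export
predict.uvsdt <- function(object, newdata = NULL,
                          type = c("lr", "posterior", "tp", "fp"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$spec$grid else newdata
  switch(type,
    lr = logistic_pdf(object$dist_pos, x) / logistic_pdf(object$dist_neg, x),
    posterior = {
      fp <- logistic_pdf(object$dist_pos, x) * object$prior_pos
      fn <- logistic_pdf(object$dist_neg, x) * object$prior_neg
      fp / (fp + fn)
    },
    tp = 1 - logistic_cdf(object$dist_pos, x),
    fp = 1 - logistic_cdf(object$dist_neg, x))
}

#' Simulate driver values from a fitted model
#'
#' Draws truth states from the prior, then driver values from the matching
#' truth-state distribution.
#'
#' @param object a \code{"uvsdt"} model.
#' @param nsim number of draws.
#' @param seed optional seed, set via \code{set.seed}.
#' @param ... unused.
#' @return Data frame with columns \code{truth} and \code{driver}.
#' @export
simulate.uvsdt <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  state <- stats::rbinom(nsim, 1, object$prior_pos) == 1
  x <- numeric(nsim)
  x[state] <- stats::rlogis(sum(state), object$dist_pos$mu, object$dist_pos$s)
  x[!state] <- stats::rlogis(sum(!state), object$dist_neg$mu, object$dist_neg$s)
  data.frame(truth = ifelse(state, "T_pos", "T_neg"), driver = x)
}

#' Plot a fitted model
#'
#' Two panels: the truth-state densities with criterion markers, and the
#' likelihood-ratio curve with the reference line at 1.
#'
#' @param x a \code{"uvsdt"} model.
#' @param ... passed to \code{matplot}.
#' @export
plot.uvsdt <- function(x, ...) {
  g <- x$spec$grid
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  graphics::matplot(g, cbind(logistic_pdf(x$dist_pos, g),
                             logistic_pdf(x$dist_neg, g)),
                    type = "l", lty = 1, col = c("blue", "red"),
                    xlab = x$spec$driver_name, ylab = "density", ...)
  graphics::legend("topright", legend = c("T+", "T-"), lty = 1,
                   col = c("blue", "red"), bty = "n")
  lr <- predict(x, type = "lr")
  graphics::plot(g, lr, type = "l", log = "y",
                 xlab = x$spec$driver_name, ylab = "likelihood ratio")
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' @export
logLik.uvsdt <- function(object, ...) {
  ll <- sum(attr(object$dist_pos, "loglik"), attr(object$dist_neg, "loglik"))
  structure(ll, df = 4L, class = "logLik")
}
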