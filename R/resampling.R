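## Leave-one-out and random-partition resampling: per-dataset refits,
## IQR-fence outlier screening, percentile summaries, hypothesis tests.

#' Exhaustive leave-one-out datasets
#'
#' For a cohort of n participants, builds the n datasets of size n - 1
#' obtained by leaving out one participant at a time, ordered by the id of
#' the omitted participant. The percentile spread of estimates over these
#' datasets measures single-deletion sensitivity.
#'
#' @param x a [cohort()].
#' @return Named list of cohorts; names are the omitted ids.
#' @export
make_loo_datasets <- function(x) {
  stopifnot(inherits(x, "cohort"))
  n <- nrow(x)
  if (n < 6L) stop("leave-one-out needs at least 6 participants (fits need 5 per state)")
  ord <- order(x$id)
  xo <- subset_cohort(x, ord, attr(x, "provenance"))
  out <- lapply(seq_len(n), function(i)
    subset_cohort(xo, -i,
                  paste0(attr(x, "provenance"), " [-", xo$id[i], "]")))
  names(out) <- xo$id
  out
}

#' Complementary random partitions
#'
#' Each repetition splits the cohort at random into a first partition of
#' \code{partition_size} participants and the complementary remainder.
#' Reproducible under \code{seed}; repetition r uses the substream
#' \code{seed + r}.
#'
#' @param x a [cohort()].
#' @param partition_size size of the first partition (default 72).
#' @param n_reps number of repetitions (default 100).
#' @param seed master seed.
#' @return List with elements \code{partition1} and \code{partition2}, each
#'   a list of \code{n_reps} cohorts.
#' @export
make_random_partitions <- function(x, partition_size = 72, n_reps = 100,
                                   seed = 1) {
  stopifnot(inherits(x, "cohort"))
  n <- nrow(x)
  if (partition_size >= n) stop("partition_size must be smaller than the cohort")
  p1 <- vector("list", n_reps); p2 <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed((seed + r) %% .Machine$integer.max)
    take <- sample.int(n, partition_size)
    p1[[r]] <- subset_cohort(x, take, sprintf("partition1 rep %d", r))
    p2[[r]] <- subset_cohort(x, -take, sprintf("partition2 rep %d", r))
  }
  list(partition1 = p1, partition2 = p2)
}

#' Refit the model on every resampled dataset
#'
#' Fits [uvsdt()] on each dataset and records the ROC accuracy parameters
#' and the likelihood-ratio curve on a shared driver grid. Datasets that do
#' not meet the fit preconditions (fewer than 5 labelled records in a truth
#' state) are skipped with the reason logged.
#'
#' @param datasets list of cohorts (from [make_loo_datasets()] or one
#'   partition of [make_random_partitions()]).
#' @param pairing \code{"sedep"} or \code{"pcu"}.
#' @param grid shared driver grid; defaults to the pairing's default grid.
#' @param method fitting method, see [fit_logistic()].
#' @param threshold THI improvement threshold in points.
#' @return Object of class \code{"dataset_estimates"}: data frame
#'   \code{params} (per-dataset \code{roc_slope}, \code{roc_intercept},
#'   state parameters), matrix \code{lr} (datasets x grid points, flagged
#'   points NA), the \code{grid}, and \code{failures}.
#' @export
fit_all <- function(datasets, pairing = c("sedep", "pcu"), grid = NULL,
                    method = "mle", threshold = 7) {
  pairing <- match.arg(pairing)
  spec <- driver_spec(pairing)
  if (is.null(grid)) grid <- spec$grid
  nm <- names(datasets)
  if (is.null(nm)) nm <- as.character(seq_along(datasets))
  params <- list(); lrs <- list(); failures <- list()
  for (i in seq_along(datasets)) {
    fit <- tryCatch(uvsdt(datasets[[i]], pairing, method, threshold),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failures[[nm[i]]] <- conditionMessage(fit)
      next
    }
    cf <- coef(fit)
    params[[nm[i]]] <- data.frame(
      dataset = nm[i], roc_slope = cf[["roc_slope"]],
      roc_intercept = cf[["roc_intercept"]],
      mu_pos = cf[["mu_pos"]], s_pos = cf[["s_pos"]],
      mu_neg = cf[["mu_neg"]], s_neg = cf[["s_neg"]],
      prior_pos = cf[["prior_pos"]], stringsAsFactors = FALSE)
    lrs[[nm[i]]] <- likelihood_ratio(fit, grid)$lr
  }
  if (length(params) == 0L)
    stop("all datasets failed to fit: ",
         paste(unique(unlist(failures)), collapse = "; "))
  structure(list(params = do.call(rbind, c(params, make.row.names = FALSE)),
                 lr = do.call(rbind, lrs), grid = grid, pairing = pairing,
                 failures = failures),
            class = "dataset_estimates")
}

#' @export
print.dataset_estimates <- function(x, ...) {
  cat(sprintf("Estimates over %d resampled datasets (%s), %d failed fits\n",
              nrow(x$params), x$pairing, length(x$failures)))
  invisible(x)
}

#' Remove outliers by the 1.5 IQR fence rule
#'
#' Removes values more than 1.5 interquartile ranges above the upper
#' quartile or below the lower quartile. Quartiles use linear interpolation
#' between order statistics (\code{stats::quantile} type 7). Fewer than 4
#' values: no-op with a warning.
#'
#' @param values numeric vector (NAs are dropped first and not counted as
#'   outliers).
#' @return List with \code{retained} and \code{n_removed}.
#' @export
remove_outliers <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) {
    warning("fewer than 4 values: outlier screening skipped")
    return(list(retained = values, n_removed = 0L))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  keep <- values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr
  list(retained = values[keep], n_removed = sum(!keep))
}

pct_summary <- function(values) {
  or <- suppressWarnings(remove_outliers(values))
  v <- or$retained
  if (length(v) == 0L)
    return(c(median = NA_real_, p2.5 = NA_real_, p97.5 = NA_real_,
             n_datasets = 0, n_outliers = 0))
  q <- stats::quantile(v, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
  c(median = q[2], p2.5 = q[1], p97.5 = q[3],
    n_datasets = length(values[!is.na(values)]), n_outliers = or$n_removed)
}

#' Percentile summary of resampled estimates
#'
#' Applies the IQR-fence outlier screen to the per-dataset ROC parameters
#' and, pointwise, to the likelihood-ratio values across datasets, then
#' reports the median and 2.5/97.5 percentiles of the retained values with
#' dataset and outlier counts. Grid points where a majority of datasets were
#' flagged (density-ratio underflow) are masked.
#'
#' @param estimates a \code{"dataset_estimates"} object from [fit_all()].
#' @param screen_outliers apply the fence rule before the percentiles.
#' @return Object of class \code{"resampling_summary"}: data frame
#'   \code{params} (one row per parameter), data frame \code{lr_band}
#'   (per grid point), and counts.
#' @export
summarize_estimates <- function(estimates, screen_outliers = TRUE) {
  stopifnot(inherits(estimates, "dataset_estimates"))
  summ1 <- function(v) {
    if (screen_outliers) return(pct_summary(v))
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      return(c(median = NA_real_, p2.5 = NA_real_, p97.5 = NA_real_,
               n_datasets = 0, n_outliers = 0))
    q <- stats::quantile(v, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
    c(median = q[2], p2.5 = q[1], p97.5 = q[3],
      n_datasets = length(v), n_outliers = 0L)
  }
  pars <- c("roc_slope", "roc_intercept")
  params <- do.call(rbind, lapply(pars, function(p) {
    s <- summ1(estimates$params[[p]])
    data.frame(parameter = p, t(s), stringsAsFactors = FALSE)
  }))
  n_flag <- colSums(is.na(estimates$lr))
  masked <- n_flag > nrow(estimates$lr) / 2
  band <- t(apply(estimates$lr, 2, summ1))
  lr_band <- data.frame(grid = estimates$grid, band,
                        n_flagged = n_flag, masked = masked)
  lr_band[masked, c("median", "p2.5", "p97.5")] <- NA_real_
  structure(list(params = params, lr_band = lr_band,
                 n_datasets = nrow(estimates$params),
                 pairing = estimates$pairing),
            class = "resampling_summary")
}

#' @export
print.resampling_summary <- function(x, ...) {
  cat(sprintf("Resampling summary (%s, %d datasets)\n", x$pairing, x$n_datasets))
  print(x$params, row.names = FALSE)
  invisible(x)
}

#' Percentile-interval test of a ROC parameter against its null value
#'
#' The null values are 0 for the ROC intercept (chance-level accuracy) and 1
#' for the ROC slope (equal truth-state scales). The null is rejected at the
#' two-sided 5% level when it lies outside the 2.5--97.5 percentile
#' interval.
#'
#' @param summary a \code{"resampling_summary"}, or a list with elements
#'   \code{p2.5} and \code{p97.5} giving an interval directly.
#' @param parameter \code{"roc_intercept"} or \code{"roc_slope"}.
#' @return List of class \code{"hypothesis_result"}: \code{parameter},
#'   \code{null_value}, \code{interval}, \code{reject},
#'   \code{comparison_type}.
#' @export
test_vs_null <- function(summary, parameter = c("roc_intercept", "roc_slope")) {
  parameter <- match.arg(parameter)
  null_value <- if (parameter == "roc_intercept") 0 else 1
  iv <- extract_interval(summary, parameter)
  structure(list(parameter = parameter, null_value = null_value,
                 interval = iv,
                 reject = null_value < iv[1] || null_value > iv[2],
                 comparison_type = "vs_null"),
            class = "hypothesis_result")
}

extract_interval <- function(summary, parameter) {
  if (inherits(summary, "resampling_summary")) {
    row <- summary$params[summary$params$parameter == parameter, ]
    if (nrow(row) != 1L) stop("summary does not contain parameter ", parameter)
    return(c(row$p2.5, row$p97.5))
  }
  if (!is.null(summary$p2.5)) return(c(summary$p2.5, summary$p97.5))
  stop("cannot extract a percentile interval from the supplied summary")
}

#' Percentile-interval comparison of a ROC parameter between two groups
#'
#' Equality is rejected when the two 95% percentile intervals are disjoint —
#' a conservative rule expressible directly from the reported interval
#' limits.
#'
#' @param summary_a,summary_b summaries as accepted by [test_vs_null()].
#' @param parameter \code{"roc_intercept"} or \code{"roc_slope"}.
#' @return A \code{"hypothesis_result"} with both intervals.
#' @export
compare_groups <- function(summary_a, summary_b,
                           parameter = c("roc_intercept", "roc_slope")) {
  parameter <- match.arg(parameter)
  a <- extract_interval(summary_a, parameter)
  b <- extract_interval(summary_b, parameter)
  structure(list(parameter = parameter, null_value = NA_real_,
                 interval = a, interval_b = b,
                 reject = a[2] < b[1] || b[2] < a[1],
                 comparison_type = "between_groups"),
            class = "hypothesis_result")
}

#' @export
print.hypothesis_result <- function(x, ...) {
  if (x$comparison_type == "vs_null")
    cat(sprintf("%s vs %g: interval (%.3f, %.3f) -> %s\n", x$parameter,
                x$null_value, x$interval[1], x$interval[2],
                if (x$reject) "REJECT" else "not rejected"))
  else
    cat(sprintf("%s between groups: (%.3f, %.3f) vs (%.3f, %.3f) -> %s\n",
                x$parameter, x$interval[1], x$interval[2],
                x$interval_b[1], x$interval_b[2],
                if (x$reject) "REJECT (disjoint)" else "not rejected (overlap)"))
  invisible(x)
}

#' Empirical ROC band over resampled datasets
#'
#' For every criterion grid point, the per-dataset logits of the true- and
#' false-positive probabilities are summarised by their median and 2.5/97.5
#' percentiles; plotting median logit TP against median logit FP gives the
#' empirical ROC curve, and the percentiles its band. The criterion
#' parameterization is retained so the bands stay well defined.
#'
#' @param estimates a \code{"dataset_estimates"} from [fit_all()].
#' @return Data frame ordered by criterion with the median and percentile
#'   columns of both logits.
#' @export
empirical_roc_band <- function(estimates) {
  stopifnot(inherits(estimates, "dataset_estimates"))
  g <- estimates$grid
  p <- estimates$params
  logit_tp <- sapply(seq_len(nrow(p)), function(i)
    clamp_logit(1 - stats::plogis(g, p$mu_pos[i], p$s_pos[i])))
  logit_fp <- sapply(seq_len(nrow(p)), function(i)
    clamp_logit(1 - stats::plogis(g, p$mu_neg[i], p$s_neg[i])))
  qs <- function(m) t(apply(m, 1, stats::quantile,
                            probs = c(0.025, 0.5, 0.975), type = 7))
  tp <- qs(logit_tp); fp <- qs(logit_fp)
  data.frame(criterion = g,
             logit_fp_median = fp[, 2], logit_fp_lo = fp[, 1], logit_fp_hi = fp[, 3],
             logit_tp_median = tp[, 2], logit_tp_lo = tp[, 1], logit_tp_hi = tp[, 3])
}

#' Likelihood-ratio band over resampled datasets
#'
#' Pointwise median and 2.5/97.5 percentiles of the likelihood ratio after
#' per-point outlier screening; grid points flagged in a majority of
#' datasets are masked with their flag counts reported.
#'
#' @param estimates a \code{"dataset_estimates"} from [fit_all()].
#' @return The \code{lr_band} data frame of [summarize_estimates()].
#' @export
lr_band <- function(estimates) summarize_estimates(estimates)$lr_band

#' Conventional nonparametric bootstrap estimates
#'
#' Resamples the cohort with replacement and refits, as a sampling-variance
#' companion to the deletion-sensitivity leave-one-out band.
#'
#' @param x a [cohort()].
#' @param pairing \code{"sedep"} or \code{"pcu"}.
#' @param n_reps bootstrap repetitions.
#' @param seed master seed; repetition r uses \code{seed + r}.
#' @param ... passed to [fit_all()].
#' @return A \code{"dataset_estimates"} object.
#' @export
bootstrap_estimates <- function(x, pairing = "sedep", n_reps = 100, seed = 1,
                                ...) {
  stopifnot(inherits(x, "cohort"))
  df <- as.data.frame(x)
  boots <- lapply(seq_len(n_reps), function(r) {
    set.seed((seed + r) %% .Machine$integer.max)
    idx <- sample.int(nrow(df), replace = TRUE)
    d <- df[idx, , drop = FALSE]
    d$id <- sprintf("%s.%d", d$id, seq_len(nrow(d)))  # keep ids unique
    cohort(d, provenance = sprintf("bootstrap rep %d", r))
  })
  fit_all(boots, pairing, ...)
}
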