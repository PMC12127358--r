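## Reporting layer: end-to-end decision profiling of a cohort (tables in the
## median / lower / upper / counts layout, figure data with percentile
## bands), simulation runs written to disk, and a collated text report.

#' Write a simulated cohort and its ground truth to disk
#'
#' @param config a [synthetic_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, the paths written: \code{cohort.csv},
#'   \code{ground_truth.csv} and \code{manifest.txt} (seed and config echo).
#' @export
write_simulation <- function(config = synthetic_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config)
  paths <- c(cohort = file.path(outdir, "cohort.csv"),
             truth = file.path(outdir, "ground_truth.csv"),
             manifest = file.path(outdir, "manifest.txt"))
  write_cohort(sim$cohort, paths[["cohort"]])
  truth_rows <- do.call(rbind, lapply(names(sim$truth), function(lev) {
    do.call(rbind, lapply(c("sedep", "pcu"), function(p) {
      m <- sim$truth[[lev]][[p]]
      data.frame(group = lev, pairing = p,
                 mu_pos = m$dist_pos$mu, s_pos = m$dist_pos$s,
                 mu_neg = m$dist_neg$mu, s_neg = m$dist_neg$s,
                 prior_pos = m$prior_pos,
                 criterion = sim$truth[[lev]]$criterion[[p]],
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(truth_rows, paths[["truth"]], row.names = FALSE)
  writeLines(c(sprintf("seed: %d", config$seed),
               utils::capture.output(utils::str(unclass(config)))),
             paths[["manifest"]])
  invisible(paths)
}

profile_one <- function(co, pairing, resampling, partition_size, n_reps,
                        seed, threshold, group) {
  fit <- tryCatch(uvsdt(co, pairing, threshold = threshold),
                  error = function(e) e)
  if (inherits(fit, "error"))
    return(list(status = conditionMessage(fit), group = group))
  est <- if (resampling == "loo")
    fit_all(make_loo_datasets(co), pairing, threshold = threshold)
  else
    bootstrap_estimates(co, pairing, n_reps = n_reps, seed = seed,
                        threshold = threshold)
  summ <- summarize_estimates(est)
  list(status = "ok", group = group, fit = fit, estimates = est,
       summary = summ,
       test_intercept = test_vs_null(summ, "roc_intercept"),
       test_slope = test_vs_null(summ, "roc_slope"),
       roc_band = empirical_roc_band(est))
}

# strict / lenient / mixed reading of the median likelihood-ratio band
classify_group_curve <- function(lr_band_df, tol = 0.05) {
  m <- lr_band_df$median[!lr_band_df$masked & !is.na(lr_band_df$median)]
  if (length(m) == 0L) return("undetermined")
  frac_strict <- mean(m > 1 + tol)
  frac_lenient <- mean(m < 1 - tol)
  if (frac_strict >= 0.95) "strict"
  else if (frac_lenient >= 0.95) "lenient"
  else "mixed (crosses 1 on the axis)"
}

#' Profile the treatment decisions of a cohort
#'
#' Runs the full analysis for each requested driver/decision pairing: fits
#' the unequal-variance signal-detection model on the whole cohort and on
#' each level of the grouping variable, runs the resampling inference
#' (exhaustive leave-one-out per group, plus complementary random partitions
#' of the whole cohort when \code{partitions = TRUE}), screens outliers,
#' and assembles parameter tables (median, 2.5/97.5 percentile limits,
#' dataset and outlier counts, significance flags against the null values 0
#' for the intercept and 1 for the slope, and a between-subgroup disjointness
#' flag) along with ROC and likelihood-ratio band data and a strict/lenient
#' classification of each group's criterion.
#'
#' @param x a [cohort()].
#' @param pairings character vector, subset of \code{c("sedep", "pcu")}.
#' @param group_by \code{"none"} or a grouping variable for [stratify()].
#' @param resampling \code{"loo"} (exhaustive leave-one-out; percentile
#'   intervals measure single-deletion sensitivity) or \code{"bootstrap"}
#'   (with-replacement resampling; intervals measure sampling variance).
#' @param partitions also run the random-partition resampling on the whole
#'   cohort.
#' @param partition_size,n_reps,seed passed to [make_random_partitions()].
#' @param threshold THI improvement threshold in points.
#' @param outdir optional directory: tables, band sidecar CSVs and figures
#'   are written there.
#' @return Object of class \code{"uvsdt_profile"}: per pairing, the group
#'   results, the intercept and slope tables, and band data.
#' @export
profile_cohort <- function(x, pairings = c("sedep", "pcu"),
                           group_by = "none", resampling = c("loo", "bootstrap"),
                           partitions = FALSE,
                           partition_size = 72, n_reps = 100, seed = 1,
                           threshold = 7, outdir = NULL) {
  stopifnot(inherits(x, "cohort"))
  pairings <- match.arg(pairings, several.ok = TRUE)
  resampling <- match.arg(resampling)
  out <- list(group_by = group_by, seed = seed)
  for (pairing in pairings) {
    res <- list()
    res[["all"]] <- profile_one(x, pairing, resampling, partition_size,
                                n_reps, seed, threshold, "all")
    if (partitions) {
      parts <- make_random_partitions(x, partition_size, n_reps, seed)
      for (p in c("partition1", "partition2")) {
        est <- fit_all(parts[[p]], pairing, threshold = threshold)
        summ <- summarize_estimates(est)
        res[[p]] <- list(status = "ok", group = p, estimates = est,
                         summary = summ,
                         test_intercept = test_vs_null(summ, "roc_intercept"),
                         test_slope = test_vs_null(summ, "roc_slope"),
                         roc_band = empirical_roc_band(est))
      }
    }
    if (group_by != "none") {
      parts <- stratify(x, group_by)
      for (lev in setdiff(names(parts), "n_dropped"))
        if (!is.null(parts[[lev]]))
          res[[lev]] <- profile_one(parts[[lev]], pairing, resampling,
                                    partition_size, n_reps, seed, threshold,
                                    lev)
    }
    out[[pairing]] <- list(
      groups = res,
      intercept_table = param_table(res, "roc_intercept", group_by),
      slope_table = param_table(res, "roc_slope", group_by))
  }
  out <- structure(out, class = "uvsdt_profile", pairings = pairings)
  if (!is.null(outdir)) write_profile(out, outdir)
  out
}

param_table <- function(res, parameter, group_by) {
  rows <- lapply(res, function(r) {
    if (!identical(r$status, "ok"))
      return(data.frame(group = r$group, median = NA, lower = NA, upper = NA,
                        n_datasets = NA, n_outliers = NA, sig_vs_null = NA,
                        status = r$status, stringsAsFactors = FALSE))
    p <- r$summary$params
    row <- p[p$parameter == parameter, ]
    tst <- if (parameter == "roc_intercept") r$test_intercept else r$test_slope
    data.frame(group = r$group, median = row$median, lower = row$p2.5,
               upper = row$p97.5, n_datasets = row$n_datasets,
               n_outliers = row$n_outliers, sig_vs_null = tst$reject,
               status = "ok", stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  tab$sig_between <- NA
  levs <- setdiff(tab$group[tab$status == "ok"],
                  c("all", "partition1", "partition2"))
  if (length(levs) == 2) {
    a <- res[[levs[1]]]$summary; b <- res[[levs[2]]]$summary
    rej <- compare_groups(a, b, parameter)$reject
    tab$sig_between[tab$group %in% levs] <- rej
  }
  if (all(c("partition1", "partition2") %in% tab$group)) {
    rej <- compare_groups(res$partition1$summary, res$partition2$summary,
                          parameter)$reject
    tab$sig_between[tab$group %in% c("partition1", "partition2")] <- rej
  }
  tab
}

#' @export
print.uvsdt_profile <- function(x, ...) {
  for (pairing in attr(x, "pairings")) {
    cat(sprintf("== %s ==\n", toupper(pairing)))
    cat("-- roc_intercept (null 0) --\n")
    print(x[[pairing]]$intercept_table, row.names = FALSE)
    cat("-- roc_slope (null 1) --\n")
    print(x[[pairing]]$slope_table, row.names = FALSE)
  }
  invisible(x)
}

write_profile <- function(profile, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (pairing in attr(profile, "pairings")) {
    pr <- profile[[pairing]]
    utils::write.csv(pr$intercept_table,
                     file.path(outdir, sprintf("%s_intercept.csv", pairing)),
                     row.names = FALSE)
    utils::write.csv(pr$slope_table,
                     file.path(outdir, sprintf("%s_slope.csv", pairing)),
                     row.names = FALSE)
    for (g in names(pr$groups)) {
      r <- pr$groups[[g]]
      if (!identical(r$status, "ok")) next
      base <- file.path(outdir, sprintf("%s_%s", pairing, g))
      utils::write.csv(r$roc_band, paste0(base, "_roc_band.csv"),
                       row.names = FALSE)
      utils::write.csv(r$summary$lr_band, paste0(base, "_lr_band.csv"),
                       row.names = FALSE)
      grDevices::pdf(paste0(base, "_roc.pdf"), width = 5, height = 5)
      plot_roc_band(r$roc_band,
                    main = sprintf("%s, %s: empirical ROC", toupper(pairing), g))
      grDevices::dev.off()
      grDevices::pdf(paste0(base, "_lr.pdf"), width = 5, height = 5)
      plot_lr_band(r$summary$lr_band,
                   xlab = driver_spec(pairing)$driver_name,
                   main = sprintf("%s, %s: likelihood ratio", toupper(pairing), g))
      grDevices::dev.off()
    }
  }
  invisible(outdir)
}

plot_roc_band <- function(band, ...) {
  graphics::plot(band$logit_fp_median, band$logit_tp_median, type = "l",
                 xlab = "logit P(FP)", ylab = "logit P(TP)", ...)
  graphics::lines(band$logit_fp_median, band$logit_tp_lo, lty = 2)
  graphics::lines(band$logit_fp_median, band$logit_tp_hi, lty = 2)
  graphics::abline(0, 1, col = "grey")
}

plot_lr_band <- function(lr_band, xlab = "driver", ...) {
  ok <- !lr_band$masked & !is.na(lr_band$median)
  graphics::plot(lr_band$grid[ok], lr_band$median[ok], type = "l", log = "y",
                 xlab = xlab, ylab = "likelihood ratio", ...)
  graphics::lines(lr_band$grid[ok], pmax(lr_band$p2.5[ok], 1e-12), lty = 2)
  graphics::lines(lr_band$grid[ok], lr_band$p97.5[ok], lty = 2)
  graphics::abline(h = 1, lty = 3)
}

#' Collated text report of a profiling run
#'
#' One human-readable document: descriptives, parameter tables with
#' significance flags, strict/lenient criterion classification per group,
#' and diagnostics (failed fits, outlier counts, masked likelihood-ratio
#' grid ranges).
#'
#' @param profile a \code{"uvsdt_profile"} from [profile_cohort()].
#' @param x the profiled [cohort()] (for the descriptives section).
#' @param path optional file to write the report to.
#' @return Character vector of report lines, invisibly when \code{path} is
#'   given.
#' @export
decision_report <- function(profile, x = NULL, path = NULL) {
  stopifnot(inherits(profile, "uvsdt_profile"))
  lines <- c("Treatment-decision profile", strrep("=", 26), "")
  if (!is.null(x)) {
    d <- descriptives(x, if (profile$group_by == "none") "none" else profile$group_by)
    lines <- c(lines, "Descriptives:",
               utils::capture.output(print(d, row.names = FALSE)), "")
  }
  for (pairing in attr(profile, "pairings")) {
    pr <- profile[[pairing]]
    lines <- c(lines, sprintf("%s (driver: %s)", toupper(pairing),
                              driver_spec(pairing)$driver_name),
               strrep("-", 40),
               "roc_intercept (accuracy; null 0):",
               utils::capture.output(print(pr$intercept_table, row.names = FALSE)),
               "roc_slope (scale ratio; null 1):",
               utils::capture.output(print(pr$slope_table, row.names = FALSE)))
    for (g in names(pr$groups)) {
      r <- pr$groups[[g]]
      if (!identical(r$status, "ok")) {
        lines <- c(lines, sprintf("  %s: fit refused (%s)", g, r$status))
        next
      }
      cls <- classify_group_curve(r$summary$lr_band)
      ub <- tryCatch(suppressWarnings(unbiased_criterion(r$fit)),
                     error = function(e) NULL)
      lines <- c(lines, sprintf(
        "  %s: criterion profile %s%s", g, cls,
        if (is.null(ub)) "" else
          sprintf("; unbiased criterion at %s",
                  paste(sprintf("%.1f", ub), collapse = ", "))))
      masked <- r$summary$lr_band$masked
      if (any(masked))
        lines <- c(lines, sprintf(
          "    masked likelihood-ratio points: %d of %d (driver %.1f..%.1f)",
          sum(masked), length(masked),
          min(r$summary$lr_band$grid[masked]),
          max(r$summary$lr_band$grid[masked])))
      if (length(r$estimates$failures) > 0)
        lines <- c(lines, sprintf("    skipped datasets: %d",
                                  length(r$estimates$failures)))
    }
    lines <- c(lines, "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
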