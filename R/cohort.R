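## Participant-level cohort: validation, CSV I/O, truth-state labelling,
## driver/decision pairings, subgroup stratification, descriptives.

#' Column set of a cohort table
#'
#' @return Character vector of the mandatory column names.
#' @export
cohort_columns <- function() {
  c("id", "sex", "age_years", "laterality", "hearing_loss_db",
    "thi_baseline", "thi_post", "decision_sedep", "decision_pcu")
}

#' Construct a validated cohort
#'
#' A cohort is a data frame of participant records: grouping fields
#' (\code{sex}, \code{age_years}, \code{laterality}), the two decision
#' drivers (\code{hearing_loss_db}: dB HL at 8 kHz on the worse ear;
#' \code{thi_baseline}: Tinnitus Handicap Inventory, 0--100), the two binary
#' treatment decisions and the post-treatment THI score. Missing values are
#' \code{NA}. Validation enforces unique ids, score and driver ranges, adult
#' age, and the factor levels of the categorical fields.
#'
#' @param data data frame with the columns of [cohort_columns()].
#' @param provenance free-text label describing the origin of the data.
#' @return A \code{data.frame} of class \code{"cohort"}.
#' @export
cohort <- function(data, provenance = "unspecified") {
  miss <- setdiff(cohort_columns(), names(data))
  if (length(miss) > 0L)
    stop("cohort schema error: missing column(s) ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)[cohort_columns()]
  if (nrow(data) == 0L) stop("cohort must be non-empty")

  data$id <- as.character(data$id)
  data$sex <- as.character(data$sex)
  data$laterality <- as.character(data$laterality)
  data$decision_sedep <- as.character(data$decision_sedep)
  data$decision_pcu <- as.character(data$decision_pcu)
  for (col in c("age_years", "hearing_loss_db", "thi_baseline", "thi_post"))
    data[[col]] <- as.numeric(data[[col]])

  problems <- character(0)
  bad <- function(rows, what) {
    if (any(rows, na.rm = TRUE))
      problems <<- c(problems, sprintf("row %d: %s", which(rows), what))
  }
  dup <- duplicated(data$id)
  bad(dup, "duplicated id")
  bad(is.na(data$id) | data$id == "", "missing id")
  bad(!is.na(data$sex) & !data$sex %in% c("male", "female"),
      "sex must be 'male' or 'female'")
  bad(!is.na(data$laterality) & !data$laterality %in% c("unilateral", "bilateral"),
      "laterality must be 'unilateral' or 'bilateral'")
  bad(!is.na(data$age_years) & data$age_years < 18, "age_years below 18")
  bad(!is.na(data$hearing_loss_db) &
        (data$hearing_loss_db < 0 | data$hearing_loss_db > 130),
      "hearing_loss_db outside [0, 130]")
  bad(!is.na(data$thi_baseline) & (data$thi_baseline < 0 | data$thi_baseline > 100),
      "thi_baseline outside [0, 100]")
  bad(!is.na(data$thi_post) & (data$thi_post < 0 | data$thi_post > 100),
      "thi_post outside [0, 100]")
  for (col in c("decision_sedep", "decision_pcu"))
    bad(!is.na(data[[col]]) & !data[[col]] %in% c("positive", "negative"),
        paste(col, "must be 'positive' or 'negative'"))
  if (length(problems) > 0L)
    stop("cohort validation error:\n  ", paste(problems, collapse = "\n  "))

  rownames(data) <- NULL
  structure(data, provenance = provenance,
            class = c("cohort", "data.frame"))
}

#' Read a cohort from CSV
#'
#' One declared dialect: comma-separated, UTF-8, header row, \code{NA} for
#' missing values. Column names can be remapped through \code{schema} when the
#' file uses different headers.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector mapping canonical column
#'   names (names) to the file's column names (values).
#' @return A [cohort()].
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                         fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw))
        stop("cohort schema error: mapped column '", src, "' not in file")
      names(raw)[names(raw) == src] <- canon
    }
  }
  cohort(raw, provenance = path)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: the round trip reproduces every field.
#'
#' @param x a [cohort()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "NA",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d participants (%s)\n", nrow(x),
              attr(x, "provenance")))
  lab <- label_truth_state(x)
  cat(sprintf("  truth states: %d T+, %d T-, %d unlabelled\n",
              sum(lab == "T_pos"), sum(lab == "T_neg"),
              sum(lab == "undefined")))
  invisible(x)
}

#' Label treatment-success truth states
#'
#' The positive truth state is a clinically important improvement:
#' \code{delta = thi_baseline - thi_post} strictly greater than
#' \code{threshold} points (default 7, the THI minimal clinically important
#' difference). A delta of exactly \code{threshold} is a negative truth state.
#' Records without a post-treatment score are \code{"undefined"} and excluded
#' from fitting.
#'
#' @param x a [cohort()] or a data frame with \code{thi_baseline}/\code{thi_post}.
#' @param threshold improvement threshold in THI points.
#' @return Factor with levels \code{T_pos}, \code{T_neg}, \code{undefined};
#'   the improvement \code{delta_thi} is attached as an attribute.
#' @export
label_truth_state <- function(x, threshold = 7) {
  delta <- x$thi_baseline - x$thi_post
  lab <- ifelse(is.na(delta), "undefined",
                ifelse(delta > threshold, "T_pos", "T_neg"))
  structure(factor(lab, levels = c("T_pos", "T_neg", "undefined")),
            delta_thi = delta)
}

#' Driver/decision pairing specification
#'
#' The two pairings assessed are \code{"sedep"} (sound enrichment device
#' evaluation period, driven by hearing loss at 8 kHz on the worse ear) and
#' \code{"pcu"} (psychosocial counseling uptake, driven by the baseline THI
#' score).
#'
#' @param pairing \code{"sedep"} or \code{"pcu"}.
#' @param grid_n number of evenly spaced criterion grid points on the axis.
#' @return List with \code{decision_name}, \code{driver_name},
#'   \code{decision_col}, \code{axis} (min, max) and \code{grid}.
#' @export
driver_spec <- function(pairing = c("sedep", "pcu"), grid_n = 512) {
  pairing <- match.arg(pairing)
  if (pairing == "sedep") {
    axis <- c(0, 130); driver <- "hearing_loss_db"; dec <- "decision_sedep"
  } else {
    axis <- c(0, 100); driver <- "thi_baseline"; dec <- "decision_pcu"
  }
  list(decision_name = toupper(pairing), driver_name = driver,
       decision_col = dec, axis = axis,
       grid = seq(axis[1], axis[2], length.out = grid_n))
}

#' Split a cohort into the two levels of a grouping variable
#'
#' Grouping variables are \code{sex} (male/female), \code{age} (younger than
#' the cut vs at least the cut, default 55 years) and \code{laterality}
#' (unilateral/bilateral). Records with a missing grouping value are dropped
#' and counted.
#'
#' @param x a [cohort()].
#' @param grouping \code{"sex"}, \code{"age"} or \code{"laterality"}.
#' @param age_cut age boundary in years; the boundary age itself belongs to
#'   the older level.
#' @return Named list of two cohorts (levels) plus \code{n_dropped}.
#' @export
stratify <- function(x, grouping = c("sex", "age", "laterality"),
                     age_cut = 55) {
  stopifnot(inherits(x, "cohort"))
  grouping <- match.arg(grouping)
  lev <- switch(grouping,
    sex = list(male = x$sex == "male", female = x$sex == "female"),
    age = {
      l <- list(x$age_years < age_cut, x$age_years >= age_cut)
      names(l) <- c(sprintf("age<%d", age_cut), sprintf("age>=%d", age_cut))
      l
    },
    laterality = list(unilateral = x$laterality == "unilateral",
                      bilateral = x$laterality == "bilateral"))
  keep1 <- !is.na(lev[[1]]) & lev[[1]]
  keep2 <- !is.na(lev[[2]]) & lev[[2]]
  dropped <- sum(!(keep1 | keep2))
  out <- list()
  for (i in 1:2) {
    k <- if (i == 1) keep1 else keep2
    out[[names(lev)[i]]] <- if (any(k))
      cohort(as.data.frame(x)[k, , drop = FALSE],
             provenance = paste0(attr(x, "provenance"), " [", names(lev)[i], "]"))
    else NULL
  }
  out$n_dropped <- dropped
  out
}

#' Descriptive statistics table
#'
#' Summarises each level of a grouping variable (or the whole cohort):
#' participant count, median and IQR of the two drivers, and truth-state
#' counts among labelled records. Continuous drivers are summarised by median
#' and IQR as for non-normally distributed data.
#'
#' @param x a [cohort()].
#' @param grouping \code{"none"} for the whole cohort, else passed to
#'   [stratify()].
#' @param age_cut age boundary in years, see [stratify()].
#' @param threshold truth-state improvement threshold in THI points.
#' @return Data frame with one row per level.
#' @export
descriptives <- function(x, grouping = "none", age_cut = 55, threshold = 7) {
  stopifnot(inherits(x, "cohort"))
  one <- function(co, label) {
    lab <- label_truth_state(co, threshold)
    data.frame(
      group = label, n = nrow(co),
      hearing_median = stats::median(co$hearing_loss_db, na.rm = TRUE),
      hearing_iqr = stats::IQR(co$hearing_loss_db, na.rm = TRUE, type = 7),
      thi_median = stats::median(co$thi_baseline, na.rm = TRUE),
      thi_iqr = stats::IQR(co$thi_baseline, na.rm = TRUE, type = 7),
      n_T_pos = sum(lab == "T_pos"), n_T_neg = sum(lab == "T_neg"),
      n_unlabelled = sum(lab == "undefined"),
      stringsAsFactors = FALSE)
  }
  if (identical(grouping, "none")) return(one(x, "all"))
  parts <- stratify(x, grouping, age_cut)
  levs <- setdiff(names(parts), "n_dropped")
  do.call(rbind, lapply(levs, function(l) {
    if (is.null(parts[[l]])) return(NULL)
    one(parts[[l]], l)
  }))
}

# Row subset of an already-validated cohort: invariants are inherited, so
# skip re-validation (LOO/partition resampling builds thousands of these).
subset_cohort <- function(x, rows, provenance) {
  df <- as.data.frame(x)[rows, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, provenance = provenance, class = c("cohort", "data.frame"))
}

#' Driver values per truth state
#'
#' Internal helper: extracts non-missing driver values of labelled records
#' for one pairing, split by truth state.
#' @noRd
driver_by_state <- function(x, spec, threshold = 7) {
  lab <- label_truth_state(x, threshold)
  v <- x[[spec$driver_name]]
  keep <- !is.na(v) & lab != "undefined"
  list(pos = v[keep & lab == "T_pos"], neg = v[keep & lab == "T_neg"],
       n_unlabelled = sum(lab == "undefined" | is.na(v)))
}
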