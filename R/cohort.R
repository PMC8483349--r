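#' Define a prognostic factor scheme
#'
#' A factor scheme fixes the studied prognostic factors, the admissible level
#' codes of each (in severity order), and optional numeric recodes (e.g. an
#' age cutoff mapping years of age to two level codes).
#'
#' @param ... Named character vectors: one per factor, in the order that
#'   combination keys are assembled (e.g. `T = c("T1a", "T1b"), N = c("N0",
#'   "N1")`).
#' @param recodes Optional named list of recode rules for numeric input
#'   columns.  Each rule is a list with `breaks` (cut points, right-open
#'   intervals `[b_i, b_{i+1})` spanning `-Inf`/`Inf` implicitly) and
#'   `labels` (level codes, one more than `breaks`).  Example: age cutoff 70
#'   as `list(A = list(breaks = 70, labels = c("A0", "A1")))` maps age 69 to
#'   `"A0"` and 70+ to `"A1"`.
#' @param sep Separator used when assembling combination keys (default `""`,
#'   giving keys in the `T1aN0M0A0S1` style).
#' @return An object of class `factor_scheme`.
#' @export
factor_scheme <- function(..., recodes = list(), sep = "") {
  levels <- list(...)
  if (length(levels) == 0L) stop("factor_scheme: at least one factor required")
  nm <- names(levels)
  if (is.null(nm) || any(nm == "")) stop("factor_scheme: factors must be named")
  if (anyDuplicated(nm)) stop("factor_scheme: duplicate factor names")
  for (f in nm) {
    levels[[f]] <- as.character(levels[[f]])
    if (anyDuplicated(levels[[f]]))
      stop("factor_scheme: duplicate level codes in factor ", f)
  }
  for (f in names(recodes)) {
    r <- recodes[[f]]
    if (!f %in% nm) stop("factor_scheme: recode for unknown factor ", f)
    if (length(r$labels) != length(r$breaks) + 1L)
      stop("factor_scheme: recode for ", f, " needs one more label than breaks")
    if (is.unsorted(r$breaks, strictly = TRUE))
      stop("factor_scheme: recode breaks for ", f, " must be strictly increasing")
    if (!all(r$labels %in% levels[[f]]))
      stop("factor_scheme: recode labels for ", f, " not admissible levels")
  }
  structure(list(levels = levels, recodes = recodes, sep = sep),
            class = "factor_scheme")
}

#' @export
print.factor_scheme <- function(x, ...) {
  cat("Factor scheme with", length(x$levels), "factors:\n")
  for (f in names(x$levels))
    cat("  ", f, ": ", paste(x$levels[[f]], collapse = ", "),
        if (f %in% names(x$recodes)) "  [numeric recode]", "\n", sep = "")
  invisible(x)
}

scheme_factors <- function(scheme) names(scheme$levels)

# Apply a numeric recode (right-open intervals) to a column.  Values that are
# already admissible level codes pass through unchanged, so coded and raw
# numeric columns can both be read under the same scheme.
apply_recode <- function(x, rule, admissible) {
  x <- trimws(x)
  v <- suppressWarnings(as.numeric(x))
  idx <- findInterval(v, rule$breaks, left.open = FALSE) + 1L
  out <- rule$labels[idx]
  out[is.na(v)] <- NA_character_
  coded <- !is.na(x) & x %in% admissible
  out[coded] <- x[coded]
  out
}

#' Read a case-level survival table
#'
#' Reads a delimited text file (comma- or tab-separated, autodetected from the
#' `.csv`/`.tsv` extension), maps columns to survival time, event indicator,
#' prognostic factors and an optional diagnosis year, applies any numeric
#' recodes in the scheme, validates levels against the scheme, and drops
#' cases with a missing or inadmissible factor level (complete-case rule; the
#' number dropped is recorded).
#'
#' @param path Path to the delimited file (header required).
#' @param scheme A [factor_scheme()].
#' @param column_map Named character vector/list mapping roles to column
#'   names: `time`, `event`, optionally `year`, and one entry per scheme
#'   factor (defaults to the factor's own name).
#' @return A tibble with columns `time`, `event`, one column per factor,
#'   `combination`, and `year` if mapped; attributes `scheme`, `n_dropped`,
#'   and `factors` (factors currently defining `combination`).
#' @export
read_cohort <- function(path, scheme, column_map = NULL) {
  stopifnot(inherits(scheme, "factor_scheme"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  cm <- as.list(column_map %||% list())
  cm$time <- cm$time %||% "time"
  cm$event <- cm$event %||% "event"
  for (f in scheme_factors(scheme)) cm[[f]] <- cm[[f]] %||% f
  needed <- unlist(cm[c("time", "event", scheme_factors(scheme))])
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("read_cohort: mapped column(s) not in file: ",
         paste(missing_cols, collapse = ", "))

  time <- suppressWarnings(as.numeric(raw[[cm$time]]))
  if (anyNA(time) || any(time < 0))
    stop("read_cohort: unparseable or negative time at row(s) ",
         paste(utils::head(which(is.na(time) | time < 0), 5), collapse = ", "))
  event <- suppressWarnings(as.integer(raw[[cm$event]]))
  if (anyNA(event) || !all(event %in% c(0L, 1L)))
    stop("read_cohort: unparseable event indicator at row(s) ",
         paste(utils::head(which(is.na(event) | !event %in% c(0L, 1L)), 5),
               collapse = ", "))

  out <- tibble::tibble(time = time, event = event)
  for (f in scheme_factors(scheme)) {
    col <- raw[[cm[[f]]]]
    lv <- if (f %in% names(scheme$recodes)) {
      apply_recode(col, scheme$recodes[[f]], scheme$levels[[f]])
    } else {
      trimws(col)
    }
    lv[!is.na(lv) & !(lv %in% scheme$levels[[f]])] <- NA_character_
    lv[!is.na(lv) & lv == ""] <- NA_character_
    out[[f]] <- lv
  }
  if (!is.null(cm$year) && cm$year %in% names(raw))
    out$year <- suppressWarnings(as.integer(raw[[cm$year]]))

  complete <- stats::complete.cases(out[scheme_factors(scheme)])
  n_dropped <- sum(!complete)
  out <- out[complete, , drop = FALSE]
  out <- add_combination(out, scheme)
  attr(out, "n_dropped") <- n_dropped
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

copy_cohort_attrs <- function(to, from) {
  attr(to, "scheme") <- attr(from, "scheme")
  attr(to, "factors") <- attr(from, "factors")
  to
}

#' Assemble combination keys over a factor subset
#'
#' A combination is the subset of cases sharing one level of each studied
#' factor; its key concatenates the level codes in scheme order (e.g.
#' `T1aN0M0A0S1`).  Recomputing keys over a factor subset pools the
#' combinations of the dropped factors.
#'
#' @param data A case tibble with one column per scheme factor.
#' @param scheme A [factor_scheme()].
#' @param factors Character vector of factors to use, in any order (the
#'   scheme order is applied); default all scheme factors.
#' @return `data` with a recomputed `combination` column; attributes `scheme`
#'   and `factors` updated.
#' @export
add_combination <- function(data, scheme, factors = scheme_factors(scheme)) {
  stopifnot(inherits(scheme, "factor_scheme"))
  if (length(factors) == 0L) stop("add_combination: empty factor subset")
  if (!all(factors %in% scheme_factors(scheme)))
    stop("add_combination: unknown factor(s): ",
         paste(setdiff(factors, scheme_factors(scheme)), collapse = ", "))
  factors <- scheme_factors(scheme)[scheme_factors(scheme) %in% factors]
  data$combination <- do.call(paste, c(unname(as.list(data[factors])),
                                       sep = scheme$sep))
  attr(data, "scheme") <- scheme
  attr(data, "factors") <- factors
  data
}

#' Combination counts
#'
#' @param data A case tibble with a `combination` column.
#' @return A tibble `combination`, `n`, sorted by key.
#' @export
count_combinations <- function(data) {
  dplyr::arrange(dplyr::count(data, .data$combination), .data$combination)
}

#' Remove rare combinations
#'
#' Drops every combination with fewer than `min_count` cases, together with
#' its cases.  The removed keys and counts are recorded in the `removed`
#' attribute.
#'
#' @param data A case tibble with a `combination` column.
#' @param min_count Minimum cases per combination (default 25).
#' @return The filtered tibble; attribute `removed` is a tibble of dropped
#'   `combination`/`n`.
#' @export
filter_rare <- function(data, min_count = 25) {
  stopifnot(min_count >= 1)
  counts <- count_combinations(data)
  removed <- counts[counts$n < min_count, , drop = FALSE]
  if (nrow(removed) == nrow(counts))
    stop("filter_rare: all combinations fall below min_count = ", min_count)
  out <- data[!(data$combination %in% removed$combination), , drop = FALSE]
  attr(out, "scheme") <- attr(data, "scheme")
  attr(out, "factors") <- attr(data, "factors")
  attr(out, "removed") <- removed
  out
}

#' Temporal split into training and validation sets
#'
#' Cases diagnosed before `cutoff_year` form the training set; cases
#' diagnosed in `cutoff_year` form the validation set.  The training set is
#' then filtered for rare combinations, and validation cases whose
#' combination does not survive the filter are excluded (they could not be
#' classified by a system built on the training set).
#'
#' @param data A case tibble with `combination` and `year` columns.
#' @param cutoff_year The validation diagnosis year.
#' @param min_count Rare-combination threshold applied to the training side
#'   (default 25).
#' @return A list with `train`, `validation`, and `excluded` (tibble of
#'   excluded validation cases); `train + validation + excluded` partition
#'   the cases at years `<= cutoff_year` exactly.
#' @export
temporal_split <- function(data, cutoff_year, min_count = 25) {
  if (!"year" %in% names(data))
    stop("temporal_split: no year column")
  train <- copy_cohort_attrs(
    data[!is.na(data$year) & data$year < cutoff_year, , drop = FALSE], data)
  valid <- copy_cohort_attrs(
    data[!is.na(data$year) & data$year == cutoff_year, , drop = FALSE], data)
  if (nrow(valid) == 0L)
    warning("temporal_split: empty validation set (no cases in ",
            cutoff_year, ")")
  train <- filter_rare(train, min_count)
  keep <- valid$combination %in% unique(train$combination)
  list(train = train,
       validation = valid[keep, , drop = FALSE],
       excluded = valid[!keep, , drop = FALSE])
}

#' Write a cohort summary
#'
#' @param data A case tibble with a `combination` column.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(data, path) {
  utils::write.csv(count_combinations(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
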