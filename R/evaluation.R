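#' Adjacent-group Cox and logrank comparisons
#'
#' For every adjacent pair of prognostic groups (`g+1` vs `g`), fits a
#' univariate two-group Cox proportional-hazards model (Breslow tie handling
#' by default; month-scale registry data carry heavy ties) and computes the
#' two-sample logrank test.  A pair without events is flagged inestimable.
#'
#' @param data Case tibble with `time` and `event`.
#' @param group Ordinal group number per case (1 = lowest risk).
#' @param conf_level Confidence level for the hazard-ratio interval
#'   (default 0.95).
#' @param ties Cox tie handling, `"breslow"` (default) or `"efron"`.
#' @return A tibble with one row per adjacent pair: `groups_compared`
#'   (e.g. `"2 vs 1"`), `hr`, `hr_lo`, `hr_hi`, `hr_p` (Wald), `logrank_p`,
#'   `estimable`.
#' @export
adjacent_cox <- function(data, group, conf_level = 0.95,
                         ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(nrow(data) == length(group))
  gs <- sort(unique(group))
  if (length(gs) < 2L) stop("adjacent_cox: need at least 2 groups")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(seq_len(length(gs) - 1L), function(i) {
    g0 <- gs[i]; g1 <- gs[i + 1L]
    sel <- group %in% c(g0, g1)
    tt <- data$time[sel]; ee <- data$event[sel]
    hi <- as.integer(group[sel] == g1)
    out <- tibble::tibble(groups_compared = paste(g1, "vs", g0),
                          hr = NA_real_, hr_lo = NA_real_, hr_hi = NA_real_,
                          hr_p = NA_real_, logrank_p = NA_real_,
                          estimable = FALSE)
    if (sum(ee) == 0L) return(out)
    fit <- tryCatch(
      survival::coxph(survival::Surv(tt, ee) ~ hi, ties = ties),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit) && is.finite(fit$coefficients[1]) &&
        is.finite(sqrt(fit$var[1, 1]))) {
      b <- unname(fit$coefficients[1]); se <- sqrt(fit$var[1, 1])
      out$hr <- exp(b)
      out$hr_lo <- exp(b - z * se)
      out$hr_hi <- exp(b + z * se)
      out$hr_p <- 2 * stats::pnorm(-abs(b / se))
      out$estimable <- TRUE
    }
    lr <- tryCatch(survival::survdiff(survival::Surv(tt, ee) ~ hi),
                   error = function(e) NULL)
    if (!is.null(lr))
      out$logrank_p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
    out
  })
  dplyr::bind_rows(rows)
}

#' Compare two correlated C-indices
#'
#' Tests the difference between the Harrell C-indices of two risk scores
#' evaluated on the same cases.  Because the scores share the case-pair
#' structure, the two C estimates are correlated; both use the same set of
#' permissible pairs, so the difference is itself a (ratio of) U-statistics.
#' The variance of the difference is estimated from the Hajek projection of
#' that U-statistic (per-subject influence terms), with an exact delete-one
#' jackknife available as a cross-check; a normal approximation gives the
#' confidence interval and two-sided p-value.
#'
#' @param time,event Observed times and event indicators.
#' @param score_a,score_b The two risk scores (higher = worse prognosis).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `c_a`, `c_b`, `difference` (`c_a - c_b`), `se`,
#'   `conf_lo`, `conf_hi`, `p_value`, `se_jackknife`, `n_pairs`.
#' @export
compare_c <- function(time, event, score_a, score_b, conf_level = 0.95) {
  n <- length(time)
  stopifnot(length(event) == n, length(score_a) == n, length(score_b) == n)
  event <- as.integer(event)

  # ordered-pair structure: row i is the earlier, event-bearing case
  perm <- outer(time, time, "<") & (event == 1L)
  if (!any(perm)) {
    warning("compare_c: no permissible pairs")
    return(tibble::tibble(c_a = NA_real_, c_b = NA_real_,
                          difference = NA_real_, se = NA_real_,
                          conf_lo = NA_real_, conf_hi = NA_real_,
                          p_value = NA_real_, se_jackknife = NA_real_,
                          n_pairs = 0))
  }
  w_of <- function(s) {
    gt <- outer(s, s, ">")
    eq <- outer(s, s, "==")
    gt + 0.5 * eq
  }
  h <- perm * (w_of(score_a) - w_of(score_b))
  mm <- perm * 1

  u_i <- rowSums(h) + colSums(h)
  m_i <- rowSums(mm) + colSums(mm)
  U <- sum(h); M <- sum(mm)
  D <- U / M

  # Hajek-projection variance of the ratio-of-U-statistics difference
  phi <- (u_i - D * m_i) / M
  var_inf <- sum(phi^2) * (n - 1) / n

  # exact delete-one jackknife
  ok <- (M - m_i) > 0
  d_loo <- ifelse(ok, (U - u_i) / (M - m_i), D)
  var_jack <- (n - 1) / n * sum((d_loo - mean(d_loo))^2)

  se <- sqrt(var_inf)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- if (se == 0) as.numeric(abs(D) < 1e-15) else 2 * stats::pnorm(-abs(D / se))
  tibble::tibble(
    c_a = harrell_c(time, event, score_a),
    c_b = harrell_c(time, event, score_b),
    difference = D,
    se = se,
    conf_lo = D - z * se,
    conf_hi = D + z * se,
    p_value = p,
    se_jackknife = sqrt(var_jack),
    n_pairs = M
  )
}

#' Contingency table between two grouping systems
#'
#' @param groups_a,groups_b Group assignments over the same cases.
#' @return A counts matrix (rows = `groups_a`, columns = `groups_b`) with
#'   `Total` margins.
#' @export
cross_tabulate <- function(groups_a, groups_b) {
  stopifnot(length(groups_a) == length(groups_b))
  stats::addmargins(table(groups_a, groups_b, dnn = c("a", "b")),
                    FUN = list(Total = sum), quiet = TRUE)
}

#' Spearman rank correlation with mid-ranks
#'
#' Pearson correlation of mid-ranks (average ranks within ties), the
#' tie-corrected Spearman coefficient, for two ordinal group assignments over
#' the same cases.
#'
#' @param groups_a,groups_b Ordinal assignments.
#' @return The correlation; `NA` with a warning if either assignment is
#'   constant.
#' @export
spearman_midrank <- function(groups_a, groups_b) {
  stopifnot(length(groups_a) == length(groups_b))
  ra <- rank(groups_a, ties.method = "average")
  rb <- rank(groups_b, ties.method = "average")
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    warning("spearman_midrank: constant assignment; correlation undefined")
    return(NA_real_)
  }
  stats::cor(ra, rb)
}

#' Distribution of factor levels over risk categories
#'
#' Collapses prognostic groups into named risk categories (e.g. low = groups
#' 1-3, medium = 4-7, high = 8-10) and tabulates, for each level of each
#' factor, the proportions of its cases falling into each category.
#'
#' @param data Case tibble with a `group` column (see [apply_system()]) and
#'   the factor columns.
#' @param categories Named list of group-number vectors; must partition the
#'   group numbers present in `data` (no overlap, full cover).
#' @param factors Character vector of factor columns to profile.
#' @return A tibble `factor`, `level`, `category`, `n`, `proportion`;
#'   proportions sum to 1 within each (factor, level).
#' @export
risk_category_distribution <- function(data, categories, factors) {
  stopifnot("group" %in% names(data), all(factors %in% names(data)))
  all_gs <- sort(unique(data$group[!is.na(data$group)]))
  mapped <- unlist(categories, use.names = FALSE)
  if (anyDuplicated(mapped) || !setequal(intersect(mapped, all_gs), all_gs) ||
      !all(all_gs %in% mapped))
    stop("risk_category_distribution: categories must partition the observed groups")
  cat_of <- stats::setNames(rep(names(categories), lengths(categories)),
                            as.character(mapped))
  data <- data[!is.na(data$group), , drop = FALSE]
  data$.category <- factor(cat_of[as.character(data$group)],
                           levels = names(categories))
  purrr::map_dfr(factors, function(f) {
    tab <- dplyr::count(data, level = .data[[f]], category = .data$.category,
                        .drop = FALSE)
    tab <- dplyr::mutate(dplyr::group_by(tab, .data$level),
                         proportion = .data$n / sum(.data$n))
    dplyr::ungroup(dplyr::mutate(tab, factor = f, .before = 1))
  })
}
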