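#' Harrell's concordance index
#'
#' Concordance between a risk score and right-censored survival: over
#' permissible pairs (pairs with distinct observed times whose earlier time
#' is an event), the fraction in which the shorter-lived case carries the
#' higher risk score, with score ties counted one half.  Pairs with equal
#' observed times are not permissible.
#'
#' @param time Observed times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param score Risk scores, higher = worse prognosis; ties allowed.
#' @return The C-index in `[0, 1]`; `NA` (with a warning) when there is no
#'   permissible pair.
#' @examples
#' harrell_c(c(3, 2, 1), c(1, 1, 1), c(1, 2, 3))  # 1
#' @export
harrell_c <- function(time, event, score) {
  n <- length(time)
  stopifnot(length(event) == n, length(score) == n, n >= 1)
  counts <- concordance_counts(time, as.integer(event), score)
  if (counts$n_pairs == 0) {
    warning("harrell_c: no permissible pairs; C-index undefined")
    return(NA_real_)
  }
  (counts$concordant + 0.5 * counts$tied) / counts$n_pairs
}

# Single descending sweep over times.  Maintains, per score rank, the count
# of cases with strictly larger observed time; events in each tied-time block
# are compared against that tally before the block is added.
concordance_counts <- function(time, event, score) {
  rank_score <- match(score, sort(unique(score)))
  k <- max(rank_score)
  ord <- order(time, decreasing = TRUE)
  time <- time[ord]; event <- event[ord]; rank_score <- rank_score[ord]
  later <- numeric(k)       # counts per score rank among strictly later times
  cum_later <- 0
  concordant <- tied <- n_pairs <- 0
  i <- 1L; n <- length(time)
  while (i <= n) {
    j <- i
    while (j < n && time[j + 1L] == time[i]) j <- j + 1L
    block <- i:j
    ev <- block[event[block] == 1L]
    if (length(ev) && cum_later > 0) {
      cs <- cumsum(later)
      for (b in ev) {
        r <- rank_score[b]
        lower <- if (r > 1L) cs[r - 1L] else 0    # later cases w/ lower score
        eq <- later[r]
        n_pairs <- n_pairs + cum_later
        concordant <- concordant + lower
        tied <- tied + eq
      }
    }
    tab <- tabulate(rank_score[block], nbins = k)
    later <- later + tab
    cum_later <- cum_later + length(block)
    i <- j + 1L
  }
  list(concordant = concordant, tied = tied, n_pairs = n_pairs)
}

#' Order clusters into risk-ranked prognostic groups
#'
#' Ranks clusters by their pooled Kaplan-Meier survival at the ordering
#' horizon (default 60 months, i.e. the 5-year rate), best survival first, so
#' group 1 has the lowest risk and risk increases with the group number.
#' Ties are broken by mean observed time, longer first.
#'
#' @param data Case tibble with `time` and `event`.
#' @param cluster Cluster label per case (any coding).
#' @param horizon Ordering horizon in months (default 60).
#' @return A tibble with one row per cluster: `cluster`, `group` (1 = lowest
#'   risk), `surv_horizon`, `mean_time`, `n`.
#' @export
order_groups <- function(data, cluster, horizon = 60) {
  stopifnot(nrow(data) == length(cluster))
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(time = data$time, event = data$event,
                                   cluster = cluster), .data$cluster),
    surv_horizon = km_at(.data$time, .data$event, horizon),
    mean_time = mean(.data$time),
    n = dplyr::n(),
    .groups = "drop"
  )
  ord <- order(-stats_tbl$surv_horizon, -stats_tbl$mean_time)
  stats_tbl$group <- integer(nrow(stats_tbl))
  stats_tbl$group[ord] <- seq_len(nrow(stats_tbl))
  dplyr::arrange(stats_tbl[, c("cluster", "group", "surv_horizon",
                               "mean_time", "n")], .data$group)
}

# Pooled KM survival at time t (step value; last value carried beyond the
# largest observed time).
km_at <- function(time, event, t) {
  cv <- km_curve(time, event)
  km_step_value(cv, min(t, cv$max_time))
}

#' C-index curve over dendrogram cuts
#'
#' For each number of groups `k`, cuts the dendrogram into `k` clusters,
#' orders them into risk-ranked groups, and computes Harrell's C-index with
#' the ordinal group number as the risk score.  `k = 1` is 0.5 by convention
#' (a single group predicts nothing).
#'
#' @param dendrogram A `minimax_dendrogram` over combination keys.
#' @param data Case tibble with `time`, `event`, `combination`; every
#'   combination must be a dendrogram leaf.
#' @param k_cap Largest `k` (default `min(M, 30)`).
#' @param horizon Risk-ordering horizon in months (default 60).
#' @return A tibble with columns `k`, `c_index`.
#' @export
c_index_curve <- function(dendrogram, data, k_cap = NULL, horizon = 60) {
  m <- length(dendrogram$labels)
  k_cap <- min(k_cap %||% min(m, 30L), m)
  if (!all(data$combination %in% dendrogram$labels))
    stop("c_index_curve: cases with combinations not in the dendrogram")
  cs <- vapply(seq_len(k_cap), function(k) {
    if (k == 1L) return(0.5)
    groups <- case_groups(dendrogram, data, k, horizon)
    harrell_c(data$time, data$event, groups)
  }, numeric(1))
  tibble::tibble(k = seq_len(k_cap), c_index = cs)
}

# group number per case for a k-cut
case_groups <- function(dendrogram, data, k, horizon = 60) {
  labels <- cut_dendrogram(dendrogram, k)
  cl <- labels[data$combination]
  ord <- order_groups(data, cl, horizon)
  ord$group[match(cl, ord$cluster)]
}

#' Knee point of a C-index curve
#'
#' The point of diminishing returns: the interior `k` maximizing the
#' perpendicular (signed, above-chord) distance from `(k, C(k))` to the chord
#' joining the first and last points of the curve.  Ties go to the smallest
#' `k`.  A flat curve has no knee; 1 is returned with a warning.
#'
#' @param curve A tibble with columns `k` and `c_index` (length >= 3).
#' @return The selected number of groups `n*`.
#' @export
knee_point <- function(curve) {
  stopifnot(all(c("k", "c_index") %in% names(curve)), nrow(curve) >= 3)
  k <- curve$k; cx <- curve$c_index
  n <- length(k)
  if (max(cx) - min(cx) < 1e-12) {
    warning("knee_point: flat curve; returning 1")
    return(1L)
  }
  dx <- k[n] - k[1]; dy <- cx[n] - cx[1]
  len <- sqrt(dx^2 + dy^2)
  dist <- (dy * k - dx * cx + k[n] * cx[1] - cx[n] * k[1]) / len
  dist <- -dist  # positive above the chord
  interior <- 2:(n - 1)
  best <- interior[which.max(dist[interior])]
  if (sum(abs(dist[interior] - dist[best]) <= 1e-12) > 1L)
    warning("knee_point: tie among interior points; smallest k returned")
  as.integer(k[best])
}

#' Fit an ordered prognostic grouping system
#'
#' The full pipeline on a (filtered) training cohort: per-combination
#' Kaplan-Meier curves completed with exponential tails at the common
#' completion time, initial Mann-Whitney dissimilarities, PAM-ensemble
#' learned dissimilarities, minimax-linkage clustering, a C-index curve over
#' dendrogram cuts, knee-point (or user-supplied) choice of the number of
#' groups, and risk-ordering of the final groups.
#'
#' @param data Case tibble with `time`, `event`, and factor columns (or a
#'   ready-made `combination` column when `scheme` is `NULL`).
#' @param scheme Optional [factor_scheme()]; with `factors`, recomputes the
#'   `combination` column before fitting.
#' @param factors Factor subset used for combinations (default: all scheme
#'   factors).
#' @param min_count Rare-combination threshold (default 25 cases).
#' @param k_cap Largest k for the C-index curve (default `min(M, 30)`).
#' @param n_star Optional override of the knee-point group count.
#' @param horizon Risk-ordering horizon in months (default 60).
#' @param tau Optional completion time override (default: common largest
#'   observed time over combinations).
#' @param k_min,k_max PAM-ensemble sweep range (defaults 2 and `M - 1`).
#' @return An object of class `eaccd_fit`; see [tidy.eaccd_fit()],
#'   [glance.eaccd_fit()], [predict.eaccd_fit()], [autoplot.eaccd_fit()].
#' @export
eaccd_fit <- function(data, scheme = NULL, factors = NULL, min_count = 25,
                      k_cap = NULL, n_star = NULL, horizon = 60, tau = NULL,
                      k_min = 2, k_max = NULL) {
  if (!is.null(scheme)) {
    data <- add_combination(data, scheme,
                            factors %||% scheme_factors(scheme))
  } else if (!"combination" %in% names(data)) {
    stop("eaccd_fit: supply a scheme or a combination column")
  }
  data <- filter_rare(data, min_count)
  removed <- attr(data, "removed")

  d_init <- initial_matrix(data, tau = tau)
  tau_used <- attr(d_init, "tau")
  m <- nrow(d_init)
  if (m == 2L) {
    # degenerate: no ensemble possible; the two combinations are the groups
    dend <- minimax_linkage(d_init)
    d_learned <- d_init
  } else {
    d_learned <- learned_matrix(d_init, k_min = k_min,
                                k_max = k_max %||% (m - 1L))
    dend <- minimax_linkage(d_learned)
  }
  curve <- c_index_curve(dend, data, k_cap = k_cap, horizon = horizon)
  n_star_auto <- if (nrow(curve) >= 3) knee_point(curve) else nrow(curve)
  n_star_used <- as.integer(n_star %||% n_star_auto)
  if (n_star_used < 1 || n_star_used > m) stop("eaccd_fit: n_star out of range")

  cl <- cut_dendrogram(dend, n_star_used)
  case_cl <- cl[data$combination]
  grp_tbl <- order_groups(data, case_cl, horizon)
  assignment <- tibble::tibble(
    combination = names(cl),
    group = grp_tbl$group[match(unname(cl), grp_tbl$cluster)]
  )
  assignment <- dplyr::arrange(assignment, .data$group, .data$combination)
  case_group <- assignment$group[match(data$combination,
                                       assignment$combination)]
  c_train <- harrell_c(data$time, data$event, case_group)

  group_summary <- dplyr::rename(grp_tbl[order(grp_tbl$group),
                                         c("group", "surv_horizon",
                                           "mean_time", "n")],
                                 surv_5yr = "surv_horizon")

  structure(
    list(
      factors = attr(data, "factors") %||% "combination",
      tau = tau_used,
      min_count = min_count,
      horizon = horizon,
      n_combinations = m,
      n_cases = nrow(data),
      removed = removed,
      d_init = d_init,
      d_learned = d_learned,
      dendrogram = dend,
      c_curve = curve,
      n_star_auto = as.integer(n_star_auto),
      n_star = n_star_used,
      assignment = assignment,
      group_summary = group_summary,
      c_index = c_train,
      data = data
    ),
    class = "eaccd_fit"
  )
}

#' @export
print.eaccd_fit <- function(x, ...) {
  cat("Prognostic grouping system (EACCD)\n")
  cat("  factors:       ", paste(x$factors, collapse = ", "), "\n")
  cat("  combinations:  ", x$n_combinations, " (", x$n_cases, " cases)\n",
      sep = "")
  cat("  completion tau:", format(x$tau), "months\n")
  cat("  groups (n*):   ", x$n_star,
      if (x$n_star != x$n_star_auto) paste0(" (override; knee = ",
                                            x$n_star_auto, ")"), "\n",
      sep = "")
  cat("  training C-index:", format(round(x$c_index, 4)), "\n")
  invisible(x)
}

#' Tidy the assignment rule of a fitted system
#'
#' @param x An `eaccd_fit`.
#' @param ... Unused.
#' @return A tibble `combination`, `group`, ordered by group.
#' @method tidy eaccd_fit
#' @export
tidy.eaccd_fit <- function(x, ...) x$assignment

#' One-row summary of a fitted system
#'
#' @param x An `eaccd_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_combinations`, `n_cases`, `tau`, `n_star`,
#'   `c_index`.
#' @method glance eaccd_fit
#' @export
glance.eaccd_fit <- function(x, ...) {
  tibble::tibble(
    n_combinations = x$n_combinations, n_cases = x$n_cases, tau = x$tau,
    n_star = x$n_star, c_index = x$c_index
  )
}

#' Apply a fitted system's assignment rule to new cases
#'
#' Attaches the group number of each case's combination.  Cases whose
#' combination is unknown to the system get `NA` and are counted in the
#' `excluded` attribute (e.g. later-diagnosed patients in combinations absent
#' from the training data).
#'
#' @param object An `eaccd_fit`.
#' @param newdata Case tibble with a `combination` column (or factor columns
#'   matching the fit's scheme when `scheme` is given).
#' @param scheme Optional [factor_scheme()] to recompute combinations.
#' @param ... Unused.
#' @return `newdata` with a `group` column; attribute `excluded` holds the
#'   number of unassignable cases.
#' @export
predict.eaccd_fit <- function(object, newdata, scheme = NULL, ...) {
  if (!is.null(scheme))
    newdata <- add_combination(newdata, scheme, object$factors)
  if (!"combination" %in% names(newdata))
    stop("predict.eaccd_fit: newdata lacks a combination column")
  grp <- object$assignment$group[match(newdata$combination,
                                       object$assignment$combination)]
  if (all(is.na(grp)))
    stop("predict.eaccd_fit: no case matches any training combination")
  newdata$group <- grp
  attr(newdata, "excluded") <- sum(is.na(grp))
  newdata
}

#' @rdname predict.eaccd_fit
#' @param fit An `eaccd_fit`.
#' @param data Case tibble to classify.
#' @export
apply_system <- function(fit, data, scheme = NULL) {
  predict(fit, data, scheme = scheme)
}
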