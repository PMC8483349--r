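#' Kaplan-Meier curves of the prognostic groups
#'
#' One survival step curve per group, on either the training cases stored in
#' the fit or supplied new cases with a `group` column.
#'
#' @param object An `eaccd_fit`.
#' @param data Optional case tibble with `time`, `event`, `group` (default:
#'   the training cases and their fitted groups).
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot eaccd_fit
#' @export
autoplot.eaccd_fit <- function(object, data = NULL, ...) {
  if (is.null(data)) {
    if (is.null(object$data))
      stop("autoplot.eaccd_fit: no stored cases; supply data")
    data <- predict(object, object$data)
  }
  df <- group_km_table(data)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = factor(.data$group))) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability",
                  colour = "Group",
                  title = "Survival by prognostic group") +
    ggplot2::theme_minimal()
}

# long table of KM curves by group
group_km_table <- function(data) {
  stopifnot(all(c("time", "event", "group") %in% names(data)))
  data <- data[!is.na(data$group), , drop = FALSE]
  purrr::map_dfr(sort(unique(data$group)), function(g) {
    sel <- data$group == g
    cv <- km_curve(data$time[sel], data$event[sel])
    df <- tidy(cv)[, c("time", "surv")]
    df$group <- g
    df
  })
}

#' Plot a C-index curve with its knee point
#'
#' @param curve A tibble with `k`, `c_index` (see [c_index_curve()]).
#' @param n_star Optional selected group count to mark.
#' @return A ggplot object.
#' @export
plot_c_index_curve <- function(curve, n_star = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$c_index)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Number of groups", y = "C-index",
                  title = "C-index over dendrogram cuts") +
    ggplot2::theme_minimal()
  if (!is.null(n_star))
    p <- p + ggplot2::geom_vline(xintercept = n_star, linetype = "dashed")
  p
}

#' Plot a minimax dendrogram
#'
#' Base-graphics rendering via [stats::as.hclust()]; leaves can be annotated
#' with the 5-year survival of their combinations.
#'
#' @param x A `minimax_dendrogram`.
#' @param data Optional case tibble (`time`, `event`, `combination`) used to
#'   annotate leaves with 5-year survival percentages.
#' @param horizon Annotation horizon in months (default 60).
#' @param ... Passed to [plot.hclust()].
#' @export
plot.minimax_dendrogram <- function(x, data = NULL, horizon = 60, ...) {
  hc <- stats::as.hclust(x)
  if (!is.null(data)) {
    rates <- vapply(hc$labels, function(key) {
      sel <- data$combination == key
      100 * km_at(data$time[sel], data$event[sel], horizon)
    }, numeric(1))
    hc$labels <- sprintf("%s (%.0f%%)", hc$labels, rates)
  }
  graphics::plot(hc, xlab = "Combination", sub = "",
                 ylab = "Minimax radius", ...)
  invisible(x)
}

#' Plot risk-category distributions by factor level
#'
#' @param dist A tibble from [risk_category_distribution()].
#' @return A ggplot object, one panel per factor.
#' @export
plot_risk_categories <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$category,
                                     y = .data$proportion,
                                     group = .data$level,
                                     colour = .data$level)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~factor) +
    ggplot2::labs(x = "Risk category", y = "Proportion of cases",
                  colour = "Level") +
    ggplot2::theme_minimal()
}
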