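#' Kaplan-Meier step survival curve
#'
#' Product-limit estimate of the survival function for one group of
#' right-censored observations.  The returned curve is right-continuous,
#' `S(t) = P(T > t)`: evaluation at an event time gives the post-jump value.
#'
#' @param time Numeric vector of non-negative follow-up times (months).
#' @param event Integer/logical vector, 1 = cause-specific death, 0 = censored.
#' @return An object of class `km_curve`: a list with `time` (distinct event
#'   times, ascending), `surv` (survival after each event time), `n_risk`,
#'   `n_event`, and `max_time` (largest observed time, event or censoring).
#' @examples
#' km_curve(c(5, 10, 15), c(1, 1, 0))
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0L) stop("km_curve: empty input")
  if (length(time) != length(event)) stop("km_curve: length mismatch")
  if (anyNA(time) || anyNA(event)) stop("km_curve: missing values")
  if (any(time < 0)) stop("km_curve: negative time")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("km_curve: event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none", se.fit = FALSE)
  keep <- fit$n.event > 0
  structure(
    list(
      time     = fit$time[keep],
      surv     = fit$surv[keep],
      n_risk   = fit$n.risk[keep],
      n_event  = fit$n.event[keep],
      max_time = max(time),
      n        = length(time)
    ),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: ", x$n, " cases, ", length(x$time),
      " event times, largest observed time ", format(x$max_time), "\n",
      sep = "")
  invisible(x)
}

# Step-function value of a km_curve at times t (right-continuous).
km_step_value <- function(curve, t) {
  if (length(curve$time) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, curve$time)
  c(1, curve$surv)[idx + 1L]
}

#' Complete a Kaplan-Meier curve with an exponential tail
#'
#' Replaces the curve beyond the completion time `tau` with the exponential
#' tail `exp(-lambda * t)`, where `lambda = -log(S(tau)) / tau`, so the
#' completed curve is continuous at `tau`.  `S(tau) = 1` yields a flat tail
#' (`lambda = 0`); `S(tau) = 0` yields a tail that is identically zero
#' (`lambda` recorded as `Inf`).
#'
#' @param curve A `km_curve`.
#' @param tau Completion time in months, `0 < tau <=` largest observed time.
#' @return An object of class `completed_curve`: the step part truncated to
#'   `[0, tau]` plus fields `tau`, `lambda`, `s_tau`.
#' @export
complete_tail <- function(curve, tau) {
  stopifnot(inherits(curve, "km_curve"))
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("complete_tail: tau must be a positive number")
  if (tau > curve$max_time)
    stop("complete_tail: tau exceeds the largest observed time (",
         format(curve$max_time), "); the Kaplan-Meier estimate is undefined there")
  keep <- curve$time <= tau
  s_tau <- km_step_value(curve, tau)
  lambda <- if (s_tau >= 1) 0 else if (s_tau <= 0) Inf else -log(s_tau) / tau
  structure(
    list(
      time    = curve$time[keep],
      surv    = curve$surv[keep],
      n_risk  = curve$n_risk[keep],
      n_event = curve$n_event[keep],
      tau     = tau,
      lambda  = lambda,
      s_tau   = s_tau,
      smooth  = FALSE
    ),
    class = "completed_curve"
  )
}

#' Exact exponential survival curve
#'
#' A `completed_curve` whose pre-`tau` part is the exact exponential
#' `exp(-rate * t)` rather than a step function.  Useful for analytic checks:
#' integrals against it are computed in closed form, so the Mann-Whitney
#' effect size of two such curves equals `rate2 / (rate1 + rate2)` to machine
#' precision for any `tau`.
#'
#' @param rate Hazard rate per month, `>= 0`.
#' @param tau Completion time in months, `> 0`.
#' @return A `completed_curve` with `smooth = TRUE`.
#' @export
exponential_curve <- function(rate, tau = 1) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0,
            is.numeric(tau), length(tau) == 1L, tau > 0)
  structure(
    list(
      time = numeric(0), surv = numeric(0),
      n_risk = numeric(0), n_event = numeric(0),
      tau = tau, lambda = rate, s_tau = exp(-rate * tau),
      smooth = TRUE
    ),
    class = "completed_curve"
  )
}

#' @export
print.completed_curve <- function(x, ...) {
  cat("Tail-completed survival curve: tau = ", format(x$tau),
      ", lambda = ", format(x$lambda), " per month, S(tau) = ",
      format(x$s_tau), if (x$smooth) " (exact exponential)", "\n", sep = "")
  invisible(x)
}

#' Evaluate a completed survival curve
#'
#' Right-continuous evaluation: the step (or exact exponential) value for
#' `t <= tau`, and `exp(-lambda * t)` beyond `tau`.  A zero tail
#' (`S(tau) = 0`) evaluates to 0 beyond `tau`.
#'
#' @param curve A `completed_curve`.
#' @param t Numeric vector of times, `>= 0`.
#' @return Numeric vector of survival probabilities.
#' @export
curve_survival <- function(curve, t) {
  stopifnot(inherits(curve, "completed_curve"), all(t >= 0))
  out <- numeric(length(t))
  pre <- t <= curve$tau
  if (any(pre)) {
    out[pre] <- if (curve$smooth) exp(-curve$lambda * t[pre])
                else km_step_value(curve, t[pre])
  }
  if (any(!pre)) {
    out[!pre] <- if (is.finite(curve$lambda)) exp(-curve$lambda * t[!pre]) else 0
  }
  out
}

#' Common completion time for a set of curves
#'
#' The maximum time by which the Kaplan-Meier estimates of all groups can be
#' calculated: the minimum over curves of each curve's largest observed time.
#'
#' @param curves A list of `km_curve` objects.
#' @return A single completion time `tau`.
#' @export
global_tau <- function(curves) {
  stopifnot(length(curves) >= 1L)
  min(vapply(curves, function(cv) cv$max_time, numeric(1)))
}

#' Tidy a survival curve into a step table
#'
#' @param x A `km_curve` or `completed_curve`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `surv`, `n_risk`, `n_event`,
#'   starting at the implicit `(0, 1)` point.
#' @method tidy km_curve
#' @export
tidy.km_curve <- function(x, ...) {
  tibble::tibble(
    time = c(0, x$time), surv = c(1, x$surv),
    n_risk = c(NA_real_, x$n_risk), n_event = c(0, x$n_event)
  )
}

#' @rdname tidy.km_curve
#' @method tidy completed_curve
#' @export
tidy.completed_curve <- function(x, ...) tidy.km_curve(x, ...)

# Jump table of the step part of a completed curve on [0, tau]:
# time, mass = S(u-) - S(u) > 0, s_left, s_right.  Empty for smooth curves.
curve_jumps <- function(curve) {
  if (curve$smooth || length(curve$time) == 0L) {
    return(list(time = numeric(0), mass = numeric(0),
                s_left = numeric(0), s_right = numeric(0)))
  }
  s_left <- c(1, curve$surv[-length(curve$surv)])
  list(time = curve$time, mass = s_left - curve$surv,
       s_left = s_left, s_right = curve$surv)
}

# Constant pieces of the step part of a completed curve over [a, b] subset of
# [0, tau]: returns matrix-like list with lo, hi, value.
curve_pieces <- function(curve, a, b) {
  if (b <= a) return(list(lo = numeric(0), hi = numeric(0), value = numeric(0)))
  knots <- c(curve$time[curve$time > a & curve$time < b])
  lo <- c(a, knots)
  hi <- c(knots, b)
  # value on (lo, hi]: right-continuous step value at hi (or any interior pt)
  value <- km_step_value(curve, lo)  # value just after lo == value on (lo, hi]
  list(lo = lo, hi = hi, value = value)
}
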