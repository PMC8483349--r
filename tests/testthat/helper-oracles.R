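# Independent oracles used across the suite.  Each recomputes a quantity by a
# different route than the package (grid integration, exhaustive enumeration,
# naive pair scans, direct Newton iteration).

# hand product-limit estimate at the distinct event times
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# random completed step curve from simulated censored data
random_completed_curve <- function(n = 40, rate = 0.05, cens = 0.3,
                                   tau_frac = runif(1, 0.5, 1)) {
  t_ev <- rexp(n, rate)
  t_cn <- ifelse(runif(n) < cens, rexp(n, rate / 2), Inf)
  time <- pmin(t_ev, t_cn)
  event <- as.integer(t_ev <= t_cn)
  cv <- km_curve(time, event)
  complete_tail(cv, tau_frac * cv$max_time)
}

# grid-based Lebesgue-Stieltjes oracle for the three effect-size terms.
# Assumes the two step curves have no coinciding jump times (true a.s. for
# the random fixtures), so midpoint evaluation is exact for the jump sums.
grid_mw_terms <- function(c1, c2, h = 1e-4) {
  t1 <- c1$tau; t2 <- c2$tau
  tmin <- min(t1, t2); tmax <- max(t1, t2)
  stieltjes <- function(f_mid, Scurve, lo, hi) {
    if (hi <= lo) return(0)
    gr <- seq(lo, hi, by = h)
    if (gr[length(gr)] < hi) gr <- c(gr, hi)
    Sv <- curve_survival(Scurve, gr)
    mid <- (gr[-1] + gr[-length(gr)]) / 2
    sum(f_mid(mid) * (Sv[-length(Sv)] - Sv[-1]))
  }
  A <- stieltjes(function(u) curve_survival(c1, u), c2, 0, tmin)
  B <- if (t1 == t2) {
    0
  } else if (t1 < t2) {
    stieltjes(function(u) exp(-c1$lambda * u), c2, t1, t2)
  } else {
    gr <- seq(t2, t1, length.out = max(2, ceiling((t1 - t2) / h)))
    mid <- (gr[-1] + gr[-length(gr)]) / 2
    dt <- diff(gr)
    sum(curve_survival(c1, mid) * c2$lambda * exp(-c2$lambda * mid) * dt)
  }
  C <- {
    l1 <- c1$lambda; l2 <- c2$lambda
    if (!is.finite(l1) || !is.finite(l2)) 0
    else if (l1 == 0 && l2 == 0) 0.5
    else {
      hi <- tmax + 40 / max(l1 + l2, 1e-3)
      gr <- seq(tmax, hi, length.out = 400000L)
      mid <- (gr[-1] + gr[-length(gr)]) / 2
      sum(exp(-l1 * mid) * l2 * exp(-l2 * mid) * diff(gr))
    }
  }
  list(a = A, b = B, c = C)
}

# no single (medoid out, item in) swap lowers the PAM objective
is_swap_local_opt <- function(d, res) {
  for (mi in res$medoids) {
    for (h in setdiff(seq_len(nrow(d)), res$medoids)) {
      cand <- c(setdiff(res$medoids, mi), h)
      if (sum(apply(d[, cand, drop = FALSE], 1, min)) <
          res$objective - 1e-12) return(FALSE)
    }
  }
  TRUE
}

# exhaustive PAM optimum: best objective over all k-subsets of medoids
pam_exhaustive <- function(d, k) {
  best <- Inf
  for (med in utils::combn(nrow(d), k, simplify = FALSE)) {
    obj <- sum(apply(d[, med, drop = FALSE], 1, min))
    if (obj < best) best <- obj
  }
  best
}

# independent minimax-linkage: explicit loops over cluster pairs and
# candidate prototypes, same deterministic tie-breaks as documented
minimax_brute <- function(d) {
  m <- nrow(d)
  clusters <- lapply(seq_len(m), identity)
  ids <- -seq_len(m)
  merges <- matrix(0L, m - 1L, 2L)
  heights <- numeric(m - 1L)
  protos <- integer(m - 1L)
  for (s in seq_len(m - 1L)) {
    best_r <- Inf; best_pair <- NULL; best_p <- NA; best_key <- c(Inf, Inf)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        u <- sort(c(clusters[[i]], clusters[[j]]))
        r_best <- Inf; p_best <- NA
        for (p in u) {
          r <- max(d[p, u])
          if (r < r_best - 1e-15) { r_best <- r; p_best <- p }
        }
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        better <- r_best < best_r - 1e-15 ||
          (abs(r_best - best_r) <= 1e-15 &&
           (key[1] < best_key[1] ||
            (key[1] == best_key[1] && key[2] < best_key[2])))
        if (better) {
          best_r <- r_best; best_pair <- c(i, j); best_p <- p_best
          best_key <- key
        }
      }
    }
    merges[s, ] <- c(ids[best_pair[1]], ids[best_pair[2]])
    heights[s] <- best_r
    protos[s] <- best_p
    clusters[[best_pair[1]]] <- c(clusters[[best_pair[1]]],
                                  clusters[[best_pair[2]]])
    ids[best_pair[1]] <- s
    clusters[[best_pair[2]]] <- NULL
    ids <- ids[-best_pair[2]]
  }
  list(merge = merges, height = heights, prototype = protos)
}

# naive O(n^2) Harrell concordance
harrell_naive <- function(time, event, score) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (time[i] == time[j]) next
      early <- if (time[i] < time[j]) i else j
      late <- if (early == i) j else i
      if (event[early] != 1) next
      den <- den + 1
      if (score[early] > score[late]) num <- num + 1
      else if (score[early] == score[late]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# one-covariate Cox fit, Breslow ties, by direct Newton iteration
cox_newton_oracle <- function(time, event, x, tol = 1e-10) {
  beta <- 0
  for (iter in 1:50) {
    eta <- exp(beta * x)
    ts <- sort(unique(time[event == 1]))
    grad <- 0; hess <- 0
    for (t in ts) {
      rs <- time >= t
      s0 <- sum(eta[rs]); s1 <- sum(x[rs] * eta[rs])
      s2 <- sum(x[rs]^2 * eta[rs])
      d <- sum(time == t & event == 1)
      xb <- sum(x[time == t & event == 1])
      grad <- grad + xb - d * s1 / s0
      hess <- hess - d * (s2 / s0 - (s1 / s0)^2)
    }
    step <- grad / hess
    beta <- beta - step
    if (abs(grad) < tol) break
  }
  # observed information at the solution
  eta <- exp(beta * x)
  info <- 0
  for (t in sort(unique(time[event == 1]))) {
    rs <- time >= t
    s0 <- sum(eta[rs]); s1 <- sum(x[rs] * eta[rs]); s2 <- sum(x[rs]^2 * eta[rs])
    d <- sum(time == t & event == 1)
    info <- info + d * (s2 / s0 - (s1 / s0)^2)
  }
  se <- 1 / sqrt(info)
  list(beta = beta, hr = exp(beta), se = se,
       p = 2 * pnorm(-abs(beta / se)))
}

# random symmetric dissimilarity matrix
random_dissimilarity <- function(m, max_val = 1) {
  x <- matrix(runif(m * m, 0, max_val), m, m)
  d <- (x + t(x)) / 2
  diag(d) <- 0
  dimnames(d) <- list(paste0("c", seq_len(m)), paste0("c", seq_len(m)))
  d
}

# small two-group planted cohort for evaluation tests
two_group_cohort <- function(n_per = 150, rates = c(0.01, 0.02), seed = 42,
                             horizon = 120) {
  set.seed(seed)
  combos <- tibble::tibble(
    combination = c("g1", "g2"), group = 1:2, rate = rates,
    n = n_per
  )
  simulate_cohort(combos, horizon = horizon, censor_frac = 0.2, seed = seed)
}
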