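test_that("exact exponential pairs give the closed-form effect size", {
  for (tau in c(0.5, 1, 10, 80)) {
    e <- mw_effect(exponential_curve(1, tau), exponential_curve(3, tau))
    expect_equal(e$estimate, 0.75, tolerance = 1e-12)
  }
  e2 <- mw_effect(exponential_curve(0.5, 20), exponential_curve(0.5, 20))
  expect_equal(e2$estimate, 0.5, tolerance = 1e-12)
  # and with unequal completion times the B bridge restores the closed form
  e3 <- mw_effect(exponential_curve(1, 5), exponential_curve(3, 15))
  expect_equal(e3$estimate, 0.75, tolerance = 1e-12)
  e4 <- mw_effect(exponential_curve(2, 15), exponential_curve(1, 5))
  expect_equal(e4$estimate, 1 / 3, tolerance = 1e-12)
})

test_that("identical curves give 0.5 under the tie-corrected convention", {
  cv <- km_curve(c(2, 5, 5, 9, 14), c(1, 1, 1, 0, 1))
  cc <- complete_tail(cv, 12)
  expect_equal(mw_effect(cc, cc)$estimate, 0.5, tolerance = 1e-14)
  expect_equal(initial_dissimilarity(cc, cc), 0, tolerance = 1e-14)
})

test_that("step-curve terms match grid Stieltjes integration", {
  set.seed(101)
  for (rep in 1:8) {
    c1 <- random_completed_curve(n = 25)
    c2 <- random_completed_curve(n = 30)
    got <- mw_effect(c1, c2)
    want <- grid_mw_terms(c1, c2, h = 1e-4)
    expect_lt(abs(got$a_term - want$a), 1e-6)
    expect_lt(abs(got$b_term - want$b), 1e-6)
    expect_lt(abs(got$c_term - want$c), 1e-6)
  }
})

test_that("complementarity: D(c1,c2) + D(c2,c1) = 1", {
  set.seed(7)
  for (rep in 1:20) {
    c1 <- random_completed_curve(n = 20)
    c2 <- random_completed_curve(n = 35)
    s <- mw_effect(c1, c2)$estimate + mw_effect(c2, c1)$estimate
    expect_equal(s, 1, tolerance = 1e-12)
  }
})

test_that("estimates stay in [0,1] and dissimilarities in [0,0.5]", {
  set.seed(15)
  for (rep in 1:20) {
    c1 <- random_completed_curve(n = 15, rate = runif(1, 0.01, 0.3))
    c2 <- random_completed_curve(n = 15, rate = runif(1, 0.01, 0.3))
    e <- mw_effect(c1, c2)$estimate
    expect_gte(e, 0); expect_lte(e, 1)
    d <- initial_dissimilarity(c1, c2)
    expect_gte(d, 0); expect_lte(d, 0.5)
  }
  # widely separated exponentials approach the 0.5 bound
  expect_gt(initial_dissimilarity(exponential_curve(0.001, 10),
                                  exponential_curve(10, 10)), 0.49)
})

test_that("degenerate tails follow the stated conventions", {
  # both event-free: flat curves, C = 1/2
  flat <- complete_tail(km_curve(c(10, 20), c(0, 0)), 15)
  e <- mw_effect(flat, flat)
  expect_equal(e$c_term, 0.5)
  expect_equal(e$estimate, 0.5)
  # zero tail: its exponential part carries no mass
  dead <- complete_tail(km_curve(c(2, 4), c(1, 1)), 4)
  e2 <- mw_effect(flat, dead)
  expect_equal(e2$c_term, 0)
  expect_equal(e2$estimate, 1)       # flat population always outlives
  e3 <- mw_effect(dead, flat)
  expect_equal(e3$estimate, 0, tolerance = 1e-14)
})

test_that("effect size converges to the exponential closed form", {
  set.seed(33)
  rates <- c(0.01, 0.03)
  for (n in c(200, 2000)) {
    t1 <- rexp(n, rates[1]); t2 <- rexp(n, rates[2])
    cv1 <- km_curve(pmin(t1, 400), as.integer(t1 <= 400))
    cv2 <- km_curve(pmin(t2, 400), as.integer(t2 <= 400))
    tau <- min(cv1$max_time, cv2$max_time)
    e <- mw_effect(complete_tail(cv1, tau), complete_tail(cv2, tau))$estimate
    tol <- 3 / sqrt(n)
    expect_equal(e, rates[2] / sum(rates), tolerance = tol)
  }
})

test_that("initial matrix is symmetric with zero diagonal and shared tau", {
  fx <- two_group_cohort(n_per = 80, seed = 5)
  d <- initial_matrix(fx)
  expect_equal(diag(d), c(g1 = 0, g2 = 0))
  expect_equal(d, t(d))
  curves <- combination_curves(fx)
  expect_equal(attr(d, "tau"), global_tau(curves))
  cc <- lapply(curves, complete_tail, tau = attr(d, "tau"))
  expect_equal(d["g1", "g2"], initial_dissimilarity(cc$g1, cc$g2))
  # identical combinations give a zero matrix
  df <- tibble::tibble(time = rep(c(3, 6, 9), 3), event = rep(c(1, 1, 0), 3),
                       combination = rep(c("x", "y", "z"), each = 3))
  expect_equal(max(initial_matrix(df)), 0)
  expect_error(initial_matrix(df[df$combination == "x", ]), "at least two")
})

test_that("initial dissimilarities track the closed form on simulated
           exponential combinations", {
  set.seed(77)
  rates <- c(0.002, 0.006, 0.02, 0.06, 0.2)
  df <- purrr::map_dfr(seq_along(rates), function(i) {
    t <- rexp(500, rates[i])
    tibble::tibble(time = t, event = 1L,
                   combination = paste0("r", i))
  })
  d <- initial_matrix(df)
  for (i in 1:4) {
    for (j in seq.int(i + 1, 5)) {
      truth <- abs(rates[j] / (rates[i] + rates[j]) - 0.5)
      expect_lt(abs(d[paste0("r", i), paste0("r", j)] - truth), 0.03)
    }
  }
})
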