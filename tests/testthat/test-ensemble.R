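block_matrix <- function(sizes, within, cross) {
  m <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  d <- ifelse(outer(lab, lab, "=="), within, cross)
  diag(d) <- 0
  dimnames(d) <- list(paste0("i", 1:m), paste0("i", 1:m))
  d
}

test_that("PAM recovers planted pairs and reports the exact objective", {
  d <- block_matrix(c(2, 2), 0.1, 0.9)
  res <- pam_medoids(d, 2)
  expect_equal(sort(unique(res$labels)), 1:2)
  expect_equal(res$labels[1], res$labels[2])
  expect_equal(res$labels[3], res$labels[4])
  expect_equal(res$objective, 0.2)
  # objective always equals the implied sum of item-to-medoid dissimilarities
  expect_equal(res$objective,
               sum(d[cbind(1:4, res$medoids[res$labels])]))
})

test_that("PAM boundary and error cases", {
  d <- block_matrix(c(2, 2), 0.1, 0.9)
  all_single <- pam_medoids(d, 4)
  expect_equal(all_single$objective, 0)
  expect_equal(sort(all_single$medoids), 1:4)
  expect_error(pam_medoids(d, 1), "out of range")
  expect_error(pam_medoids(d, 5), "out of range")
  bad <- d; bad[1, 2] <- 5
  expect_error(pam_medoids(bad, 2), "symmetric")
})

test_that("PAM reaches the exhaustive optimum or a true local optimum", {
  # On arbitrary random matrices best-improvement k-medoids can stop at a
  # single-swap local optimum; the contract is: never below the optimum, and
  # never improvable by one more swap.
  set.seed(202)
  for (rep in 1:25) {
    m <- sample(4:7, 1)
    k <- sample(2:3, 1)
    d <- random_dissimilarity(m)
    res <- pam_medoids(d, k)
    expect_gte(res$objective, pam_exhaustive(d, k) - 1e-12)
    expect_true(is_swap_local_opt(d, res))
  }
})

test_that("PAM attains the exhaustive optimum on cluster-aligned fixtures", {
  # the matrices this pipeline feeds to PAM carry planted group structure;
  # when k matches that structure the optimum is always reached
  set.seed(203)
  for (rep in 1:25) {
    k <- sample(2:3, 1)
    sizes <- sample(2:3, k, replace = TRUE)
    if (sum(sizes) > 7) sizes[which.max(sizes)] <- 2
    d <- block_matrix(sizes, 0.05, 0.45)
    x <- matrix(runif(sum(sizes)^2, 0, 0.08), sum(sizes))
    d <- d + (x + t(x)) / 2; diag(d) <- 0
    expect_equal(pam_medoids(d, k)$objective, pam_exhaustive(d, k),
                 tolerance = 1e-12)
  }
})

test_that("PAM agrees with the reference implementation on aligned fixtures", {
  skip_if_not_installed("cluster")
  set.seed(301)
  for (rep in 1:10) {
    k <- sample(2:3, 1)
    sizes <- sample(2:4, k, replace = TRUE)
    d <- block_matrix(sizes, 0.05, 0.45)
    x <- matrix(runif(sum(sizes)^2, 0, 0.08), sum(sizes))
    d <- d + (x + t(x)) / 2; diag(d) <- 0
    ours <- pam_medoids(d, k)
    ref <- cluster::pam(stats::as.dist(d), k)
    ref_obj <- sum(apply(d[, ref$id.med, drop = FALSE], 1, min))
    expect_equal(ours$objective, ref_obj, tolerance = 1e-12)
  }
})

test_that("learned dissimilarities separate planted blocks", {
  d <- block_matrix(c(3, 3), 0.05, 0.9)
  learned <- learned_matrix(d)
  within <- learned[cbind(c(1, 1, 2, 4, 4, 5), c(2, 3, 3, 5, 6, 6))]
  lab <- rep(1:2, each = 3)
  cross <- learned[outer(lab, lab, "!=")]
  expect_lt(max(within), min(cross))
  expect_equal(diag(learned), setNames(rep(0, 6), rownames(d)))
  expect_true(all(learned >= 0 & learned <= 1))
})

test_that("single-run ensemble yields 0/1 entries and duplicates stay together", {
  d <- block_matrix(c(2, 1), 0.2, 0.8)   # 3 items, k range {2} only
  learned <- learned_matrix(d)
  expect_true(all(learned %in% c(0, 1)))
  # duplicate rows (zero dissimilarity) are never split
  d2 <- block_matrix(c(2, 2, 2), 0, 0.7)
  learned2 <- learned_matrix(d2)
  expect_equal(learned2[1, 2], 0)
  expect_equal(learned2[3, 4], 0)
  expect_equal(learned2[5, 6], 0)
})

test_that("the sweep ensemble is deterministic", {
  set.seed(404)
  d <- random_dissimilarity(8)
  expect_identical(learned_matrix(d), learned_matrix(d))
  expect_identical(learned_matrix(d, weights = "equal"),
                   learned_matrix(d, weights = "equal"))
  expect_error(learned_matrix(d, weights = "x"), "weights")
})

test_that("run weights equal the mean silhouette width of each partition", {
  skip_if_not_installed("cluster")
  set.seed(405)
  for (rep in 1:5) {
    d <- random_dissimilarity(9)
    for (k in 2:4) {
      lab <- pam_medoids(d, k)$labels
      ref <- mean(cluster::silhouette(lab, stats::as.dist(d))[, "sil_width"])
      expect_equal(mean_silhouette(d, lab), max(ref, 0), tolerance = 1e-12)
    }
  }
})

test_that("bootstrap ensemble is reproducible from its seed and needs one", {
  set.seed(11)
  d <- random_dissimilarity(8)
  b1 <- learned_matrix(d, scheme = "bootstrap", n_boot = 50, seed = 99)
  b2 <- learned_matrix(d, scheme = "bootstrap", n_boot = 50, seed = 99)
  expect_identical(b1, b2)
  expect_error(learned_matrix(d, scheme = "bootstrap"), "seed")
})

test_that("planted two-block matrices keep within <= cross after learning", {
  set.seed(500)
  for (rep in 1:10) {
    sizes <- sample(3:5, 2, replace = TRUE)
    base <- block_matrix(sizes, 0.1, 0.5)     # gap above 0.3
    noise <- matrix(runif(sum(sizes)^2, 0, 0.05), sum(sizes))
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    d <- base + noise
    learned <- learned_matrix(d)
    lab <- rep(1:2, sizes)
    within <- learned[outer(lab, lab, "==") & upper.tri(learned)]
    cross <- learned[outer(lab, lab, "!=") & upper.tri(learned)]
    expect_lte(max(within), min(cross))
  }
})
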