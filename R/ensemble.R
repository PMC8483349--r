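#' Two-phase Partitioning Around Medoids
#'
#' Deterministic k-medoids on a precomputed dissimilarity matrix.  The BUILD
#' phase seeds medoids greedily (first the item with the smallest total
#' dissimilarity, then the item with the largest total reduction in the
#' objective; ties broken by lowest index).  The SWAP phase repeatedly applies
#' the best-improvement (medoid, non-medoid) swap — ties broken by lowest
#' (medoid, candidate) index pair — until no swap lowers the objective.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @param k Number of clusters, `2 <= k <= nrow(d)` (`k = nrow(d)` allowed as
#'   the degenerate all-singletons case).
#' @return An object of class `pam_result`: list with `k`, `medoids` (item
#'   indices), `labels` (cluster of each item, numbered by medoid order),
#'   `objective` (sum of dissimilarities of items to their medoids).
#' @export
pam_medoids <- function(d, k) {
  check_dissimilarity(d)
  m <- nrow(d)
  if (k < 2 || k > m) stop("pam_medoids: k out of range")

  # BUILD
  medoids <- which.min(colSums(d))  # lowest index on ties (which.min)
  while (length(medoids) < k) {
    nearest <- apply(d[, medoids, drop = FALSE], 1L, min)
    gain <- vapply(seq_len(m), function(h) {
      if (h %in% medoids) return(-Inf)
      sum(pmax(0, nearest - d[, h]))
    }, numeric(1))
    medoids <- c(medoids, which.max(gain))
  }

  objective_of <- function(med) sum(apply(d[, med, drop = FALSE], 1L, min))

  # SWAP: best improvement, deterministic tie-breaks
  obj <- objective_of(medoids)
  max_iter <- 10L * m
  for (iter in seq_len(max_iter + 1L)) {
    if (iter > max_iter)
      stop("pam_medoids: SWAP failed to converge within ", max_iter,
           " iterations")
    best <- list(delta = 0, medoids = NULL)
    ms <- sort(medoids)
    hs <- setdiff(seq_len(m), medoids)
    for (mi in ms) {
      for (h in hs) {
        cand <- c(setdiff(medoids, mi), h)
        delta <- objective_of(cand) - obj
        if (delta < best$delta - 1e-15) best <- list(delta = delta, medoids = cand)
      }
    }
    if (is.null(best$medoids)) break
    medoids <- best$medoids
    obj <- obj + best$delta
  }

  medoids <- as.integer(unname(sort(medoids)))
  dm <- d[, medoids, drop = FALSE]
  labels <- apply(dm, 1L, which.min)  # nearest medoid, lowest index on ties
  objective <- sum(dm[cbind(seq_len(m), labels)])
  structure(list(k = k, medoids = medoids, labels = as.integer(labels),
                 objective = objective),
            class = "pam_result")
}

#' @export
print.pam_result <- function(x, ...) {
  cat("PAM: k = ", x$k, ", medoids = ", paste(x$medoids, collapse = ", "),
      ", objective = ", format(x$objective), "\n", sep = "")
  invisible(x)
}

check_dissimilarity <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("dissimilarity must be a square matrix")
  if (any(d < 0)) stop("dissimilarity has negative entries")
  if (max(abs(d - t(d))) > 1e-12) stop("dissimilarity is not symmetric")
  if (any(diag(d) != 0)) stop("dissimilarity has non-zero diagonal")
  invisible(TRUE)
}

#' Learned dissimilarities by a PAM ensemble
#'
#' Runs the deterministic two-phase PAM once for every cluster count `k` in
#' `k_min:k_max` and sets the learned dissimilarity of items `i` and `j` to
#' the weighted fraction of runs in which they fall in different clusters —
#' a co-association ensemble over the sweep of `k`.
#'
#' By default each run is weighted by the mean silhouette width of its
#' partition (computed on `d`, clamped at zero).  Runs at a `k` far from any
#' real group structure earn weight near zero, so they contribute little;
#' with equal weights the many high-`k` runs — which mostly split genuine
#' groups arbitrarily — dominate the average and can drown the separation
#' present in the initial dissimilarities.
#'
#' With the optional bootstrap scheme, each run instead resamples the items
#' with replacement, clusters the (deduplicated) resample at a random `k`
#' drawn from the range, and pairs are averaged over the runs in which both
#' items appear.
#'
#' @param d Initial dissimilarity matrix (symmetric, zero diagonal).
#' @param k_min,k_max Range of cluster counts; defaults 2 and `M - 1`.
#' @param weights `"silhouette"` (default), `"equal"`, or a numeric vector of
#'   per-run weights (recycled to the number of runs).
#' @param scheme `"sweep"` (default, deterministic) or `"bootstrap"`.
#' @param n_boot,seed Bootstrap runs and seed (ignored for `"sweep"`).
#' @return A learned dissimilarity matrix in `[0, 1]` with the same dimnames,
#'   zero diagonal.
#' @export
learned_matrix <- function(d, k_min = 2, k_max = nrow(d) - 1L,
                           weights = "silhouette",
                           scheme = c("sweep", "bootstrap"),
                           n_boot = 100L, seed = NULL) {
  check_dissimilarity(d)
  scheme <- match.arg(scheme)
  m <- nrow(d)
  if (m < 3L) stop("learned_matrix: need at least 3 items")
  if (!(2 <= k_min && k_min <= k_max && k_max <= m - 1L))
    stop("learned_matrix: need 2 <= k_min <= k_max <= M - 1")

  if (scheme == "sweep") {
    ks <- seq.int(k_min, k_max)
    labs <- lapply(ks, function(k) pam_medoids(d, k)$labels)
    w <- if (is.numeric(weights)) {
      rep_len(weights, length(ks))
    } else if (identical(weights, "equal")) {
      rep(1, length(ks))
    } else if (identical(weights, "silhouette")) {
      vapply(labs, function(lab) mean_silhouette(d, lab), numeric(1))
    } else {
      stop("learned_matrix: weights must be \"silhouette\", \"equal\", ",
           "or a numeric vector")
    }
    if (sum(w) <= 0) w <- rep(1, length(ks))  # degenerate: no structure at all
    acc <- matrix(0, m, m)
    for (i in seq_along(ks)) acc <- acc + w[i] * outer(labs[[i]], labs[[i]], "!=")
    learned <- acc / sum(w)
  } else {
    if (is.null(seed)) stop("learned_matrix: bootstrap scheme requires a seed")
    set.seed(seed)
    diff_cnt <- matrix(0, m, m)
    both_cnt <- matrix(0, m, m)
    for (b in seq_len(n_boot)) {
      idx <- sort(unique(sample.int(m, m, replace = TRUE)))
      if (length(idx) < 3L) next
      ks <- seq.int(k_min, min(k_max, length(idx) - 1L))
      k <- ks[sample.int(length(ks), 1L)]
      lab <- pam_medoids(d[idx, idx, drop = FALSE], k)$labels
      both_cnt[idx, idx] <- both_cnt[idx, idx] + 1
      diff_cnt[idx, idx] <- diff_cnt[idx, idx] + outer(lab, lab, "!=")
    }
    learned <- ifelse(both_cnt > 0, diff_cnt / both_cnt, 1)
  }
  diag(learned) <- 0
  dimnames(learned) <- dimnames(d)
  check_dissimilarity(learned)
  learned
}

# Mean silhouette width of a partition under dissimilarity d, clamped at 0.
# Items in singleton clusters contribute 0 (the usual convention).
mean_silhouette <- function(d, lab) {
  m <- nrow(d)
  k <- max(lab)
  if (k < 2L || k >= m) return(0)
  occupied <- which(tabulate(lab, nbins = k) > 0)  # ties can empty a cluster
  s <- numeric(m)
  for (i in seq_len(m)) {
    own <- lab == lab[i] & seq_len(m) != i
    others <- setdiff(occupied, lab[i])
    if (!any(own) || length(others) == 0L) next   # singleton / lone cluster
    a <- mean(d[i, own])
    b <- min(vapply(others, function(g) mean(d[i, lab == g]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  max(mean(s), 0)
}
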