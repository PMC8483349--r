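#' Minimax-linkage hierarchical clustering
#'
#' Agglomerative clustering in which, at every step, the pair of clusters
#' merged is the one whose union has the smallest minimax radius: the minimum
#' over candidate prototypes (members of the union) of the maximum
#' dissimilarity from the prototype to all members.  The merge height is that
#' radius and the minimizing member is recorded as the cluster's prototype,
#' so every internal cluster is summarized by an actual item.
#'
#' Ties are broken deterministically: among equal-radius candidate merges the
#' pair whose clusters contain the lexicographically smallest (minimum leaf
#' index) pair wins; among equally good prototypes the lowest leaf index
#' wins.  Height inversions (a merge lower than an earlier one), which
#' minimax linkage permits, are flagged in `inversions`; cutting is by merge
#' order, so they do not affect the groups.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal; dimnames used
#'   as leaf labels.
#' @return An object of class `minimax_dendrogram`: `merge` (hclust-style
#'   `(M-1) x 2` matrix, negative = leaf, positive = earlier merge), `height`,
#'   `prototype` (leaf index per merge), `labels`, `order` (leaf ordering for
#'   plotting), `inversions` (logical).
#' @export
minimax_linkage <- function(d) {
  check_dissimilarity(d)
  m <- nrow(d)
  if (m < 2L) stop("minimax_linkage: need at least 2 items")
  labels <- rownames(d) %||% as.character(seq_len(m))

  # active clusters: list of member leaf-index vectors; id = hclust code
  members <- as.list(seq_len(m))
  ids <- -seq_len(m)
  merge <- matrix(0L, m - 1L, 2L)
  height <- numeric(m - 1L)
  prototype <- integer(m - 1L)

  for (step in seq_len(m - 1L)) {
    n_act <- length(members)
    best <- NULL
    for (i in seq_len(n_act - 1L)) {
      for (j in seq.int(i + 1L, n_act)) {
        u <- c(members[[i]], members[[j]])
        pr <- minimax_prototype(d, u)
        key <- sort(c(min(members[[i]]), min(members[[j]])))
        if (is.null(best) ||
            pr$radius < best$radius - 1e-15 ||
            (abs(pr$radius - best$radius) <= 1e-15 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, radius = pr$radius,
                       prototype = pr$prototype, key = key)
        }
      }
    }
    merge[step, ] <- c(ids[[best$i]], ids[[best$j]])
    height[step] <- best$radius
    prototype[step] <- best$prototype
    members[[best$i]] <- c(members[[best$i]], members[[best$j]])
    ids[[best$i]] <- step
    members[[best$j]] <- NULL
    ids <- ids[-best$j]
  }

  structure(
    list(merge = merge, height = height, prototype = prototype,
         labels = labels, order = dendrogram_order(merge, m),
         inversions = is.unsorted(height)),
    class = "minimax_dendrogram"
  )
}

# Prototype of a member set: the member minimizing the maximum dissimilarity
# to all members; ties -> lowest leaf index.  Returns prototype and radius.
minimax_prototype <- function(d, u) {
  u <- sort(u)
  radii <- apply(d[u, u, drop = FALSE], 1L, max)
  i <- which.min(radii)
  list(prototype = u[i], radius = radii[i])
}

# hclust-compatible leaf order: left-to-right traversal of the merge tree.
dendrogram_order <- function(merge, m) {
  leaves <- function(node) {
    if (node < 0) return(-node)
    c(leaves(merge[node, 1]), leaves(merge[node, 2]))
  }
  leaves(m - 1L)
}

#' @export
print.minimax_dendrogram <- function(x, ...) {
  cat("Minimax-linkage dendrogram: ", length(x$labels), " leaves, ",
      if (x$inversions) "with" else "no", " height inversions\n", sep = "")
  invisible(x)
}

#' @method as.hclust minimax_dendrogram
#' @export
as.hclust.minimax_dendrogram <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = x$order,
         labels = x$labels, method = "minimax",
         dist.method = "learned dissimilarity", call = match.call()),
    class = "hclust"
  )
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges, i.e. keeps the clusters formed by the first
#' `M - k` merges.  Cluster numbers are stable: clusters are numbered by the
#' order in which their first leaf appears (leaf 1's cluster is 1, ...).
#'
#' @param dendrogram A `minimax_dendrogram`.
#' @param k Number of clusters, `1 <= k <= M`.
#' @return Named integer vector of cluster labels, one per leaf.
#' @export
cut_dendrogram <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "minimax_dendrogram"))
  m <- length(dendrogram$labels)
  if (k < 1 || k > m) stop("cut_dendrogram: k out of range")
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  node_root <- integer(m - 1L)
  n_merges <- m - k
  for (s in seq_len(n_merges)) {
    a <- dendrogram$merge[s, 1]; b <- dendrogram$merge[s, 2]
    ra <- find(if (a < 0) -a else node_root[a])
    rb <- find(if (b < 0) -b else node_root[b])
    parent[rb] <- ra
    node_root[s] <- ra
  }
  if (n_merges < m - 1L) {
    for (s in seq.int(n_merges + 1L, m - 1L)) {
      a <- dendrogram$merge[s, 1]
      node_root[s] <- if (a < 0) -a else node_root[a]
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  lab <- match(roots, unique(roots))  # numbered by first-leaf appearance
  stats::setNames(as.integer(lab), dendrogram$labels)
}

#' Dendrogram merge table
#'
#' @param x A `minimax_dendrogram`.
#' @param ... Unused.
#' @return A tibble with one row per merge: `step`, `height`, `prototype`
#'   (leaf label), `members` (comma-separated leaf labels of the merged
#'   cluster).
#' @method tidy minimax_dendrogram
#' @export
tidy.minimax_dendrogram <- function(x, ...) {
  m <- length(x$labels)
  members_of <- function(node) {
    if (node < 0) return(-node)
    c(members_of(x$merge[node, 1]), members_of(x$merge[node, 2]))
  }
  tibble::tibble(
    step = seq_len(m - 1L),
    height = x$height,
    prototype = x$labels[x$prototype],
    members = vapply(seq_len(m - 1L), function(s)
      paste(x$labels[sort(members_of(s))], collapse = ","), character(1))
  )
}

#' Serialize a dendrogram to Newick
#'
#' Branch lengths derive from merge heights and internal node labels are the
#' cluster prototypes.
#'
#' @param dendrogram A `minimax_dendrogram`.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(dendrogram, path = NULL) {
  hc <- stats::as.hclust(dendrogram)
  phy <- ape::as.phylo(hc)
  # attach prototypes as internal node labels, matching nodes to merges by
  # their descendant tip sets (phylo node numbering differs from merge order)
  m <- length(dendrogram$labels)
  merge_sets <- vector("list", m - 1L)
  for (s in seq_len(m - 1L)) {
    kids <- dendrogram$merge[s, ]
    merge_sets[[s]] <- sort(unlist(lapply(kids, function(x)
      if (x < 0) -x else merge_sets[[x]])))
  }
  merge_keys <- vapply(merge_sets, function(ix)
    paste(sort(dendrogram$labels[ix]), collapse = "\r"), character(1))
  clades <- ape::prop.part(phy)
  node_keys <- vapply(clades, function(ix)
    paste(sort(attr(clades, "labels")[ix]), collapse = "\r"), character(1))
  phy$node.label <- dendrogram$labels[
    dendrogram$prototype[match(node_keys, merge_keys)]]
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
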