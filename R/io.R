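#' Write / read a dissimilarity matrix as CSV
#'
#' Square CSV with the combination keys as header row and first column.
#' Values are written with 17 significant digits so that a read-back followed
#' by a re-write reproduces the file byte-for-byte.
#'
#' @param d Symmetric dissimilarity matrix with dimnames.
#' @param path CSV path.
#' @return `path` (writer) / the matrix with a `tau` attribute if present
#'   (reader).
#' @export
write_dissimilarity <- function(d, path) {
  check_dissimilarity(d)
  keys <- rownames(d) %||% as.character(seq_len(nrow(d)))
  lines <- c(
    paste(c("key", keys), collapse = ","),
    vapply(seq_len(nrow(d)), function(i)
      paste(c(keys[i], sprintf("%.17g", d[i, ])), collapse = ","),
      character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  keys <- raw[[1]]
  d <- as.matrix(raw[, -1, drop = FALSE])
  dimnames(d) <- list(keys, colnames(raw)[-1])
  storage.mode(d) <- "double"
  check_dissimilarity(d)
  d
}

#' Write a fitted system to a structured text file
#'
#' Serializes the assignment rule, dissimilarity matrices, dendrogram,
#' C-index curve and group summaries of an [eaccd_fit()] as a single JSON
#' document (numbers at full precision).  `read_system()` restores an
#' `eaccd_fit` equivalent for prediction and reporting (the training cases
#' themselves are not stored).
#'
#' @param fit An `eaccd_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_system <- function(fit, path) {
  stopifnot(inherits(fit, "eaccd_fit"))
  dend <- fit$dendrogram
  doc <- list(
    format = "eaccd_system",
    version = 1L,
    factors = fit$factors,
    tau = fit$tau,
    min_count = fit$min_count,
    horizon = fit$horizon,
    n_combinations = fit$n_combinations,
    n_cases = fit$n_cases,
    n_star = fit$n_star,
    n_star_auto = fit$n_star_auto,
    c_index = fit$c_index,
    assignment = as.list(fit$assignment),
    group_summary = as.list(fit$group_summary),
    c_curve = as.list(fit$c_curve),
    dendrogram = list(
      labels = dend$labels,
      merge1 = dend$merge[, 1], merge2 = dend$merge[, 2],
      height = dend$height, prototype = dend$prototype,
      order = dend$order, inversions = dend$inversions
    ),
    d_init = list(keys = rownames(fit$d_init),
                  values = as.vector(fit$d_init)),
    d_learned = list(keys = rownames(fit$d_learned),
                     values = as.vector(fit$d_learned))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_system
#' @export
read_system <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "eaccd_system"))
    stop("read_system: not an eaccd system file")
  m <- doc$n_combinations
  unpack <- function(x) {
    d <- matrix(x$values, m, m, dimnames = list(x$keys, x$keys))
    d
  }
  dend <- structure(
    list(merge = cbind(as.integer(doc$dendrogram$merge1),
                       as.integer(doc$dendrogram$merge2)),
         height = doc$dendrogram$height,
         prototype = as.integer(doc$dendrogram$prototype),
         labels = doc$dendrogram$labels,
         order = as.integer(doc$dendrogram$order),
         inversions = doc$dendrogram$inversions),
    class = "minimax_dendrogram")
  structure(
    list(
      factors = doc$factors, tau = doc$tau, min_count = doc$min_count,
      horizon = doc$horizon, n_combinations = m, n_cases = doc$n_cases,
      removed = NULL,
      d_init = unpack(doc$d_init), d_learned = unpack(doc$d_learned),
      dendrogram = dend,
      c_curve = tibble::as_tibble(doc$c_curve),
      n_star_auto = as.integer(doc$n_star_auto),
      n_star = as.integer(doc$n_star),
      assignment = tibble::as_tibble(doc$assignment),
      group_summary = tibble::as_tibble(doc$group_summary),
      c_index = doc$c_index,
      data = NULL
    ),
    class = "eaccd_fit"
  )
}

#' Write a survival curve as CSV
#'
#' @param curve A `km_curve` or `completed_curve`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(tidy(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
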