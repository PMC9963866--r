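# Matrix correlation statistics: Pearson on vectors, the Mantel permutation
# test for distance matrices, and the clustered-heatmap computation
# (unit-variance column scaling, correlation distance, average linkage).

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite values.
#' @return List with `r`, `p_value`, `n`, `df`.
#' @export
pearson_vector <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  list(r = r, p_value = min(p, 1), n = n, df = n - 2L)
}

.lower_vec <- function(m) m[lower.tri(m)]

.align_matrices <- function(m1, m2) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    common <- intersect(rownames(m1), rownames(m2))
    only1 <- setdiff(rownames(m1), rownames(m2))
    only2 <- setdiff(rownames(m2), rownames(m1))
    if (length(only1) || length(only2))
      stop("matrix labels disagree; only in first: ",
           paste(only1, collapse = ", "), "; only in second: ",
           paste(only2, collapse = ", "))
    m2 <- m2[rownames(m1), rownames(m1)]
  } else if (!all(dim(m1) == dim(m2))) {
    stop("unlabeled matrices of different dimensions")
  }
  # drop taxa with missing entries so the permuted submatrix is complete
  diag(m1) <- 0; diag(m2) <- 0
  bad <- rowSums(is.na(m1)) > 0 | rowSums(is.na(m2)) > 0
  if (any(bad)) {
    warning("dropping ", sum(bad),
            " taxa with missing entries before the Mantel test")
    m1 <- m1[!bad, !bad]; m2 <- m2[!bad, !bad]
  }
  list(m1 = m1, m2 = m2)
}

.perms <- function(n) {
  # all permutations of 1..n, deterministic order
  if (n == 1L) return(list(1L))
  out <- list()
  for (k in seq_len(n)) {
    sub <- .perms(n - 1L)
    out <- c(out, lapply(sub, function(p) c(k, ifelse(p >= k, p + 1L, p))))
  }
  out
}

#' Mantel permutation test
#'
#' Pearson correlation between the lower triangles of two distance matrices;
#' significance by jointly permuting one matrix's rows and columns. The
#' p-value uses the add-one convention `p = (hits + 1) / (n_perm + 1)`. With
#' `exact = TRUE` all `n!` relabelings are enumerated (n <= 8) and
#' `p = hits / n!` with the identity included.
#'
#' @param dm1,dm2 Symmetric matrices with matching labels (order reconciled
#'   by name when dimnames are present).
#' @param n_perm Number of random permutations (default 9999).
#' @param tail `"greater"` (default; positive association), `"less"` or
#'   `"two_sided"`.
#' @param seed Integer seed (required unless `exact = TRUE`).
#' @param exact Enumerate all permutations instead of sampling.
#' @return A list of class `"mantel_result"`: `r`, `p_value`,
#'   `n_permutations`, `tail`, `seed`, `n`.
#' @export
mantel <- function(dm1, dm2, n_perm = 9999,
                   tail = c("greater", "less", "two_sided"), seed = NULL,
                   exact = FALSE) {
  tail <- match.arg(tail)
  al <- .align_matrices(dm1, dm2)
  m1 <- al$m1; m2 <- al$m2
  n <- nrow(m1)
  if (n < 3L) stop("need at least 3 taxa after alignment")
  v1 <- .lower_vec(m1)
  r_obs <- stats::cor(v1, .lower_vec(m2))
  meets <- function(r_perm) switch(tail,
    greater = r_perm >= r_obs - 1e-12,
    less = r_perm <= r_obs + 1e-12,
    two_sided = abs(r_perm) >= abs(r_obs) - 1e-12)
  if (exact) {
    if (n > 8L) stop("exact enumeration limited to n <= 8")
    perms <- .perms(n)
    rs <- vapply(perms, function(p) stats::cor(v1, .lower_vec(m2[p, p])), 0)
    p <- sum(meets(rs)) / length(perms)
    n_used <- length(perms)
  } else {
    if (is.null(seed)) stop("a seed is required for the permutation test")
    set.seed(as.integer(seed))
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pp <- sample.int(n)
      if (meets(stats::cor(v1, .lower_vec(m2[pp, pp])))) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(r = r_obs, p_value = p, n_permutations = n_used,
                 tail = tail, seed = seed, n = n, exact = exact),
            class = "mantel_result")
}

#' Clustered-heatmap computation
#'
#' Numeric contract behind a ClustVis-style heatmap: columns are scaled to
#' unit variance (mean 0, sd 1; constant columns dropped with a warning), row
#' and column dissimilarities are `1 - Pearson` between profiles, and both
#' are clustered by average linkage (UPGMA on the dissimilarities). Rows with
#' missing values use pairwise-complete correlations (with a warning); rows
#' sharing fewer than 3 complete entries with some other row are dropped.
#'
#' @param values Numeric matrix with row and column labels (>= 2 x 2 after
#'   dropping constant columns).
#' @return A list of class `"clustered_heatmap"`: `scaled_values`,
#'   `row_order`, `col_order` (label permutations), `row_linkage`,
#'   `col_linkage` (`hclust` objects).
#' @export
cluster_heatmap <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("row", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("col", seq_len(ncol(values)))
  sds <- apply(values, 2L, stats::sd, na.rm = TRUE)
  const <- !is.na(sds) & sds == 0
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(values)[const], collapse = ", "))
    values <- values[, !const, drop = FALSE]
  }
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need at least 2 rows and 2 non-constant columns")
  scaled <- scale(values)

  if (anyNA(scaled)) {
    warning("missing values present; using pairwise-complete correlations")
    shared <- tcrossprod(!is.na(scaled))
    bad <- apply(shared - diag(diag(shared)), 1L, max) < 3
    if (any(bad)) {
      warning("dropping row(s) with < 3 shared entries: ",
              paste(rownames(scaled)[bad], collapse = ", "))
      scaled <- scaled[!bad, , drop = FALSE]
    }
  }
  cor_dist <- function(m) stats::as.dist(1 - stats::cor(t(m),
                                         use = "pairwise.complete.obs"))
  row_hc <- stats::hclust(cor_dist(scaled), method = "average")
  col_hc <- stats::hclust(cor_dist(t(scaled)), method = "average")
  structure(list(
    scaled_values = scaled[, , drop = FALSE],
    row_order = rownames(scaled)[row_hc$order],
    col_order = colnames(scaled)[col_hc$order],
    row_linkage = row_hc, col_linkage = col_hc),
    class = "clustered_heatmap")
}
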