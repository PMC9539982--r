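#' Cophenetic (patristic) distances from a tree
#'
#' Tip-to-tip path lengths summed over branch lengths, via
#' [ape::cophenetic.phylo()] after validating that branch lengths exist.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Symmetric distance matrix with zero diagonal, tips as dimnames.
#' @export
cophenetic_distances <- function(tree) {
  validate_tree(tree)
  if (length(tree$tip.label) < 2L)
    stop("need at least two tips", call. = FALSE)
  stats::cophenetic(tree)
}

#' Jaccard dissimilarity between partner sets
#'
#' For each pair of rows (or columns) of a binary incidence matrix, one minus
#' the Jaccard similarity of their partner sets. Rows with no partners are
#' excluded with a warning. Delegates to [vegan::vegdist()].
#'
#' @param incidence Binary matrix.
#' @param axis `"rows"` (default; e.g. plants by their fungi) or `"columns"`.
#' @return Symmetric dissimilarity matrix in `[0, 1]`.
#' @export
jaccard_dissimilarity <- function(incidence, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(incidence), all(incidence %in% c(0L, 1L)))
  x <- if (axis == "rows") incidence else t(incidence)
  empty <- rowSums(x) == 0L
  if (any(empty)) {
    warning("excluding ", sum(empty), " units with empty partner sets")
    x <- x[!empty, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("need at least two non-empty units", call. = FALSE)
  as.matrix(vegan::vegdist(x, method = "jaccard", binary = TRUE))
}

.mantel_check <- function(d1, d2) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2)))
    stop("distance matrices are not conformable", call. = FALSE)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop("distance matrices must share ids in the same order", call. = FALSE)
  if (nrow(d1) < 4L)
    stop("Mantel tests need at least 4 units", call. = FALSE)
  list(d1 = d1, d2 = d2)
}

# Pearson correlation between strictly-lower-triangle vectors; NA if either
# triangle has zero variance.
.tri_cor <- function(v1, v2) {
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
  stats::cor(v1, v2)
}

#' Mantel permutation test
#'
#' Pearson correlation between the strictly-lower-triangle vectors of two
#' distance (or similarity) matrices, with significance from jointly
#' permuting the row/column labels of the second matrix. The test is
#' one-tailed for positive association, the ecological hypothesis here, and
#' uses the +1/+1 convention so the reported p is never 0:
#' `p = (1 + #permuted r >= observed r) / (1 + n_perm)`.
#'
#' @param d1,d2 Conformable symmetric matrices over the same ids.
#' @param n_perm Number of label permutations.
#' @return A list of class `mantel_test` with `r`, `p`, `n_perm`, `partial`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L) {
  m <- .mantel_check(d1, d2)
  d1 <- m$d1; d2 <- m$d2
  n <- nrow(d1)
  lt <- lower.tri(d1)
  ij <- which(lt, arr.ind = TRUE)
  v1 <- d1[lt]; v2 <- d2[lt]
  r_obs <- .tri_cor(v1, v2)
  if (is.na(r_obs)) {
    warning("zero-variance distance triangle; Mantel r undefined")
    return(structure(list(r = NA_real_, p = NA_real_, n_perm = n_perm,
                          partial = FALSE), class = "mantel_test"))
  }
  v1c <- v1 - mean(v1)
  den1 <- sqrt(sum(v1c^2))
  r_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    vp <- d2[cbind(p[ij[, 1]], p[ij[, 2]])]
    vpc <- vp - mean(vp)
    r_perm[b] <- sum(v1c * vpc) / (den1 * sqrt(sum(vpc^2)))
  }
  p_val <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  structure(list(r = r_obs, p = p_val, n_perm = n_perm, partial = FALSE),
            class = "mantel_test")
}

# First-order partial correlation of triangle vectors.
.partial_r <- function(r12, r13, r23) {
  (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
}

#' Partial Mantel permutation test
#'
#' First-order partial correlation between `d1` and `d2` controlling `d3` on
#' triangle vectors, `r12.3 = (r12 - r13 r23) / sqrt((1-r13^2)(1-r23^2))`.
#' Significance comes from permuting the labels of `d2` and recomputing the
#' partial statistic (one-tailed, +1/+1 convention).
#'
#' @param d1,d2,d3 Conformable symmetric matrices over the same ids; `d3` is
#'   the matrix controlled for.
#' @param n_perm Number of label permutations.
#' @return A `mantel_test` with `partial = TRUE` and `controlled = "d3"`.
#' @export
partial_mantel_test <- function(d1, d2, d3, n_perm = 999L) {
  m <- .mantel_check(d1, d2)
  m3 <- .mantel_check(d1, d3)
  d1 <- m$d1; d2 <- m$d2; d3 <- m3$d2
  n <- nrow(d1)
  lt <- lower.tri(d1)
  ij <- which(lt, arr.ind = TRUE)
  v1 <- d1[lt]; v2 <- d2[lt]; v3 <- d3[lt]
  r12 <- .tri_cor(v1, v2); r13 <- .tri_cor(v1, v3); r23 <- .tri_cor(v2, v3)
  if (anyNA(c(r12, r13, r23)) || abs(r13) >= 1 || abs(r23) >= 1) {
    warning("partial Mantel statistic undefined (degenerate correlations)")
    return(structure(list(r = NA_real_, p = NA_real_, n_perm = n_perm,
                          partial = TRUE, controlled = "d3"),
                     class = "mantel_test"))
  }
  r_obs <- .partial_r(r12, r13, r23)
  r_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    vp <- d2[cbind(p[ij[, 1]], p[ij[, 2]])]
    r12p <- .tri_cor(v1, vp)
    r23p <- .tri_cor(vp, v3)
    r_perm[b] <- if (anyNA(c(r12p, r23p)) || abs(r23p) >= 1) NA_real_
                 else .partial_r(r12p, r13, r23p)
  }
  r_perm <- r_perm[!is.na(r_perm)]
  p_val <- (1 + sum(r_perm >= r_obs)) / (1 + length(r_perm))
  structure(list(r = r_obs, p = p_val, n_perm = n_perm, partial = TRUE,
                 controlled = "d3"), class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(if (isTRUE(x$partial)) "Partial Mantel" else "Mantel",
      "test: r =", format(x$r, digits = 4),
      " p =", format(x$p, digits = 4),
      " (", x$n_perm, "permutations, one-tailed )\n")
  invisible(x)
}
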