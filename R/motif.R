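#' Count diamond-shaped modules
#'
#' A diamond is an unordered pair of distinct fungi linked to the same
#' mycoheterotrophic plant and the same autotrophic plant (four nodes, four
#' edges). With `S_M = t(M) %*% M` and `S_A = t(A) %*% A` the fungal
#' co-occurrence matrices within each guild block, the count is
#' `sum over f1 < f2 of S_M[f1,f2] * S_A[f1,f2]` — every combination of a
#' shared mycoheterotroph and a shared autotroph for every fungus pair.
#'
#' @param net A `tripartite_network`.
#' @return Integer-valued count (as double; counts can exceed .Machine
#'   integer range on dense networks).
#' @export
count_diamond_modules <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  sm <- crossprod(net$M)
  sa <- crossprod(net$A)
  lt <- lower.tri(sm)
  sum(as.numeric(sm[lt]) * as.numeric(sa[lt]))
}

#' Degree-proportional null-model probabilities for one block
#'
#' Cell probabilities of the degree-proportional Bernoulli null model: the
#' probability of a link between plant `i` and fungus `j` is the arithmetic
#' mean of the plant's fill fraction and the fungus's fill fraction,
#' `p_ij = (k_i / C + k_j / R) / 2` for an `R x C` block. The probabilities
#' conserve the block's link total exactly: `sum(p) = sum(m)`.
#'
#' @param incidence Binary `R x C` matrix.
#' @return List of class `null_model_spec`: `p` (probability matrix),
#'   `row_degrees`, `col_degrees`, `links`.
#' @export
null_probabilities <- function(incidence) {
  stopifnot(is.matrix(incidence), nrow(incidence) > 0L, ncol(incidence) > 0L,
            all(incidence %in% c(0L, 1L)))
  R <- nrow(incidence); C <- ncol(incidence)
  ki <- rowSums(incidence); kj <- colSums(incidence)
  p <- (matrix(ki / C, R, C) + matrix(kj / R, R, C, byrow = TRUE)) / 2
  dimnames(p) <- dimnames(incidence)
  structure(list(p = p, row_degrees = ki, col_degrees = kj,
                 links = sum(incidence)),
            class = "null_model_spec")
}

#' Draw one null incidence matrix
#'
#' Independent Bernoulli draw per cell from a [null_probabilities()] spec. A
#' surveyed plant always carries at least one fungus, so draws leaving any
#' plant row without links are rejected and the whole matrix redrawn (up to
#' `max_retries`), which avoids biasing individual cells. Fungal columns are
#' unconstrained: with few plants per block, low-degree fungi go extinct in
#' a sizable fraction of faithful null draws (and the aligned blocks of a
#' tripartite network legitimately contain empty columns), so conditioning
#' columns on presence would be both infeasible and a misrepresentation of
#' the null.
#'
#' @param spec A `null_model_spec`.
#' @param max_retries Whole-matrix redraw cap.
#' @return Binary matrix with the spec's dimensions and dimnames.
#' @export
sample_null_network <- function(spec, max_retries = 1000L) {
  stopifnot(inherits(spec, "null_model_spec"))
  p <- spec$p
  nr <- nrow(p); nc <- ncol(p)
  for (i in seq_len(max_retries)) {
    draw <- matrix((stats::runif(nr * nc) < p) * 1L, nr, nc,
                   dimnames = dimnames(p))
    if (all(rowSums(draw) > 0L)) return(draw)
  }
  stop("could not draw a null matrix without empty rows/columns in ",
       max_retries, " attempts (block too sparse)", call. = FALSE)
}

#' Randomize a tripartite network under the null model
#'
#' The two guild blocks are randomized separately — each from its own
#' degree-proportional spec, reflecting the imbalanced numbers of
#' mycoheterotrophic and autotrophic plants — then recombined over the
#' unchanged fungal index.
#'
#' @param net A `tripartite_network`.
#' @param max_retries Redraw cap passed to [sample_null_network()].
#' @return A randomized `tripartite_network` with identical dimensions.
#' @export
randomize_tripartite <- function(net, max_retries = 1000L) {
  stopifnot(inherits(net, "tripartite_network"))
  M <- sample_null_network(null_probabilities(net$M), max_retries)
  A <- sample_null_network(null_probabilities(net$A), max_retries)
  structure(list(M = M, A = A, fungi = net$fungi),
            class = "tripartite_network")
}

#' Diamond-module overrepresentation test
#'
#' Counts diamond modules in the empirical network and in `n_null` null
#' networks drawn by [randomize_tripartite()], then summarizes the null
#' distribution. Reported are the z-score `(obs - null mean) / null SD`, the
#' empirical one-tailed p-value with the +1/+1 convention (never exactly 0),
#' and the 2.5th/97.5th null percentiles. The overrepresentation flag is
#' governed by the percentile interval: the module is flagged when the
#' observed count exceeds the upper bound.
#'
#' With `scope = "shared"` the empirical network is first restricted to fungi
#' present in both guilds, and the null probabilities are recomputed on the
#' restricted blocks, so the test asks about preference among the fungi the
#' mycoheterotrophs actually use.
#'
#' @param net A `tripartite_network`.
#' @param scope `"all"` fungi or only the `"shared"` fungi.
#' @param n_null Number of null networks.
#' @param max_retries Redraw cap per null network.
#' @return Object of class `motif_null_test`.
#' @export
motif_null_test <- function(net, scope = c("all", "shared"), n_null = 1000L,
                            max_retries = 1000L) {
  scope <- match.arg(scope)
  stopifnot(inherits(net, "tripartite_network"), n_null >= 2L)
  if (scope == "shared") net <- restrict_to_shared_fungi(net)
  obs <- count_diamond_modules(net)
  spec_m <- null_probabilities(net$M)
  spec_a <- null_probabilities(net$A)
  null_counts <- vapply(seq_len(n_null), function(i) {
    rnd <- structure(list(M = sample_null_network(spec_m, max_retries),
                          A = sample_null_network(spec_a, max_retries),
                          fungi = net$fungi),
                     class = "tripartite_network")
    count_diamond_modules(rnd)
  }, numeric(1))
  null_mean <- mean(null_counts)
  null_sd <- stats::sd(null_counts)
  z <- if (null_sd > 0) (obs - null_mean) / null_sd else {
    warning("null distribution has zero spread; z undefined")
    NA_real_
  }
  ci <- stats::quantile(null_counts, c(0.025, 0.975), names = FALSE)
  p_emp <- (1 + sum(null_counts >= obs)) / (1 + n_null)
  structure(list(observed = obs, null_counts = null_counts,
                 null_mean = null_mean, null_sd = null_sd, z = z,
                 p = p_emp, ci_low = ci[1], ci_high = ci[2],
                 overrepresented = obs > ci[2], scope = scope,
                 n_null = n_null),
            class = "motif_null_test")
}

#' @export
print.motif_null_test <- function(x, ...) {
  cat("Diamond-module null test (scope:", x$scope, ",", x$n_null,
      "null networks)\n")
  cat("  observed:", x$observed, "  null:",
      format(x$null_mean, digits = 6), "+/-", format(x$null_sd, digits = 4),
      "\n")
  cat("  z =", format(x$z, digits = 4), "  p =", format(x$p, digits = 4),
      "  95% null interval: [", x$ci_low, ",", x$ci_high, "]\n")
  cat("  overrepresented:", x$overrepresented, "\n")
  invisible(x)
}
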