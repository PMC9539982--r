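#' Build a tripartite network from a binary incidence matrix
#'
#' Splits a plant x fungus incidence matrix into its two guild blocks — M
#' (mycoheterotrophs x fungi, the antagonistic interactions) and A
#' (autotrophs x fungi, the mutualistic interactions) — over one shared,
#' identically ordered fungal index.
#'
#' @param incidence Binary plant x fungus matrix with row and column names.
#' @param guild Named character vector (`"autotroph"`/`"mycoheterotroph"`)
#'   covering every row of `incidence`.
#' @return An object of class `tripartite_network` with elements `M`, `A`
#'   (binary matrices sharing colnames) and `fungi` (the column ids).
#' @export
tripartite_network <- function(incidence, guild) {
  stopifnot(is.matrix(incidence), all(incidence %in% c(0L, 1L)))
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("incidence matrix needs row and column names", call. = FALSE)
  g <- guild[rownames(incidence)]
  if (anyNA(g))
    stop("guild missing for plants: ",
         paste(rownames(incidence)[is.na(g)], collapse = ", "), call. = FALSE)
  M <- incidence[g == "mycoheterotroph", , drop = FALSE]
  A <- incidence[g == "autotroph", , drop = FALSE]
  if (nrow(M) == 0L || nrow(A) == 0L)
    stop("both guilds must be represented in the network", call. = FALSE)
  structure(list(M = M, A = A, fungi = colnames(incidence)),
            class = "tripartite_network")
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat("tripartite_network:", nrow(x$M), "mycoheterotrophs /",
      nrow(x$A), "autotrophs /", length(x$fungi), "fungi\n")
  cat("  links: M =", sum(x$M), " A =", sum(x$A), "\n")
  invisible(x)
}

#' Normalized degree
#'
#' A node's realized partners divided by its possible partners within the
#' incidence matrix: for plants, the fraction of all fungi it hosts; for
#' fungi, the fraction of all plants hosting it.
#'
#' @param incidence Binary matrix (plants x fungi).
#' @param axis `"plants"` (rows) or `"fungi"` (columns).
#' @return Named numeric vector in `[0, 1]`.
#' @export
normalized_degree <- function(incidence, axis = c("plants", "fungi")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(incidence), nrow(incidence) > 0L, ncol(incidence) > 0L)
  if (axis == "plants") rowSums(incidence) / ncol(incidence)
  else colSums(incidence) / nrow(incidence)
}

#' Phylogenetic species variability of a community
#'
#' One minus the mean phylogenetic correlation among the community's members:
#' 1 for a star-like, fully unrelated community, approaching 0 as relatedness
#' increases. The tip correlation is shared root-to-MRCA path length scaled by
#' the geometric mean of tip depths, which reduces to the classic formulation
#' on ultrametric trees and stays defined otherwise.
#'
#' @param community Character vector of tip labels (the fungi of one plant).
#' @param tree A `phylo` tree containing all community members.
#' @return A list of class `psv_result`: `n` (community size) and `psv`
#'   (`NA` with a warning when `n < 2`).
#' @export
psv <- function(community, tree) {
  community <- unique(as.character(community))
  missing_tips <- setdiff(community, tree$tip.label)
  if (length(missing_tips))
    stop("community members absent from tree: ",
         paste(missing_tips, collapse = ", "), call. = FALSE)
  n <- length(community)
  if (n < 2L) {
    warning("psv undefined for communities of fewer than 2 taxa")
    return(structure(list(n = n, psv = NA_real_), class = "psv_result"))
  }
  C <- ape::vcv(tree, corr = TRUE)[community, community]
  val <- (n * sum(diag(C)) - sum(C)) / (n * (n - 1))
  structure(list(n = n, psv = val), class = "psv_result")
}

#' Fungal-overlap weights between plant pairs
#'
#' For every unordered pair of plants (any guild combination), the number of
#' fungi they share. Pairs sharing nothing are omitted. Each edge is tagged by
#' its guild combination (`MH-MH`, `MH-A`, `A-A`).
#'
#' @param net A `tripartite_network`.
#' @return data.frame with columns `plant1`, `plant2`, `weight`, `type`.
#' @export
plant_plant_overlap <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  B <- rbind(net$M, net$A)
  g <- c(rep("MH", nrow(net$M)), rep("A", nrow(net$A)))
  W <- tcrossprod(B)
  idx <- which(lower.tri(W) & W > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(plant1 = character(), plant2 = character(),
                      weight = integer(), type = character()))
  type <- paste(pmin(g[idx[, 1]], g[idx[, 2]]),
                pmax(g[idx[, 1]], g[idx[, 2]]), sep = "-")
  type[type == "A-MH"] <- "MH-A"
  type[type == "MH-MH"] <- "MH-MH"
  data.frame(plant1 = rownames(B)[idx[, 1]],
             plant2 = rownames(B)[idx[, 2]],
             weight = as.integer(W[idx]),
             type = type)
}

#' Ecological similarity between fungi
#'
#' Pairwise similarity of fungi through their shared plants within one
#' incidence block. `jaccard` is shared plants over the union of plant
#' partners, `C_ij / (d_i + d_j - C_ij)`; `overlap` is shared plants over the
#' smaller partner set, `C_ij / min(d_i, d_j)`, which discounts differing
#' ceilings on partner number. Fungi with no plants in the block are excluded
#' (both formulas are 0/0 there) with a warning.
#'
#' @param incidence Binary plants x fungi matrix.
#' @param measure `"jaccard"` or `"overlap"`.
#' @return Symmetric similarity matrix (diagonal 1) over the retained fungi,
#'   with attribute `measure`.
#' @export
fungal_similarity <- function(incidence, measure = c("jaccard", "overlap")) {
  measure <- match.arg(measure)
  stopifnot(is.matrix(incidence))
  d <- colSums(incidence)
  if (any(d == 0L)) {
    warning("excluding ", sum(d == 0L), " zero-degree fungi from similarity")
    incidence <- incidence[, d > 0L, drop = FALSE]
    d <- d[d > 0L]
  }
  if (ncol(incidence) < 2L)
    stop("need at least two fungi with partners", call. = FALSE)
  C <- crossprod(incidence)
  s <- if (measure == "jaccard") C / (outer(d, d, `+`) - C)
       else C / outer(d, d, pmin)
  diag(s) <- 1
  attr(s, "measure") <- measure
  s
}

#' Restrict a network to fungi shared by both guilds
#'
#' Keeps only fungal columns present in the mycoheterotroph block AND the
#' autotroph block of the empirical network; plant rows left with no fungi
#' are dropped with a message.
#'
#' @param net A `tripartite_network`.
#' @return Restricted `tripartite_network`.
#' @export
restrict_to_shared_fungi <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  shared <- colSums(net$M) > 0L & colSums(net$A) > 0L
  if (!any(shared))
    stop("no fungi are shared between the two guilds", call. = FALSE)
  M <- net$M[, shared, drop = FALSE]
  A <- net$A[, shared, drop = FALSE]
  drop_m <- rowSums(M) == 0L
  drop_a <- rowSums(A) == 0L
  if (any(drop_m) || any(drop_a))
    message("restrict_to_shared_fungi: dropping plants with no shared fungi: ",
            paste(c(rownames(M)[drop_m], rownames(A)[drop_a]), collapse = ", "))
  M <- M[!drop_m, , drop = FALSE]
  A <- A[!drop_a, , drop = FALSE]
  if (nrow(M) == 0L || nrow(A) == 0L)
    stop("a guild lost all plants under the shared-fungi restriction",
         call. = FALSE)
  structure(list(M = M, A = A, fungi = colnames(M)),
            class = "tripartite_network")
}
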