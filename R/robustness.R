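# Coerce an analysis_fn result into a named numeric vector of metrics.
.as_metrics <- function(x) {
  if (inherits(x, "motif_null_test"))
    return(c(diamond_obs = x$observed, diamond_z = x$z, diamond_p = x$p,
             diamond_overrep = as.numeric(x$overrepresented)))
  if (inherits(x, "mantel_test"))
    return(c(mantel_r = x$r, mantel_p = x$p))
  if (is.list(x) && !is.null(names(x))) {
    out <- numeric(0)
    for (nm in names(x)) {
      v <- .as_metrics(x[[nm]])
      if (length(v) == 1L && is.null(names(v))) names(v) <- nm
      else names(v) <- paste(nm, names(v), sep = "_")
      out <- c(out, v)
    }
    return(out)
  }
  if (is.numeric(x) && (!is.null(names(x)) || length(x) == 1L)) return(x)
  stop("analysis_fn must return a named numeric vector or a result object",
       call. = FALSE)
}

.new_ensemble <- function(values_list, extra = list()) {
  reps <- seq_along(values_list)
  long <- do.call(rbind, lapply(reps, function(i) {
    v <- values_list[[i]]
    data.frame(replicate = i, metric = names(v), value = unname(v))
  }))
  agg_mean <- tapply(long$value, long$metric, mean, na.rm = TRUE)
  agg_sd <- tapply(long$value, long$metric, stats::sd, na.rm = TRUE)
  agg_sd[is.na(agg_sd)] <- 0
  summ <- data.frame(metric = names(agg_mean),
                     mean = as.numeric(agg_mean),
                     sd = as.numeric(agg_sd[names(agg_mean)]),
                     row.names = NULL)
  over <- summ$mean[grepl("overrep", summ$metric)]
  names(over) <- summ$metric[grepl("overrep", summ$metric)]
  out <- c(list(values = long, summary = summ,
                n_replicates = length(values_list),
                fraction_overrepresented = if (length(over)) over),
           extra)
  structure(out, class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("ensemble_summary over", x$n_replicates, "replicates\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$fraction_overrepresented)) {
    cat("fraction overrepresented:\n")
    print(x$fraction_overrepresented)
  }
  invisible(x)
}

# Rarefy + binarize one replicate and hand the network to analysis_fn.
.one_rarefied_network <- function(communities, depth) {
  rare <- rarefy_counts(communities, depth)
  tripartite_network(binarize(rare), communities$guild)
}

#' Rarefaction ensemble
#'
#' Draws `n_reps` independent rarefactions of the species communities to
#' `depth`, binarizes each, and applies `analysis_fn` to the resulting
#' tripartite network. Results are summarized as mean and SD per metric (and,
#' for motif tests, the fraction of replicates flagged overrepresented) —
#' the replication scheme behind every reported network statistic.
#'
#' @param communities A `species_communities` object.
#' @param depth Rarefaction depth (reads per species).
#' @param n_reps Number of replicate rarefactions.
#' @param analysis_fn Function of one argument (a `tripartite_network`)
#'   returning a named numeric vector, a `motif_null_test`, a `mantel_test`,
#'   or a named list of these.
#' @return An `ensemble_summary`: long per-replicate `values`, a `summary`
#'   table, and `fraction_overrepresented` when motif flags are present.
#' @export
rarefaction_ensemble <- function(communities, depth, n_reps, analysis_fn) {
  stopifnot(inherits(communities, "species_communities"), n_reps >= 1L)
  vals <- lapply(seq_len(n_reps), function(i)
    .as_metrics(analysis_fn(.one_rarefied_network(communities, depth))))
  .new_ensemble(vals, extra = list(depth = depth))
}

#' Per-species sample-resampling ensemble
#'
#' Quantifies sensitivity to uneven per-species sampling effort: each
#' replicate draws `k` samples per plant species without replacement
#' (species with fewer than `k` samples are discarded), pools them,
#' rarefies to the replicate's minimum species total so read depth stays
#' comparable within the replicate, binarizes, and applies `analysis_fn`.
#'
#' @param counts Sample x OTU matrix (after cell masking and sample
#'   filtering).
#' @param metadata Validated sample metadata covering the samples.
#' @param k Samples drawn per species.
#' @param n_reps Number of resampling replicates.
#' @param analysis_fn As in [rarefaction_ensemble()].
#' @return An `ensemble_summary`; each replicate's rarefaction depth is
#'   recorded in `depths`.
#' @export
sample_resampling_ensemble <- function(counts, metadata, k, n_reps,
                                       analysis_fn) {
  stopifnot(is.matrix(counts), k >= 1L, n_reps >= 1L)
  idx <- match(rownames(counts), metadata$sample_id)
  if (anyNA(idx)) stop("samples without metadata", call. = FALSE)
  sp <- metadata$species_id[idx]
  n_per <- table(sp)
  eligible <- names(n_per)[n_per >= k]
  if (length(eligible) == 0L)
    stop("no species has at least ", k, " samples", call. = FALSE)
  guild_of <- vapply(eligible, function(s)
    metadata$guild[metadata$species_id == s][1L], character(1))
  for (gl in .guild_levels)
    if (!any(guild_of == gl))
      stop("no ", gl, " species has at least ", k, " samples", call. = FALSE)
  depths <- integer(n_reps)
  vals <- lapply(seq_len(n_reps), function(i) {
    take <- unlist(lapply(eligible, function(s) {
      rows <- which(sp == s)
      rows[sample.int(length(rows), k)]
    }))
    sub <- counts[take, , drop = FALSE]
    comm <- aggregate_to_species(sub, metadata)
    depth <- min(rowSums(comm$counts))
    depths[i] <<- depth
    net <- .one_rarefied_network(comm, depth)
    .as_metrics(analysis_fn(net))
  })
  .new_ensemble(vals, extra = list(k = k, depths = depths,
                                   species_used = eligible))
}

#' Rarefaction-depth sweep
#'
#' Repeats [rarefaction_ensemble()] at each requested depth, to check that
#' conclusions (in particular the motif overrepresentation flag) are not
#' artifacts of the chosen sampling depth. Depths exceeding the smallest
#' species total are skipped with a warning.
#'
#' @param communities A `species_communities` object.
#' @param depths Integer vector of depths to test.
#' @param n_reps_per_depth Replicates per depth.
#' @param analysis_fn As in [rarefaction_ensemble()].
#' @return A list of class `depth_sweep`: `by_depth` (named list of
#'   `ensemble_summary`), and `conclusion_stable` (TRUE when every depth's
#'   majority overrepresentation call agrees; NA when no motif flag present).
#' @export
depth_sweep <- function(communities, depths, n_reps_per_depth, analysis_fn) {
  stopifnot(inherits(communities, "species_communities"))
  feasible <- depths <= min(rowSums(communities$counts))
  if (any(!feasible))
    warning("skipping infeasible depths: ",
            paste(depths[!feasible], collapse = ", "))
  depths <- depths[feasible]
  if (length(depths) == 0L) stop("no feasible depths", call. = FALSE)
  by_depth <- lapply(depths, function(d)
    rarefaction_ensemble(communities, d, n_reps_per_depth, analysis_fn))
  names(by_depth) <- as.character(depths)
  flags <- vapply(by_depth, function(e) {
    f <- e$fraction_overrepresented
    if (is.null(f)) NA_real_ else mean(f >= 0.5)
  }, numeric(1))
  stable <- if (all(is.na(flags))) NA else length(unique(flags[!is.na(flags)])) == 1L
  structure(list(by_depth = by_depth, depths = depths,
                 conclusion_stable = stable),
            class = "depth_sweep")
}
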