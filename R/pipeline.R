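#' Analyze one tripartite network
#'
#' Computes, on a single (typically rarefied) network, the full set of
#' descriptors the pipeline replicates across rarefactions: network sizes
#' (fungi overall, per block, and shared), guild-wise mean normalized degree
#' and phylogenetic species variability, Mantel phylogenetic-signal tests of
#' fungal and plant relatedness against interaction-profile dissimilarity,
#' cross-guild Mantel (and partial Mantel, controlling fungal relatedness)
#' correlations of fungal ecological similarity, and the diamond-module null
#' tests at the requested scopes. Components whose preconditions fail on a
#' given replicate (e.g. too few units for a Mantel test) are skipped.
#'
#' @param net A `tripartite_network`.
#' @param fungal_tree,plant_tree Optional `phylo` trees; enable the
#'   phylogenetic components.
#' @param n_null Null networks per motif test.
#' @param n_perm Mantel permutations.
#' @param scopes Motif-test scopes to run, subset of `c("all", "shared")`.
#' @return Named list mixing scalar metrics and result objects; suitable as
#'   `analysis_fn` output for the ensemble functions.
#' @export
analyze_network <- function(net, fungal_tree = NULL, plant_tree = NULL,
                            n_null = 1000L, n_perm = 999L,
                            scopes = c("all", "shared")) {
  stopifnot(inherits(net, "tripartite_network"))
  pres_m <- colSums(net$M) > 0L
  pres_a <- colSums(net$A) > 0L
  out <- list(
    n_fungi = sum(pres_m | pres_a),
    n_fungi_mut = sum(pres_a),
    n_fungi_ant = sum(pres_m),
    n_fungi_shared = sum(pres_m & pres_a),
    nd_auto_mean = mean(normalized_degree(net$A, "plants")),
    nd_mh_mean = mean(normalized_degree(net$M, "plants"))
  )

  try_mantel <- function(expr) tryCatch(suppressWarnings(expr),
                                        error = function(e) NULL)

  if (!is.null(fungal_tree)) {
    coph <- cophenetic_distances(fungal_tree)
    # phylogenetic signal: fungal relatedness vs interaction-profile
    # dissimilarity, per guild block
    for (blk in c(ant = "M", mut = "A")) {
      B <- net[[blk]]
      B <- B[, colSums(B) > 0L, drop = FALSE]
      f <- intersect(colnames(B), rownames(coph))
      if (length(f) >= 4L) {
        mt <- try_mantel(mantel_test(coph[f, f],
                                     jaccard_dissimilarity(B[, f, drop = FALSE],
                                                           "columns"),
                                     n_perm))
        nm <- if (blk == "M") "phylo_fungi_ant" else "phylo_fungi_mut"
        if (!is.null(mt)) out[[nm]] <- mt
      }
    }
    # mean psv of each guild's fungal communities
    Cfull <- ape::vcv(fungal_tree, corr = TRUE)
    psv_one <- function(row) {
      f <- names(row)[row > 0]
      f <- intersect(f, rownames(Cfull))
      n <- length(f)
      if (n < 2L) return(NA_real_)
      Cm <- Cfull[f, f]
      (n * sum(diag(Cm)) - sum(Cm)) / (n * (n - 1))
    }
    out$psv_auto_mean <- mean(apply(net$A, 1L, psv_one), na.rm = TRUE)
    out$psv_mh_mean <- mean(apply(net$M, 1L, psv_one), na.rm = TRUE)
  }

  if (!is.null(plant_tree)) {
    coph_p <- cophenetic_distances(plant_tree)
    for (blk in c(mh = "M", auto = "A")) {
      B <- net[[blk]]
      p <- intersect(rownames(B), rownames(coph_p))
      if (length(p) >= 4L) {
        mt <- try_mantel(mantel_test(coph_p[p, p],
                                     jaccard_dissimilarity(B[p, , drop = FALSE],
                                                           "rows"),
                                     n_perm))
        nm <- if (blk == "M") "phylo_plants_mh" else "phylo_plants_auto"
        if (!is.null(mt)) out[[nm]] <- mt
      }
    }
  }

  # cross-guild similarity of the shared fungi
  shared_ok <- tryCatch(restrict_to_shared_fungi(net), error = function(e) NULL)
  if (!is.null(shared_ok) && length(shared_ok$fungi) >= 4L) {
    for (meas in c("jaccard", "overlap")) {
      sM <- fungal_similarity(shared_ok$M, meas)
      sA <- fungal_similarity(shared_ok$A, meas)
      mt <- try_mantel(mantel_test(sA, sM, n_perm))
      if (!is.null(mt)) out[[paste0("sim_", meas)]] <- mt
      if (!is.null(fungal_tree)) {
        f <- intersect(shared_ok$fungi, fungal_tree$tip.label)
        if (length(f) == length(shared_ok$fungi)) {
          coph_s <- cophenetic_distances(fungal_tree)[f, f]
          pm <- try_mantel(partial_mantel_test(sA[f, f], sM[f, f], coph_s,
                                               n_perm))
          if (!is.null(pm)) out[[paste0("psim_", meas)]] <- pm
        }
      }
    }
  }

  for (sc in scopes) {
    res <- tryCatch(motif_null_test(net, scope = sc, n_null = n_null),
                    error = function(e) NULL)
    if (!is.null(res)) out[[paste0("motif_", sc)]] <- res
  }
  out
}

#' Run the full analysis end-to-end
#'
#' Preprocesses the sample-level count table (cell mask, sample filter,
#' species pooling, species filter), then replicates the network analysis
#' over `n_rarefactions` rarefied binary matrices, optionally followed by the
#' per-species sample-resampling ensemble and the rarefaction-depth sweep.
#' Every stage draws from a substream seeded deterministically from
#' `config$seed`, so a run is reproducible from its configuration alone.
#'
#' @param counts Sample x OTU integer matrix.
#' @param metadata Validated sample metadata.
#' @param fungal_tree,plant_tree Optional `phylo` trees.
#' @param config A [run_config()].
#' @return Object of class `run_report`: `config`, `stage_log`,
#'   `rarefaction` (ensemble), optional `resampling` and `depth_sweep`.
#' @export
run_full_analysis <- function(counts, metadata, fungal_tree = NULL,
                              plant_tree = NULL, config) {
  stopifnot(inherits(config, "run_config"))
  metadata <- validate_sample_metadata(metadata)
  scopes <- if (config$fungal_scope == "both") c("all", "shared")
            else config$fungal_scope
  analysis_fn <- function(net)
    analyze_network(net, fungal_tree, plant_tree,
                    n_null = config$n_null, n_perm = config$n_perm,
                    scopes = scopes)

  set.seed(config$seed)
  pre <- preprocess_counts(counts, metadata, config)
  comm <- pre$communities

  set.seed(config$seed + 1L)
  rar <- rarefaction_ensemble(comm, config$rarefy_depth,
                              config$n_rarefactions, analysis_fn)

  resamp <- NULL
  if (config$n_resamples > 0L) {
    set.seed(config$seed + 2L)
    masked <- mask_low_count_cells(counts, config$min_otu_reads)
    filt <- filter_samples(masked, config$min_sample_reads)
    resamp <- tryCatch(
      sample_resampling_ensemble(filt, metadata, config$resample_k,
                                 config$n_resamples, analysis_fn),
      error = function(e) {
        warning("resampling ensemble skipped: ", conditionMessage(e))
        NULL
      })
  }

  sweep <- NULL
  if (!is.null(config$depths) && length(config$depths)) {
    set.seed(config$seed + 3L)
    sweep <- depth_sweep(comm, config$depths,
                         max(1L, config$n_rarefactions %/% 5L), analysis_fn)
  }

  rep <- list(config = config, stage_log = pre$stage_log, rarefaction = rar)
  if (!is.null(resamp)) rep$resampling <- resamp
  if (!is.null(sweep)) rep$depth_sweep <- sweep
  structure(rep, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed", x$config$seed, ")\n\nstage log:\n")
  print(x$stage_log, row.names = FALSE)
  cat("\nrarefaction ensemble:\n")
  print(x$rarefaction)
  if (!is.null(x$resampling)) {
    cat("\nsample-resampling ensemble:\n"); print(x$resampling)
  }
  if (!is.null(x$depth_sweep)) {
    cat("\ndepth sweep over", paste(x$depth_sweep$depths, collapse = ", "),
        "- conclusion stable:", x$depth_sweep$conclusion_stable, "\n")
  }
  invisible(x)
}
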