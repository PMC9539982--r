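#' Mask low-count cells
#'
#' Sets every cell with fewer reads than `min_otu_reads` to zero, the standard
#' guard against tag-switching artifacts in amplicon tables. The rule acts per
#' cell, so an OTU legitimately abundant in one sample survives even if it
#' trickles into others. OTU columns left with no reads anywhere are dropped.
#'
#' @param counts Integer sample x OTU matrix.
#' @param min_otu_reads Cells with `0 < count < min_otu_reads` are zeroed.
#' @return Masked count matrix, possibly with fewer columns.
#' @export
mask_low_count_cells <- function(counts, min_otu_reads = 6L) {
  stopifnot(is.matrix(counts), min_otu_reads >= 1L)
  masked <- counts
  masked[masked > 0L & masked < min_otu_reads] <- 0L
  became_zero <- colSums(masked) == 0L & colSums(counts) > 0L
  if (any(became_zero))
    masked <- masked[, !became_zero, drop = FALSE]
  masked
}

#' Filter samples by read depth
#'
#' Keeps only samples whose total read count reaches `min_sample_reads`.
#'
#' @param counts Integer sample x OTU matrix.
#' @param min_sample_reads Samples with fewer total reads are removed.
#' @return Filtered matrix.
#' @export
filter_samples <- function(counts, min_sample_reads = 500L) {
  stopifnot(is.matrix(counts), min_sample_reads >= 1L)
  keep <- rowSums(counts) >= min_sample_reads
  if (!any(keep))
    stop("no samples remain after the ", min_sample_reads,
         "-read sample filter", call. = FALSE)
  counts[keep, , drop = FALSE]
}

#' Pool samples into per-species communities
#'
#' Sums read counts over all retained samples of each plant species, the
#' species-level community used by all downstream analyses.
#'
#' @param counts Integer sample x OTU matrix.
#' @param metadata Validated metadata (see [read_sample_metadata()]); every
#'   sample in `counts` must appear in it.
#' @return An object of class `species_communities`: a list with `counts`
#'   (species x OTU integer matrix), `guild` (named character vector) and
#'   `n_samples` (named integer vector).
#' @export
aggregate_to_species <- function(counts, metadata) {
  stopifnot(is.matrix(counts))
  idx <- match(rownames(counts), metadata$sample_id)
  if (anyNA(idx))
    stop("samples without metadata: ",
         paste(rownames(counts)[is.na(idx)], collapse = ", "), call. = FALSE)
  sp <- metadata$species_id[idx]
  pooled <- rowsum(counts, group = sp, reorder = FALSE)
  storage.mode(pooled) <- "integer"
  guild <- vapply(rownames(pooled), function(s)
    metadata$guild[metadata$species_id == s][1L], character(1))
  n_samples <- vapply(rownames(pooled), function(s) sum(sp == s), integer(1))
  structure(list(counts = pooled, guild = guild, n_samples = n_samples),
            class = "species_communities")
}

#' @export
print.species_communities <- function(x, ...) {
  cat("species_communities:", nrow(x$counts), "plant species x",
      ncol(x$counts), "fungal OTUs\n")
  cat("  autotrophs:", sum(x$guild == "autotroph"),
      " mycoheterotrophs:", sum(x$guild == "mycoheterotroph"), "\n")
  invisible(x)
}

#' Filter species by pooled read depth
#'
#' Removes plant species whose pooled read total falls below
#' `min_species_reads`; removals are reported by id. The pipeline needs both
#' guilds, so a guild losing all its species is an error.
#'
#' @param communities A `species_communities` object.
#' @param min_species_reads Threshold on pooled reads per species.
#' @return Filtered `species_communities`.
#' @export
filter_species <- function(communities, min_species_reads = 500L) {
  stopifnot(inherits(communities, "species_communities"),
            min_species_reads >= 1L)
  tot <- rowSums(communities$counts)
  keep <- tot >= min_species_reads
  if (any(!keep))
    message("filter_species: removed ", sum(!keep), " species (< ",
            min_species_reads, " reads): ",
            paste(names(tot)[!keep], collapse = ", "))
  g <- communities$guild[keep]
  for (gl in .guild_levels)
    if (!any(g == gl))
      stop("species filter removed every ", gl, " species", call. = FALSE)
  structure(list(counts = communities$counts[keep, , drop = FALSE],
                 guild = communities$guild[keep],
                 n_samples = communities$n_samples[keep]),
            class = "species_communities")
}

#' Rarefy species communities to a common depth
#'
#' Subsamples exactly `depth` reads per species without replacement
#' (multivariate hypergeometric), removing read-depth bias before
#' binarization. Every species total must reach `depth`; the draw itself is
#' delegated to [vegan::rrarefy()].
#'
#' @param x A `species_communities` object or an integer count matrix.
#' @param depth Reads to draw per row.
#' @return Same shape as the count matrix of `x`, every row summing to
#'   `depth`.
#' @export
rarefy_counts <- function(x, depth) {
  counts <- if (inherits(x, "species_communities")) x$counts else x
  stopifnot(is.matrix(counts), depth >= 1L)
  tot <- rowSums(counts)
  short <- tot < depth
  if (any(short))
    stop("species with fewer reads than the rarefaction depth ", depth, ": ",
         paste(names(tot)[short], collapse = ", "), call. = FALSE)
  # vegan warns when the smallest nonzero count exceeds 1, which is always
  # the case after the low-count cell mask; that warning is spurious here
  out <- withCallingHandlers(
    vegan::rrarefy(counts, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "integer"
  out
}

#' Binarize a count matrix to incidence
#'
#' Presence/absence is the appropriate resolution here: read abundance does
#' not track fungal abundance across root-sampling schemes, so only which
#' interactions exist is retained. All-zero OTU columns are dropped.
#'
#' @param counts Count (or already binary) matrix.
#' @return Binary integer matrix of the same rows, columns with at least one
#'   presence.
#' @export
binarize <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  b <- (counts > 0L) * 1L
  dimnames(b) <- dimnames(counts)
  b[, colSums(b) > 0L, drop = FALSE]
}

#' Run the fixed preprocessing chain
#'
#' Applies, in order: per-cell read mask, sample read filter, species pooling,
#' species read filter. The order matters (masking before the sample filter
#' changes which samples survive) and is fixed to the study design.
#'
#' @param counts Sample x OTU integer matrix.
#' @param metadata Validated sample metadata.
#' @param config A [run_config()].
#' @return A list with `communities` (filtered `species_communities`) and
#'   `stage_log` (data.frame of dimensions after each stage).
#' @export
preprocess_counts <- function(counts, metadata, config) {
  log_row <- function(stage, m) data.frame(stage = stage,
                                           n_rows = nrow(m), n_otus = ncol(m))
  masked <- mask_low_count_cells(counts, config$min_otu_reads)
  filt <- filter_samples(masked, config$min_sample_reads)
  comm <- aggregate_to_species(filt, metadata)
  comm <- filter_species(comm, config$min_species_reads)
  stage_log <- rbind(log_row("input", counts),
                     log_row("masked", masked),
                     log_row("sample_filtered", filt),
                     log_row("species_filtered", comm$counts))
  list(communities = comm, stage_log = stage_log)
}
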