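#' Read a sample x OTU read-count table
#'
#' Parses a tab-separated table whose header row holds OTU identifiers and
#' whose first column holds sample (or species) identifiers. All cells must be
#' nonnegative integers.
#'
#' @param path Path to a TSV file.
#' @return Integer matrix with sample ids as rownames and OTU ids as colnames.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("count table has an empty data section", call. = FALSE)
  row_ids <- df[[1L]]
  otu_ids <- colnames(df)[-1L]
  if (anyDuplicated(row_ids))
    stop("duplicate row ids in count table: ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU ids in count table", call. = FALSE)
  num <- suppressWarnings(vapply(df[-1L], as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(row_ids, otu_ids))
  if (anyNA(num) || any(num < 0) || any(num != round(num)))
    stop("count table cells must be nonnegative integers", call. = FALSE)
  storage.mode(num) <- "integer"
  num
}

#' Write a count table as TSV
#'
#' Inverse of [read_count_table()]: writing then reading returns an identical
#' matrix (ids and ordering preserved).
#'
#' @param x Integer matrix with dimnames.
#' @param path Output path.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.guild_levels <- c("autotroph", "mycoheterotroph")

#' Read sample metadata
#'
#' Requires columns `sample_id`, `species_id`, `guild`, `subplot`. Guild labels
#' are matched case-insensitively against `"autotroph"` and
#' `"mycoheterotroph"` and normalized to those canonical strings. A species
#' listed under both guilds is a validation error, as is a duplicated sample
#' id.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with the four validated columns.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  validate_sample_metadata(df)
}

#' Validate a metadata data.frame
#'
#' @param df data.frame with columns sample_id, species_id, guild, subplot.
#' @return The validated data.frame with canonical guild strings.
#' @export
validate_sample_metadata <- function(df) {
  need <- c("sample_id", "species_id", "guild", "subplot")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("metadata missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[, need]
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  g <- tolower(trimws(df$guild))
  bad <- setdiff(unique(g), .guild_levels)
  if (length(bad))
    stop("unknown guild value(s): ", paste(bad, collapse = ", "),
         "; expected autotroph or mycoheterotroph", call. = FALSE)
  df$guild <- g
  mixed <- tapply(df$guild, df$species_id, function(v) length(unique(v)) > 1L)
  if (any(mixed))
    stop("species with inconsistent guild: ",
         paste(names(mixed)[mixed], collapse = ", "), call. = FALSE)
  df
}

#' Write sample metadata as TSV
#' @param df Validated metadata data.frame.
#' @param path Output path.
#' @export
write_sample_metadata <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phylogenetic tree from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contracts the
#' downstream analyses rely on: unique tip labels and nonnegative branch
#' lengths present on every edge.
#'
#' @param path Path to a Newick file.
#' @return An object of class `phylo`.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path, call. = FALSE)
  validate_tree(tr)
}

#' @rdname read_newick
#' @param tree A `phylo` object to validate.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in tree", call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree is missing branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths", call. = FALSE)
  tree
}

#' Run configuration
#'
#' Bundles every tunable parameter of the pipeline. The defaults are the
#' study-design values for this kind of root-tip OTU survey: a 6-read
#' per-cell mask against tag switching, 500-read sample and species filters,
#' rarefaction to 844 reads over 100 replicate draws, 1000 null networks, and
#' resampling of 3 samples per species.
#'
#' @param seed Integer seed; required, all randomness derives from it.
#' @param min_otu_reads Per-cell read mask threshold (reads).
#' @param min_sample_reads Minimum reads for a sample to be retained.
#' @param min_species_reads Minimum pooled reads for a species to be retained.
#' @param rarefy_depth Reads drawn per species in each rarefaction.
#' @param n_rarefactions Number of rarefied replicate matrices.
#' @param n_null Number of null networks per motif test.
#' @param n_perm Number of Mantel permutations.
#' @param fungal_scope `"all"`, `"shared"`, or `"both"` motif-test scopes.
#' @param depths Optional integer vector of rarefaction depths for the sweep.
#' @param resample_k Samples drawn per species in the resampling ensemble.
#' @param n_resamples Number of resampling replicates (0 disables).
#' @param out_dir Output directory for [write_results()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed,
                       min_otu_reads = 6L,
                       min_sample_reads = 500L,
                       min_species_reads = 500L,
                       rarefy_depth = 844L,
                       n_rarefactions = 100L,
                       n_null = 1000L,
                       n_perm = 999L,
                       fungal_scope = c("both", "all", "shared"),
                       depths = NULL,
                       resample_k = 3L,
                       n_resamples = 0L,
                       out_dir = NULL) {
  fungal_scope <- match.arg(fungal_scope)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("run_config() requires an explicit integer seed", call. = FALSE)
  cfg <- list(seed = as.integer(seed),
              min_otu_reads = as.integer(min_otu_reads),
              min_sample_reads = as.integer(min_sample_reads),
              min_species_reads = as.integer(min_species_reads),
              rarefy_depth = as.integer(rarefy_depth),
              n_rarefactions = as.integer(n_rarefactions),
              n_null = as.integer(n_null),
              n_perm = as.integer(n_perm),
              fungal_scope = fungal_scope,
              depths = if (!is.null(depths)) as.integer(depths),
              resample_k = as.integer(resample_k),
              n_resamples = as.integer(n_resamples),
              out_dir = out_dir)
  pos <- c("min_otu_reads", "min_sample_reads", "min_species_reads",
           "rarefy_depth", "n_rarefactions", "n_null", "n_perm", "resample_k")
  for (p in pos)
    if (cfg[[p]] < 1L) stop(p, " must be a positive integer", call. = FALSE)
  if (!is.null(cfg$depths) && any(cfg$depths < 1L))
    stop("depths must be positive integers", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Write analysis results to disk
#'
#' Writes a structured JSON summary (`results.json`, schema-versioned, echoing
#' the seed and configuration) plus per-replicate TSV tables for every
#' ensemble in the report.
#'
#' @param report A `run_report` from [run_full_analysis()], or any list of
#'   result objects with a `$config` entry.
#' @param dir Output directory (created if absent).
#' @param overwrite Refuse to clobber an existing `results.json` unless TRUE.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(report, dir, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  main <- file.path(dir, "results.json")
  if (file.exists(main) && !overwrite)
    stop("results.json already exists in ", dir,
         " (use overwrite = TRUE)", call. = FALSE)
  paths <- main

  summarize_obj <- function(x) {
    if (inherits(x, "motif_null_test")) {
      list(scope = x$scope, observed = x$observed, null_mean = x$null_mean,
           null_sd = x$null_sd, z = x$z, p = x$p,
           ci_low = x$ci_low, ci_high = x$ci_high,
           overrepresented = x$overrepresented, n_null = x$n_null)
    } else if (inherits(x, "ensemble_summary")) {
      list(n_replicates = x$n_replicates, summary = x$summary)
    } else if (inherits(x, "mantel_test")) {
      list(r = x$r, p = x$p, n_perm = x$n_perm, partial = x$partial)
    } else x
  }
  payload <- list(
    schema_version = "1.0",
    package = "mycomotif",
    r_version = as.character(getRversion()),
    config = unclass(report$config),
    results = lapply(report[setdiff(names(report), "config")], function(x) {
      if (is.list(x) && !is.data.frame(x) && is.null(attr(x, "class")))
        lapply(x, summarize_obj)
      else summarize_obj(x)
    })
  )
  jsonlite::write_json(payload, main, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)

  write_ens <- function(x, nm) {
    if (inherits(x, "ensemble_summary") && !is.null(x$values)) {
      p <- file.path(dir, paste0(nm, "_replicates.tsv"))
      utils::write.table(x$values, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <<- c(paths, p)
    }
  }
  for (nm in setdiff(names(report), "config")) {
    x <- report[[nm]]
    if (inherits(x, "ensemble_summary")) write_ens(x, nm)
    else if (is.list(x) && !is.data.frame(x))
      for (nm2 in names(x)) write_ens(x[[nm2]], paste(nm, nm2, sep = "_"))
  }
  invisible(paths)
}
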