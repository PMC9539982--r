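#' Simulation configuration
#'
#' Parameters of the synthetic tripartite dataset generator. Defaults emulate
#' the shape of a root-tip OTU survey of a species-rich AM community: 21
#' autotrophic and 5 mycoheterotrophic plant species, 115 fungal OTUs, 1-9
#' samples per species, and lognormal per-sample read totals floored well
#' above the sample read filter so every species pool also clears the default
#' rarefaction depth.
#'
#' @param seed Integer seed (required).
#' @param n_auto,n_mh,n_fungi Numbers of autotroph species, mycoheterotroph
#'   species and fungal OTUs.
#' @param samples_range Integer range (min, max) of samples per species.
#' @param read_meanlog,read_sdlog Lognormal parameters of per-sample read
#'   totals.
#' @param read_min Floor on per-sample read totals (reads).
#' @param heterogeneity Spread (logit scale) of fungal attachment scores;
#'   larger values give more skewed fungal degree distributions.
#' @param gamma Mycoheterotroph preference exponent: MH attachment
#'   probability scales with (expected autotroph degree)^gamma. 0 =
#'   degree-independent attachment.
#' @param phylo_signal Fraction (0-1) of fungal attachment-score variance
#'   explained by a Brownian trait on the fungal tree.
#' @param base_fill_auto,base_fill_mh Baseline interaction probabilities of
#'   the autotroph and mycoheterotroph blocks.
#' @param dirichlet_alpha Symmetric Dirichlet concentration distributing a
#'   sample's reads over its realized fungi (small = skewed read counts).
#' @param stress When TRUE, a fraction of samples get sub-filter read totals
#'   so the preprocessing filters have something to reject.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_auto = 21L, n_mh = 5L, n_fungi = 115L,
                       samples_range = c(1L, 9L),
                       read_meanlog = log(3000), read_sdlog = 0.5,
                       read_min = 1200L,
                       heterogeneity = 1.5,
                       gamma = 1,
                       phylo_signal = 0.5,
                       base_fill_auto = 0.15,
                       base_fill_mh = 0.30,
                       dirichlet_alpha = 0.3,
                       stress = FALSE) {
  if (missing(seed)) stop("sim_config() requires an explicit seed",
                          call. = FALSE)
  stopifnot(n_auto >= 1L, n_mh >= 1L, n_fungi >= 2L,
            samples_range[1] >= 1L, samples_range[2] >= samples_range[1],
            gamma >= 0, phylo_signal >= 0, phylo_signal <= 1,
            base_fill_auto > 0, base_fill_auto < 1,
            base_fill_mh > 0, base_fill_mh < 1)
  structure(list(seed = as.integer(seed), n_auto = as.integer(n_auto),
                 n_mh = as.integer(n_mh), n_fungi = as.integer(n_fungi),
                 samples_range = as.integer(samples_range),
                 read_meanlog = read_meanlog, read_sdlog = read_sdlog,
                 read_min = as.integer(read_min),
                 heterogeneity = heterogeneity, gamma = gamma,
                 phylo_signal = phylo_signal,
                 base_fill_auto = base_fill_auto,
                 base_fill_mh = base_fill_mh,
                 dirichlet_alpha = dirichlet_alpha,
                 stress = isTRUE(stress)),
            class = "sim_config")
}

#' Generate a random phylogenetic tree
#'
#' Random binary topology (sequential random joins, via [ape::rtree()]) with
#' independent exponential branch lengths; tips relabeled deterministically
#' `prefix1 ... prefixN`. Draws from the current RNG stream.
#'
#' @param n_tips Number of tips (>= 2).
#' @param prefix Tip-label prefix.
#' @return A `phylo` tree.
#' @export
generate_tree <- function(n_tips, prefix = "t") {
  stopifnot(n_tips >= 2L)
  tr <- ape::rtree(n_tips, br = function(n) stats::rexp(n, rate = 1))
  tr$tip.label <- paste0(prefix, seq_len(n_tips))
  tr
}

#' Generate guild-specific interaction probability matrices
#'
#' Each fungus carries a latent attachment score mixing a Brownian trait
#' evolved on the fungal tree (weight `phylo_signal`) with an independent
#' component; autotroph-fungus probabilities are a logistic function of that
#' score plus a plant effect, so closely related fungi get similar partner
#' profiles when the signal is strong. Mycoheterotroph-fungus probabilities
#' scale with the fungus's expected autotroph degree raised to `gamma` (the
#' keystone-preference knob); `gamma = 0` makes mycoheterotroph attachment
#' independent of fungal connectedness.
#'
#' @param config A `sim_config`.
#' @param fungal_tree Fungal tree with `config$n_fungi` tips.
#' @return List with `P_auto` (`n_auto x n_fungi`) and `P_mh`
#'   (`n_mh x n_fungi`) probability matrices.
#' @export
generate_interactions <- function(config, fungal_tree) {
  stopifnot(inherits(config, "sim_config"),
            length(fungal_tree$tip.label) == config$n_fungi)
  fungi <- fungal_tree$tip.label
  trait <- ape::rTraitCont(fungal_tree, model = "BM", sigma = 1)[fungi]
  trait <- as.numeric(scale(trait))
  noise <- stats::rnorm(config$n_fungi)
  s <- sqrt(config$phylo_signal) * trait +
       sqrt(1 - config$phylo_signal) * noise
  s <- config$heterogeneity * s
  auto_ids <- sprintf("auto%02d", seq_len(config$n_auto))
  mh_ids <- sprintf("mh%d", seq_len(config$n_mh))
  row_eff <- stats::rnorm(config$n_auto, 0, 0.5)
  P_auto <- stats::plogis(stats::qlogis(config$base_fill_auto) +
                          outer(row_eff, s, `+`))
  dimnames(P_auto) <- list(auto_ids, fungi)
  e_deg <- colSums(P_auto)
  w <- (e_deg / mean(e_deg))^config$gamma
  mh_eff <- exp(stats::rnorm(config$n_mh, 0, 0.3))
  P_mh <- pmin(config$base_fill_mh * outer(mh_eff, w), 0.95)
  dimnames(P_mh) <- list(mh_ids, fungi)
  list(P_auto = P_auto, P_mh = P_mh)
}

# One sample's fungal read vector: Bernoulli incidence from the species'
# probability row, then reads spread over realized fungi by a symmetric
# Dirichlet-weighted multinomial. Every realized fungus gets at least one
# read, so read-level incidence reproduces the probability matrix exactly.
.sample_reads <- function(p_row, n_reads, alpha) {
  inc <- which(stats::runif(length(p_row)) < p_row)
  if (length(inc) == 0L) inc <- which.max(p_row)
  if (length(inc) > n_reads) inc <- sample(inc, n_reads)
  w <- stats::rgamma(length(inc), shape = alpha)
  w[w == 0 | !is.finite(w)] <- .Machine$double.xmin
  out <- integer(length(p_row))
  out[inc] <- 1L + as.integer(stats::rmultinom(1, n_reads - length(inc),
                                               prob = w))
  out
}

#' Generate a full synthetic dataset
#'
#' Builds fungal and plant trees, guild-specific interaction probabilities,
#' per-sample read-count rows and sample metadata, bundled with the
#' ground-truth probabilities for recovery tests. Seeded from
#' `config$seed`.
#'
#' @param config A `sim_config`.
#' @return Object of class `synthetic_dataset` with elements `counts`
#'   (sample x OTU matrix), `metadata`, `fungal_tree`, `plant_tree`,
#'   `P_auto`, `P_mh`, `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fungal_tree <- generate_tree(config$n_fungi, "f")
  n_plants <- config$n_auto + config$n_mh
  plant_tree <- generate_tree(n_plants, "p")
  probs <- generate_interactions(config, fungal_tree)
  species <- c(rownames(probs$P_auto), rownames(probs$P_mh))
  plant_tree$tip.label <- species[sample.int(n_plants)]
  guild <- c(rep("autotroph", config$n_auto),
             rep("mycoheterotroph", config$n_mh))
  names(guild) <- species
  P <- rbind(probs$P_auto, probs$P_mh)

  n_samp <- sample(seq(config$samples_range[1], config$samples_range[2]),
                   n_plants, replace = TRUE)
  rows <- list(); ids <- character(0); meta <- list()
  k <- 0L
  for (i in seq_len(n_plants)) {
    for (j in seq_len(n_samp[i])) {
      k <- k + 1L
      n_reads <- max(config$read_min,
                     round(stats::rlnorm(1, config$read_meanlog,
                                         config$read_sdlog)))
      if (config$stress && stats::runif(1) < 0.15)
        n_reads <- sample(50:400, 1)
      rows[[k]] <- .sample_reads(P[i, ], n_reads, config$dirichlet_alpha)
      ids[k] <- sprintf("s%03d", k)
      meta[[k]] <- data.frame(sample_id = ids[k], species_id = species[i],
                              guild = guild[i],
                              subplot = sample(c("P1", "P2"), 1))
    }
  }
  counts <- do.call(rbind, rows)
  dimnames(counts) <- list(ids, colnames(P))
  storage.mode(counts) <- "integer"
  metadata <- do.call(rbind, meta)
  structure(list(counts = counts, metadata = metadata,
                 fungal_tree = fungal_tree, plant_tree = plant_tree,
                 P_auto = probs$P_auto, P_mh = probs$P_mh, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$counts), "samples x", ncol(x$counts),
      "OTUs;", x$config$n_auto, "autotrophs,", x$config$n_mh,
      "mycoheterotrophs; gamma =", x$config$gamma, "\n")
  invisible(x)
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' Emits `counts.tsv`, `samples.tsv`, `fungi.nwk`, `plants.nwk` — byte-for-
#' byte the formats [read_count_table()], [read_sample_metadata()] and
#' [read_newick()] consume.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the four paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- file.path(dir, c("counts.tsv", "samples.tsv", "fungi.nwk",
                        "plants.nwk"))
  write_count_table(dataset$counts, p[1])
  write_sample_metadata(dataset$metadata, p[2])
  ape::write.tree(dataset$fungal_tree, p[3])
  ape::write.tree(dataset$plant_tree, p[4])
  invisible(p)
}

#' Draw a network exactly from the motif null model
#'
#' Convenience wrapper over [randomize_tripartite()] producing a network
#' whose true generating process is the degree-proportional null of `net` —
#' the ingredient of calibration tests, where the motif test applied to such
#' draws should flag overrepresentation at its nominal rate.
#'
#' @param net Template `tripartite_network`.
#' @param max_retries Redraw cap per block.
#' @return A `tripartite_network` drawn from the null model of `net`.
#' @export
generate_null_conditioned <- function(net, max_retries = 1000L) {
  randomize_tripartite(net, max_retries)
}
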