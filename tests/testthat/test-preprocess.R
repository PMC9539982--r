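make_counts <- function(m, samples, otus) {
  storage.mode(m) <- "integer"
  dimnames(m) <- list(samples, otus)
  m
}

test_that("cell mask zeroes sub-threshold cells and drops emptied OTUs", {
  # f1 survives via s2, so masking s1's 5 reads only zeroes that cell
  m <- make_counts(rbind(c(5L, 6L, 0L), c(10L, 0L, 8L)), c("s1", "s2"),
                   paste0("f", 1:3))
  out <- mask_low_count_cells(m, 6L)
  expect_identical(unname(out["s1", ]), c(0L, 6L, 0L))
  expect_identical(unname(out["s2", ]), c(10L, 0L, 8L))

  # an OTU emptied by the mask is dropped
  single <- make_counts(rbind(c(5L, 6L)), "s1", c("f1", "f2"))
  expect_identical(colnames(mask_low_count_cells(single, 6L)), "f2")

  m2 <- make_counts(matrix(c(1L, 9L, 3L, 4L), 2), c("s1", "s2"),
                    c("f1", "f2"))
  expect_identical(mask_low_count_cells(m2, 1L), m2)

  all_low <- make_counts(matrix(c(2L, 3L), 1), "s1", c("f1", "f2"))
  out3 <- mask_low_count_cells(all_low, 6L)
  expect_identical(ncol(out3), 0L)
})

test_that("sample filter applies the strict < threshold boundary", {
  m <- make_counts(matrix(c(499L, 500L, 0L, 0L), 2), c("s1", "s2"),
                   c("f1", "f2"))
  out <- filter_samples(m, 500L)
  expect_identical(rownames(out), "s2")

  pos <- make_counts(matrix(1L, 3, 2), paste0("s", 1:3), c("f1", "f2"))
  expect_identical(filter_samples(pos, 1L), pos)

  zero <- make_counts(matrix(0L, 2, 2), c("s1", "s2"), c("f1", "f2"))
  expect_error(filter_samples(zero, 1L), "no samples remain")
})

test_that("species aggregation sums sample counts and records n_samples", {
  m <- make_counts(rbind(c(1L, 0L), c(2L, 3L), c(4L, 4L)),
                   c("s1", "s2", "s3"), c("f1", "f2"))
  md <- data.frame(sample_id = c("s1", "s2", "s3"),
                   species_id = c("spA", "spA", "spB"),
                   guild = c("autotroph", "autotroph", "mycoheterotroph"),
                   subplot = "P1")
  comm <- aggregate_to_species(m, md)
  expect_identical(comm$counts["spA", ], c(f1 = 3L, f2 = 3L))
  expect_identical(comm$n_samples[["spA"]], 2L)
  expect_identical(comm$counts["spB", ], c(f1 = 4L, f2 = 4L))
  expect_identical(comm$guild[["spB"]], "mycoheterotroph")

  # brute-force summation oracle on a random 3-sample toy
  set.seed(4)
  m3 <- make_counts(matrix(rpois(12, 10), 3, 4), paste0("s", 1:3),
                    paste0("f", 1:4))
  md3 <- data.frame(sample_id = paste0("s", 1:3), species_id = "spX",
                    guild = "autotroph", subplot = "P1")
  agg <- aggregate_to_species(m3, md3)
  expect_equal(unname(agg$counts["spX", ]), unname(colSums(m3)))

  expect_error(aggregate_to_species(
    make_counts(matrix(1L, 1, 2), "sX", c("f1", "f2")), md),
    "without metadata")
})

test_that("species filter removes low-read species and protects both guilds", {
  counts <- matrix(0L, 3, 2,
                   dimnames = list(c("a1", "a2", "m1"), c("f1", "f2")))
  counts["a1", ] <- c(800L, 44L)   # 844 total
  counts["a2", ] <- c(400L, 99L)   # 499 total
  counts["m1", ] <- c(300L, 300L)
  comm <- toy_communities(counts, c(a1 = "autotroph", a2 = "autotroph",
                                    m1 = "mycoheterotroph"))
  expect_message(out <- filter_species(comm, 500L), "a2")
  expect_setequal(rownames(out$counts), c("a1", "m1"))

  expect_identical(filter_species(comm, 1L)$counts, comm$counts)

  expect_error(filter_species(comm, 700L), "mycoheterotroph")
})

test_that("rarefaction conserves depth, never exceeds source cells, matches hypergeometric moments", {
  counts <- matrix(c(600L, 244L, 0L, 500L, 300L, 100L), 2, 3, byrow = TRUE,
                   dimnames = list(c("sp1", "sp2"), paste0("f", 1:3)))
  set.seed(9)
  r <- rarefy_counts(counts, 300L)
  expect_true(all(rowSums(r) == 300L))
  expect_true(all(r <= counts))

  # depth equal to a species total leaves that species' counts unchanged
  set.seed(9)
  expect_identical(rarefy_counts(counts, 844L)["sp1", ],
                   counts["sp1", ])

  expect_error(rarefy_counts(counts, 1000L), "sp2")

  # hypergeometric mean: E[count] = c*d/N over 10,000 independent draws
  one <- matrix(rep(c(120L, 60L, 20L), each = 1), 1, 3,
                dimnames = list("sp", paste0("f", 1:3)))
  many <- one[rep(1, 10000), ]
  rownames(many) <- paste0("r", 1:10000)
  set.seed(10)
  draws <- rarefy_counts(many, 50L)
  expected <- c(120, 60, 20) * 50 / 200
  n <- 200; d <- 50
  se <- sqrt(d * (c(120, 60, 20) / n) * (1 - c(120, 60, 20) / n) *
               (n - d) / (n - 1) / 10000)
  expect_true(all(abs(colMeans(draws) - expected) < 3 * se))
})

test_that("binarization thresholds presence and drops empty OTUs", {
  m <- matrix(c(0L, 7L, 844L), 1, dimnames = list("sp", paste0("f", 1:3)))
  b <- binarize(m)
  expect_identical(unname(b), rbind(c(1L, 1L)))
  expect_identical(colnames(b), c("f2", "f3"))
  expect_identical(binarize(b), b)
})

test_that("the preprocessing chain runs in the fixed order on a fixture", {
  # sample s2 only survives the 10-read sample filter because masking is
  # applied first: its 12 raw reads drop to 9 after the 5-read cell mask
  m <- matrix(c(9L, 3L, 20L, 0L, 0L, 30L), 3, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("f1", "f2")))
  md <- data.frame(sample_id = c("s1", "s2", "s3"),
                   species_id = c("spA", "spA", "spB"),
                   guild = c("autotroph", "autotroph", "mycoheterotroph"),
                   subplot = "P1")
  cfg <- run_config(seed = 1, min_otu_reads = 5L, min_sample_reads = 10L,
                    min_species_reads = 10L)
  pre <- preprocess_counts(m, md, cfg)
  expect_identical(pre$stage_log$stage,
                   c("input", "masked", "sample_filtered",
                     "species_filtered"))
  # masking (3 -> 0) leaves s1 at 9 reads, below the sample filter
  expect_identical(unname(pre$communities$counts["spA", ]), c(20L, 0L))
  # masking after filtering would instead have kept s1 (12 raw reads)
  filt_first <- filter_samples(m, 10L)
  expect_true("s1" %in% rownames(filt_first))
})
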