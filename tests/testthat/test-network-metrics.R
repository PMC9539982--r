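test_that("normalized degree is partners over possible partners", {
  set.seed(2)
  net <- rand_net(2, 3, 110, 0.5)
  inc <- rbind(net$M, net$A)
  inc["mh1", ] <- c(rep(1L, 55), rep(0L, 55))
  expect_equal(normalized_degree(inc, "plants")[["mh1"]], 0.5)
  inc["auto1", ] <- 1L
  expect_equal(normalized_degree(inc, "plants")[["auto1"]], 1.0)
  expect_equal(unname(normalized_degree(inc, "fungi")),
               unname(colSums(inc) / nrow(inc)))
  # conservation: degrees scaled back up sum to total links
  expect_equal(sum(normalized_degree(inc, "plants")) * ncol(inc), sum(inc))
})

test_that("psv hits its closed forms and matches the path-length oracle", {
  # star tree, equal branch lengths: all off-diagonal correlations 0
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(psv(c("A", "B", "C", "D"), star)$psv, 1)

  # two tips with zero-length terminals under a shared stem: correlation 1
  cherry <- ape::read.tree(text = "((A:0,B:0):1,C:2);")
  expect_equal(psv(c("A", "B"), cherry)$psv, 0)

  # arbitrary random trees match the direct 1 - mean-correlation oracle
  for (seed in 1:5) {
    set.seed(seed)
    tr <- ape::rtree(6, br = function(n) runif(n, 0.1, 2))
    comm <- sample(tr$tip.label, 4)
    expect_equal(psv(comm, tr)$psv, psv_oracle(comm, tr), tolerance = 1e-10)
  }

  # cross-check against the community-phylogenetics reference implementation
  set.seed(42)
  tr <- ape::rcoal(8)
  comm1 <- tr$tip.label[1:5]
  comm2 <- tr$tip.label[4:8]
  samp <- rbind(c1 = as.integer(tr$tip.label %in% comm1),
                c2 = as.integer(tr$tip.label %in% comm2))
  colnames(samp) <- tr$tip.label
  ref <- picante::psv(samp, tr)$PSVs
  expect_equal(psv(comm1, tr)$psv, ref[[1]], tolerance = 1e-10)
  expect_equal(psv(comm2, tr)$psv, ref[[2]], tolerance = 1e-10)

  # invariance under tip relabeling and uniform branch scaling
  set.seed(7)
  tr <- ape::rtree(7, br = function(n) runif(n, 0.5, 1.5))
  comm <- sample(tr$tip.label, 4)
  v1 <- psv(comm, tr)$psv
  relabel <- stats::setNames(paste0("x", seq_along(tr$tip.label)),
                             tr$tip.label)
  tr2 <- tr; tr2$tip.label <- unname(relabel[tr$tip.label])
  expect_equal(psv(unname(relabel[comm]), tr2)$psv, v1)
  tr3 <- tr; tr3$edge.length <- tr$edge.length * 13.7
  expect_equal(psv(comm, tr3)$psv, v1)

  expect_warning(res <- psv("A", star), "fewer than 2")
  expect_true(is.na(res$psv))
  expect_error(psv(c("A", "ZZZ"), star), "absent from tree")
})

test_that("plant-plant overlap equals brute-force set intersections", {
  inc <- rbind(mh1 = c(1L, 1L, 1L, 0L), auto1 = c(0L, 1L, 1L, 0L),
               auto2 = c(0L, 0L, 0L, 1L))
  colnames(inc) <- paste0("f", 1:4)
  net <- tripartite_network(inc, c(mh1 = "mycoheterotroph",
                                   auto1 = "autotroph",
                                   auto2 = "autotroph"))
  ov <- plant_plant_overlap(net)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$weight, 2L)
  expect_equal(ov$type, "MH-A")

  set.seed(6)
  net8 <- rand_net(3, 5, 12, 0.4)
  ov8 <- plant_plant_overlap(net8)
  inc8 <- rbind(net8$M, net8$A)
  for (r in seq_len(nrow(ov8))) {
    s1 <- which(inc8[ov8$plant1[r], ] == 1L)
    s2 <- which(inc8[ov8$plant2[r], ] == 1L)
    expect_identical(ov8$weight[r], length(intersect(s1, s2)))
  }
  # zero-weight pairs omitted
  expect_true(all(ov8$weight > 0L))
})

test_that("fungal similarity formulas and overlap >= jaccard dominance", {
  # fungi with plant sets {A,B} and {B,C,D}
  inc <- rbind(A = c(1L, 0L), B = c(1L, 1L), C = c(0L, 1L), D = c(0L, 1L))
  colnames(inc) <- c("f1", "f2")
  expect_equal(fungal_similarity(inc, "jaccard")["f1", "f2"], 0.25)
  expect_equal(fungal_similarity(inc, "overlap")["f1", "f2"], 0.5)

  ident <- cbind(f1 = c(1L, 1L, 0L), f2 = c(1L, 1L, 0L))
  rownames(ident) <- c("A", "B", "C")
  expect_equal(fungal_similarity(ident, "jaccard")["f1", "f2"], 1)
  expect_equal(fungal_similarity(ident, "overlap")["f1", "f2"], 1)

  disj <- cbind(f1 = c(1L, 0L), f2 = c(0L, 1L))
  rownames(disj) <- c("A", "B")
  expect_equal(fungal_similarity(disj, "jaccard")["f1", "f2"], 0)
  expect_equal(fungal_similarity(disj, "overlap")["f1", "f2"], 0)

  for (seed in 1:20) {
    set.seed(seed)
    inc <- matrix(rbinom(8 * 10, 1L, 0.4), 8, 10,
                  dimnames = list(paste0("p", 1:8), paste0("f", 1:10)))
    inc <- inc[, colSums(inc) > 0, drop = FALSE]
    sj <- fungal_similarity(inc, "jaccard")
    so <- fungal_similarity(inc, "overlap")
    expect_true(all(so - sj >= -1e-12))
    expect_true(all(sj >= 0 & sj <= 1) && all(so >= 0 & so <= 1))
    expect_equal(sj, t(sj))
  }

  with_zero <- cbind(f1 = c(1L, 1L), f2 = c(0L, 0L), f3 = c(1L, 0L))
  rownames(with_zero) <- c("A", "B")
  expect_warning(s <- fungal_similarity(with_zero, "jaccard"), "zero-degree")
  expect_false("f2" %in% colnames(s))
  degenerate <- cbind(f1 = c(1L, 0L), f2 = c(0L, 0L))
  rownames(degenerate) <- c("A", "B")
  expect_error(suppressWarnings(fungal_similarity(degenerate, "jaccard")),
               "at least two")
})

test_that("shared-fungi restriction keeps exactly the guild-intersection columns", {
  inc <- rbind(mh1 = c(1L, 1L, 0L, 0L), mh2 = c(1L, 0L, 0L, 0L),
               auto1 = c(1L, 0L, 1L, 0L), auto2 = c(0L, 0L, 1L, 1L))
  colnames(inc) <- paste0("f", 1:4)
  guild <- c(mh1 = "mycoheterotroph", mh2 = "mycoheterotroph",
             auto1 = "autotroph", auto2 = "autotroph")
  net <- tripartite_network(inc, guild)
  expect_message(shared <- restrict_to_shared_fungi(net), "auto2")
  expect_identical(shared$fungi, "f1")
  expect_false("auto2" %in% rownames(shared$A))

  set.seed(12)
  for (i in 1:10) {
    net <- rand_net(3, 4, 15, 0.3)
    shared <- tryCatch(suppressMessages(restrict_to_shared_fungi(net)),
                       error = function(e) NULL)
    want <- colnames(net$M)[colSums(net$M) > 0 & colSums(net$A) > 0]
    if (is.null(shared)) expect_length(want, 0)
    else expect_identical(shared$fungi, want)
  }

  inc2 <- rbind(mh1 = c(1L, 0L), auto1 = c(0L, 1L))
  colnames(inc2) <- c("f1", "f2")
  disjoint <- tripartite_network(inc2, c(mh1 = "mycoheterotroph",
                                         auto1 = "autotroph"))
  expect_error(restrict_to_shared_fungi(disjoint), "no fungi are shared")
})
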