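# Neighbour joining, bootstrap support, monophyly.

test_that("three taxa solve the closed-form star equations", {
  d <- matrix(c(0, 0.2, 0.3,
                0.2, 0, 0.5,
                0.3, 0.5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  phy <- nj_tree(d)
  # la = (dab + dac - dbc)/2, etc.
  len <- structure(phy$edge.length,
                   names = phy$tip.label[phy$edge[, 2]])
  expect_equal(unname(len["a"]), 0)
  expect_equal(unname(len["b"]), 0.2)
  expect_equal(unname(len["c"]), 0.3)
})

test_that("NJ recovers additive trees exactly (topology and path lengths)", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
    true <- ape::unroot(true)
    d <- ape::cophenetic.phylo(true)
    d <- d[order(rownames(d)), order(colnames(d))]
    est <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(est), true), 0,
                 ignore_attr = TRUE)
    dd <- ape::cophenetic.phylo(est)[rownames(d), colnames(d)]
    expect_lt(max(abs(dd - d)), 1e-9)
  }
})

test_that("NJ matches ape's implementation on random matrices", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 8
    m <- matrix(runif(n * n, 0.05, 0.6), n)
    d <- (m + t(m)) / 2
    diag(d) <- 0
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- nj_tree(d)
    theirs <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(mine),
                                ape::unroot(theirs)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ tree has n-3 internal edges and is reproducible", {
  sim <- gap_sim(seed = 31, n_species = 4, n_per_species = 3)
  D <- distance_matrix(sim$alignment)
  phy <- nj_tree(D)
  n <- length(phy$tip.label)
  internal <- sum(phy$edge[, 2] > n)
  expect_equal(internal, n - 3)
  expect_equal(ape::write.tree(phy), ape::write.tree(nj_tree(D)))
  # input order must not matter
  perm <- sample(length(D$ids))
  D2 <- structure(list(ids = D$ids[perm], d = D$d[perm, perm],
                       metric = "K2P"), class = "barcode_dist")
  expect_equal(ape::write.tree(phy), ape::write.tree(nj_tree(D2)))
})

test_that("negative NJ branch lengths are zeroed with path lengths preserved", {
  # a non-additive matrix known to drive one NJ branch negative
  d <- matrix(c(0, .1, .4, .45,
                .1, 0, .42, .47,
                .4, .42, 0, .05,
                .45, .47, .05, 0), 4, 4)
  d[2, 3] <- d[3, 2] <- 0.10 # contradiction forcing negativity
  dimnames(d) <- list(letters[1:4], letters[1:4])
  phy <- nj_tree(d)
  expect_true(all(phy$edge.length >= 0))
})

test_that("monophyly is read off bipartitions; planted swap breaks it", {
  sim <- gap_sim(seed = 51, n_species = 5, n_per_species = 4)
  D <- distance_matrix(sim$alignment)
  phy <- nj_tree(D)
  mono <- monophyly(phy, sim$specimens)
  expect_true(all(mono$status == "monophyletic"))
  expect_true(all(mono$n_clades == 1))
  # swap one label: recipient species becomes non-monophyletic with 2
  # maximal conspecific clades
  S2 <- sim$specimens
  donor_id <- S2$specimen_id[S2$species_label == "Species_001"][1]
  S2$species_label[S2$specimen_id == donor_id] <- "Species_002"
  mono2 <- monophyly(phy, S2)
  rec <- mono2[mono2$species == "Species_002", ]
  expect_equal(rec$status, "non-monophyletic")
  expect_equal(rec$n_clades, 2L)
  # singletons report trivially monophyletic and flagged
  S3 <- sim$specimens
  S3$species_label[which(S3$species_label == "Species_003")[1]] <- "Solo"
  mono3 <- monophyly(phy, S3)
  expect_true(mono3$singleton[mono3$species == "Solo"])
  expect_equal(mono3$status[mono3$species == "Solo"], "monophyletic")
})

test_that("mixed haplotype-sharing pair forms one cluster, both non-monophyletic", {
  sim <- simulate_barcodes(sim_params(
    n_species = 5, n_per_species = 4, inter_range = c(5, 9),
    anomalies = list(shared_haplotype = 1), seed = 61))
  rec <- sim$anomalies[[1]]
  D <- distance_matrix(sim$alignment)
  phy <- nj_tree(D)
  mono <- monophyly(phy, sim$specimens)
  both <- mono[mono$species %in% rec$species, ]
  expect_true(all(both$status == "non-monophyletic"))
  ss <- species_summaries(D, sim$specimens)
  expect_equal(ss$min_inter[ss$species == rec$flag_species], 0)
})

test_that("bootstrap support is high for well-separated species and seeded", {
  sim <- gap_sim(seed = 71, n_species = 4, n_per_species = 4,
                 inter = c(8, 12), intra = 0.2)
  sup1 <- bootstrap_support(sim$alignment, sim$specimens, B = 30,
                            seed = 5)
  expect_true(all(sup1$support >= 0.95))
  sup2 <- bootstrap_support(sim$alignment, sim$specimens, B = 30,
                            seed = 5)
  expect_identical(sup1$support, sup2$support)
  # B = 1 is legal and deterministic
  sup3 <- bootstrap_support(sim$alignment, sim$specimens, B = 1,
                            seed = 9)
  expect_true(all(sup3$support %in% c(0, 1)))
  # specimen input order does not change support for a fixed seed
  perm <- sample(nrow(sim$specimens))
  sup4 <- bootstrap_support(sim$alignment[sim$specimens$specimen_id[perm]],
                            sim$specimens[perm, ], B = 30, seed = 5)
  expect_equal(sup1$support, sup4$support)
})

test_that("newick export carries per-species support labels", {
  sim <- gap_sim(seed = 81, n_species = 4, n_per_species = 3,
                 inter = c(8, 12))
  D <- distance_matrix(sim$alignment)
  phy <- nj_tree(D)
  sup <- bootstrap_support(sim$alignment, sim$specimens, B = 20,
                           seed = 2)
  p <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(phy, p, support = sup, S = sim$specimens)
  reread <- ape::read.tree(p)
  expect_true(any(reread$node.label == "100"))
})
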