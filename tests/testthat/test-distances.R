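# K2P / p-distances with pairwise deletion, matrix construction,
# haplotype collapsing.

test_that("pair_k2p matches the closed-form oracle on constructed pairs", {
  # identical sequences
  r <- pair_k2p("ACGTACGT", "ACGTACGT")
  expect_identical(r$distance, 0)
  expect_equal(r$P, 0); expect_equal(r$Q, 0); expect_equal(r$n, 8)

  # 20 sites, 1 transition (A->G) + 1 transversion (C->A)
  x <- strrep("ACGTT", 4)
  y <- mutate_at(mutate_at(x, 1, "G"), 2, "A")
  r <- pair_k2p(x, y)
  expect_equal(r$P, 0.05)
  expect_equal(r$Q, 0.05)
  expect_equal(r$distance, -0.5 * log(0.85) - 0.25 * log(0.90))

  # mismatching column with an N is excluded from numerator and n
  r <- pair_k2p("ACGTACGT", "NCGTACGC") # T->C transition at column 8
  expect_equal(r$n, 7)
  expect_equal(r$P, 1 / 7)

  # error cases: no comparable sites, saturation
  expect_error(pair_k2p("NNNN", "ACGT"), "no comparable")
  expect_error(pair_k2p("AAAA", "GGGG"), "saturated")
  expect_error(pair_k2p("ACGT", "ACGTA"), "length")
})

test_that("p-distance is the mismatch proportion and never exceeds K2P", {
  expect_equal(pair_p("ACGT", "ACGT")$distance, 0)
  x <- strrep("ACGTT", 4)
  y <- mutate_at(mutate_at(x, 1, "G"), 2, "A")
  expect_equal(pair_p(x, y)$distance, 0.10)
  set.seed(20)
  for (i in 1:50) {
    a <- random_seq(200)
    b <- mutate_at(a, sample(200, 25),
                   sample(c("A", "C", "G", "T"), 25, replace = TRUE))
    k <- try(pair_k2p(a, b), silent = TRUE)
    if (inherits(k, "try-error")) next
    expect_lte(pair_p(a, b)$distance, k$distance + 1e-12)
  }
})

test_that("K2P approaches P for small transition-only divergence", {
  for (npos in c(1, 3, 5)) {
    a <- random_seq(1000)
    v <- strsplit(a, "")[[1]]
    pos <- which(v == "A")[seq_len(npos)]
    b <- mutate_at(a, pos, "G") # pure transitions
    r <- pair_k2p(a, b)
    expect_equal(r$Q, 0)
    # exact expansion: d - P = P^2 + O(P^3), so bound at twice P^2
    expect_lt(abs(r$distance - r$P), 2 * r$P^2)
  }
})

test_that("adding a mismatch never decreases the K2P distance", {
  set.seed(33)
  a <- random_seq(300)
  b <- a
  prev <- 0
  v <- strsplit(a, "")[[1]]
  swap <- c(A = "G", C = "T", G = "A", T = "C") # transitions
  for (pos in sample(300, 40)) {
    b <- mutate_at(b, pos, swap[[v[pos]]])
    d <- pair_k2p(a, b)$distance
    expect_gte(d, prev)
    prev <- d
  }
})

test_that("distance_matrix agrees with per-pair calls and with ape's K80", {
  set.seed(8)
  seqs <- c(s1 = random_seq(120))
  seqs["s2"] <- mutate_at(seqs[["s1"]], 1:6,
                          c("G", "A", "T", "C", "N", "-"))
  seqs["s3"] <- mutate_at(seqs[["s1"]], 10:14,
                          c("T", "T", "N", "A", "G"))
  seqs["s4"] <- seqs[["s1"]]
  aln <- aln_from_strings(seqs)
  D <- distance_matrix(aln)
  expect_true(isSymmetric(D$d))
  expect_equal(unname(diag(D$d)), rep(0, 4))
  for (i in 1:3) for (j in (i + 1):4) {
    ref <- pair_k2p(paste(aln$seq[i, ], collapse = ""),
                    paste(aln$seq[j, ], collapse = ""))
    expect_equal(D$d[i, j], ref$distance)
    expect_equal(D$n_sites[i, j], ref$n)
  }
  # independent implementation: ape::dist.dna K80 with pairwise deletion
  dn <- ape::as.DNAbin(tolower(aln$seq))
  dk <- as.matrix(ape::dist.dna(dn, model = "K80",
                                pairwise.deletion = TRUE))
  expect_equal(D$d, dk[rownames(D$d), colnames(D$d)], tolerance = 1e-12)

  # p-distance entries live in [0, 1]
  Dp <- distance_matrix(aln, metric = "p")
  expect_true(all(Dp$d >= 0 & Dp$d <= 1))

  # identical sequences -> all-zero matrix
  D0 <- distance_matrix(aln_from_strings(a = "ACGT", b = "ACGT",
                                         c = "ACGT"))
  expect_true(all(D0$d == 0))
})

test_that("undefined pairs are flagged NA without aborting the matrix", {
  aln <- aln_from_strings(a = "AAAATTTT", b = "GGGGTTTT", # saturated pair
                          c = "AAAATTTT")
  expect_warning(D <- distance_matrix(aln), "undefined")
  expect_true(is.na(D$d["a", "b"]))
  expect_false(is.na(D$d["a", "c"]))
  p <- withr::local_tempfile()
  fp <- withr::local_tempfile()
  write_distance_matrix(D, p, flagged_path = fp)
  flags <- read.delim(fp) # both a-b and b-c are saturated
  expect_equal(flags$reason, c("saturated", "saturated"))
})

test_that("haplotypes are zero-distance components, robust to missing data", {
  # s1 == s2; s3 differs; s4 overlaps s1 and s3 through Ns (chain rule)
  aln <- aln_from_strings(
    s1 = "ACGTACGT", s2 = "ACGTACGT", s3 = "ACGTACGA",
    s4 = "ACGTACGN")
  S <- spec_table(c(s1 = "X", s2 = "X", s3 = "X", s4 = "X"))
  D <- distance_matrix(aln)
  hap <- collapse_haplotypes(D, S)
  # s4 is zero-distance from both s1 and s3, chaining all into one
  expect_equal(hap$per_species$n_haplotypes, 1L)

  aln2 <- aln_from_strings(s1 = "ACGTACGT", s2 = "ACGTACGT",
                           s3 = "ACGTACGA")
  hap2 <- collapse_haplotypes(distance_matrix(aln2),
                              spec_table(c(s1 = "X", s2 = "X", s3 = "X")))
  expect_equal(hap2$per_species$n_haplotypes, 2L)
  expect_equal(sum(hap2$per_species$n_specimens), 3L)

  # brute-force component oracle on a random dataset
  sim <- gap_sim(seed = 17)
  D3 <- distance_matrix(sim$alignment)
  hap3 <- collapse_haplotypes(D3, sim$specimens)
  for (sp in unique(sim$specimens$species_label)) {
    ids <- sim$specimens$specimen_id[sim$specimens$species_label == sp]
    adj <- (D3$d[ids, ids] == 0); diag(adj) <- TRUE
    # transitive closure by boolean powers
    reach <- adj
    for (k in seq_along(ids)) reach <- (reach %*% adj) > 0 | reach
    n_comp <- length(unique(apply(reach, 1, paste, collapse = "")))
    expect_equal(
      hap3$per_species$n_haplotypes[hap3$per_species$species == sp],
      n_comp)
  }
})
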