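# Species summaries, flags, histogram, unknown assignment.

test_that("species summaries match a brute-force pair scan", {
  sim <- gap_sim(seed = 12, n_species = 5)
  D <- distance_matrix(sim$alignment)
  S <- sim$specimens
  ss <- species_summaries(D, S)
  dpct <- 100 * D$d
  for (sp in ss$species) {
    ids <- S$specimen_id[S$species_label == sp]
    oth <- S$specimen_id[S$species_label != sp]
    sub <- dpct[ids, ids]
    vals <- sub[upper.tri(sub)]
    row <- ss[ss$species == sp, ]
    expect_equal(row$max_intra, max(vals))
    expect_equal(row$mean_intra, mean(vals))
    expect_equal(row$min_inter, min(dpct[ids, oth, drop = FALSE]))
    expect_gte(row$max_intra, row$mean_intra)
  }
  # at least one mutual nearest-neighbour pair exists
  nn <- structure(ss$nn_species, names = ss$species)
  expect_true(any(nn[nn] == names(nn), na.rm = TRUE))
})

test_that("two clean species give zero intra and the cross distance as NN", {
  aln <- aln_from_strings(
    a1 = strrep("ACGTT", 20), a2 = strrep("ACGTT", 20),
    b1 = strrep("AGGTT", 20), b2 = strrep("AGGTT", 20))
  S <- spec_table(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  ss <- species_summaries(distance_matrix(aln), S)
  expect_equal(ss$max_intra, c(0, 0))
  expect_equal(ss$nn_species, c("B", "A"))
  expect_equal(ss$min_inter[1], ss$min_inter[2])
  expect_equal(ss$n_haplotypes, c(1L, 1L))
})

test_that("singletons join as neighbours but carry no intra stats", {
  aln <- aln_from_strings(
    a1 = strrep("ACGTT", 20), a2 = strrep("ACGTT", 20),
    s1 = strrep("ACTTT", 20))
  S <- spec_table(c(a1 = "A", a2 = "A", s1 = "Solo"))
  ss <- species_summaries(distance_matrix(aln), S)
  solo <- ss[ss$species == "Solo", ]
  expect_true(is.na(solo$max_intra))
  expect_false(is.na(solo$min_inter))
  expect_equal(ss$nn_species[ss$species == "A"], "Solo")
})

test_that("flag rules: inclusive overlap, strict 2% cuts, singleton restriction", {
  ss <- data.frame(
    species = c("over", "hi", "lo", "clean", "edge", "solo"),
    n_specimens = c(3L, 3L, 3L, 3L, 3L, 1L),
    n_haplotypes = 1L,
    max_intra = c(2.50, 2.50, 0.10, 0.50, 1.30, NA),
    mean_intra = 0.1,
    nn_species = "x",
    min_inter = c(2.01, 5.00, 1.20, 5.00, 1.30, 1.50))
  fl <- flag_taxa(ss)
  expect_equal(fl$flags[fl$species == "over"], "OVERLAP,HIGH_INTRA")
  expect_equal(fl$flags[fl$species == "hi"], "HIGH_INTRA")
  expect_equal(fl$flags[fl$species == "lo"], "LOW_INTER")
  expect_equal(fl$flags[fl$species == "clean"], "")
  # exact equality still flags OVERLAP
  expect_true(fl$overlap[fl$species == "edge"])
  # singleton can only be LOW_INTER
  expect_equal(fl$flags[fl$species == "solo"], "LOW_INTER")
})

test_that("flags are stable under specimen reordering", {
  sim <- gap_sim(seed = 21)
  D <- distance_matrix(sim$alignment)
  fl1 <- flag_taxa(species_summaries(D, sim$specimens))
  perm <- sample(nrow(sim$specimens))
  S2 <- sim$specimens[perm, ]
  aln2 <- sim$alignment[S2$specimen_id]
  fl2 <- flag_taxa(species_summaries(distance_matrix(aln2), S2))
  expect_equal(fl1, fl2[order(match(fl2$species, fl1$species)), ],
               ignore_attr = TRUE)
})

test_that("histogram uses half-open bins with boundary values in the upper bin", {
  ss <- data.frame(species = c("a", "b", "c"), n_specimens = 2L,
                   n_haplotypes = 1L,
                   max_intra = c(0, 0.25, 0.30), mean_intra = 0,
                   nn_species = "x", min_inter = c(0.9, 1.0, 1.1))
  h <- gap_histogram(ss, bin_width = 0.25)
  expect_equal(h$intra_count[1], 1) # the 0
  expect_equal(h$intra_count[2], 2) # 0.25 (boundary -> upper) and 0.30
  expect_equal(sum(h$intra_count), 3)
  expect_equal(sum(h$inter_count), 3)
  # brute-force binning oracle on synthetic summaries
  sim <- gap_sim(seed = 9)
  ss2 <- species_summaries(distance_matrix(sim$alignment),
                           sim$specimens)
  h2 <- gap_histogram(ss2)
  for (r in sample(nrow(h2), 5)) {
    expect_equal(h2$intra_count[r],
                 sum(ss2$max_intra >= h2$bin_lo[r] &
                     ss2$max_intra < h2$bin_hi[r], na.rm = TRUE))
  }
})

test_that("unknowns are assigned by NN + cluster exclusivity, else AMBIGUOUS", {
  # unknown identical to species A member -> assigned A
  aln <- aln_from_strings(
    a1 = strrep("ACGTT", 30), a2 = strrep("ACGTT", 30),
    b1 = strrep("AGGTA", 30), b2 = strrep("AGGTA", 30),
    u1 = strrep("ACGTT", 30))
  S <- spec_table(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B",
                    u1 = "UNKNOWN"))
  res <- assign_unknowns(distance_matrix(aln), S)
  expect_equal(res$assigned, "A")
  expect_equal(res$nn_distance, 0)

  # unknown inside a mixed cluster -> AMBIGUOUS
  aln2 <- aln_from_strings(
    a1 = strrep("ACGTT", 30), b1 = strrep("ACGTT", 30),
    u1 = strrep("ACGTT", 30), c1 = strrep("TTTTT", 30))
  S2 <- spec_table(c(a1 = "A", b1 = "B", u1 = "UNKNOWN", c1 = "C"))
  res2 <- assign_unknowns(distance_matrix(aln2), S2)
  expect_equal(res2$assigned, "AMBIGUOUS")

  expect_error(assign_unknowns(distance_matrix(aln),
                               spec_table(c(a1 = "A", a2 = "A"))),
               "UNKNOWN")
})

test_that("synthetic unknowns are mostly assigned to their true species", {
  correct <- 0L; total <- 0L
  for (seed in 1:10) {
    sim <- gap_sim(seed = 300 + seed, n_species = 6, n_per_species = 4)
    S <- sim$specimens
    # hide the label of one specimen per dataset
    hide <- vapply(split(S$specimen_id, S$species_label),
                   `[`, character(1), 1)[1:3]
    S$species_label[S$specimen_id %in% hide] <- "UNKNOWN"
    res <- assign_unknowns(distance_matrix(sim$alignment), S)
    truth <- sim$truth$true_species[match(res$specimen_id,
                                          sim$truth$specimen_id)]
    correct <- correct + sum(res$assigned == truth)
    total <- total + length(truth)
  }
  expect_gte(correct / total, 0.95)
})
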