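# Seeded generator of aligned COI-like barcode datasets with known
# species structure and planted anomalies.
#
# Sequences evolve along a random species tree under a two-rate
# (Kimura-type, transition-biased) substitution process with exact
# closed-form site transition probabilities, so a branch of length d
# accrues d expected substitutions per site.  No indels are generated;
# missing data enter only as planted terminal N runs, mimicking short
# reads.  Infeasible divergence targets (intraspecific at or above the
# interspecific floor) are rejected before generation.

#' Simulation parameters
#'
#' Defaults emulate a well-populated northern-fauna barcode survey:
#' most species carry a handful of specimens with a tail of singletons,
#' intraspecific divergences sit mostly below 1% with a cap near 3%, and
#' nearest-neighbour interspecific divergences start around 0.8%.
#'
#' @param n_species Number of species (default 40).
#' @param n_per_species Optional explicit integer vector of specimen
#'   counts (recycled to `n_species`); by default counts are drawn as
#'   singletons with probability `prop_singletons`, else `2 + Poisson(5)`.
#' @param aln_length Alignment columns (default 658, the standard
#'   barcode fragment).
#' @param intra_mean Target mean pairwise intraspecific divergence, in
#'   percent (default 0.2).
#' @param intra_max Cap on individual terminal branches so intraspecific
#'   divergence stays below roughly this value, percent (default 3).
#' @param inter_range Target range for interspecific divergences,
#'   percent (default `c(0.8, 11)`): the species tree's node depths are
#'   mapped onto this range, so the closest species pair diverges by the
#'   lower bound and the deepest split by the upper.
#' @param kappa Transition/transversion rate ratio of the substitution
#'   process (default 6, giving an observed transition:transversion
#'   count ratio near 3, typical of insect COI).
#' @param base_freqs Root base frequencies in A, C, G, T order
#'   (default the AT-rich profile typical of insect mitochondrial COI,
#'   about 69% A+T); normalised internally.  At barcode-scale
#'   divergences the composition of the whole dataset stays close to
#'   this profile.
#' @param prop_singletons Probability a species is a singleton
#'   (default 0.15).
#' @param missing_rate Per-specimen probability of a terminal run of Ns
#'   (default 0).
#' @param missing_run Length range of planted N runs (default
#'   `c(20, 80)`).
#' @param focal_region,prop_focal Region labelling: each specimen is
#'   assigned `focal_region` with probability `prop_focal`, else
#'   `"Other"` (defaults `"Churchill"`, 0.85).
#' @param anomalies Named list of anomaly counts to plant after
#'   generation: `label_swap`, `cryptic_split`, `shared_haplotype`
#'   (defaults 0), plus `d_c`, the cryptic-split divergence in percent
#'   (default 4).
#' @param seed Mandatory integer seed.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_species = 40, n_per_species = NULL,
                       aln_length = 658, intra_mean = 0.2, intra_max = 3,
                       inter_range = c(0.8, 11), kappa = 6,
                       base_freqs = c(0.300, 0.154, 0.154, 0.392),
                       prop_singletons = 0.15, missing_rate = 0,
                       missing_run = c(20, 80),
                       focal_region = "Churchill", prop_focal = 0.85,
                       anomalies = list(), seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(n_species >= 1, aln_length >= 1, intra_mean >= 0,
            intra_max > 0, length(inter_range) == 2,
            inter_range[1] > 0, diff(inter_range) >= 0, kappa > 0,
            length(base_freqs) == 4, all(base_freqs > 0),
            prop_singletons >= 0, prop_singletons <= 1,
            missing_rate >= 0, missing_rate <= 1,
            prop_focal >= 0, prop_focal <= 1)
  base_freqs <- base_freqs / sum(base_freqs)
  if (intra_mean >= inter_range[1] || intra_max >= inter_range[1] * 4)
    stop("infeasible targets: intraspecific divergence reaches the ",
         "interspecific floor; no barcode gap can be generated")
  an <- list(label_swap = 0, cryptic_split = 0, shared_haplotype = 0,
             d_c = 4)
  an[names(anomalies)] <- anomalies
  structure(list(n_species = n_species, n_per_species = n_per_species,
                 aln_length = aln_length, intra_mean = intra_mean,
                 intra_max = intra_max, inter_range = inter_range,
                 kappa = kappa, base_freqs = base_freqs,
                 prop_singletons = prop_singletons,
                 missing_rate = missing_rate, missing_run = missing_run,
                 focal_region = focal_region, prop_focal = prop_focal,
                 anomalies = an, seed = as.integer(seed)),
            class = "sim_params")
}

# K80 site evolution over branch length d (expected substitutions/site):
# exact transition probabilities, vectorised over sites.
.evolve_k80 <- function(seq_int, d, kappa) {
  if (d <= 0) return(seq_int)
  bt <- d / (kappa + 2)
  at <- kappa * bt
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.25 - 0.25 * exp(-4 * bt) # each of the two transversions
  ts_target <- c(3L, 4L, 1L, 2L)     # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)
  tv2 <- c(4L, 3L, 4L, 3L)
  u <- stats::runif(length(seq_int))
  out <- seq_int
  m <- u < p_ts
  out[m] <- ts_target[seq_int[m]]
  m <- u >= p_ts & u < p_ts + p_tv
  out[m] <- tv1[seq_int[m]]
  m <- u >= p_ts + p_tv & u < p_ts + 2 * p_tv
  out[m] <- tv2[seq_int[m]]
  out
}

.int_to_chars <- function(v) .BASES[v]

#' Generate a synthetic barcode dataset
#'
#' Draws a root sequence uniformly, evolves species ancestors along a
#' random species tree scaled so the smallest interspecific divergence
#' matches the target floor, evolves individuals from their ancestor on
#' exponential terminal branches matching the intraspecific scale, then
#' plants the requested anomalies and missing-data runs.  Byte-identical
#' output for the same parameters and seed.
#'
#' @param params A [sim_params()] object.
#' @return Object of class `barcode_sim`: list with `alignment`
#'   (`barcode_aln`), `specimens` (metadata table whose labels reflect
#'   planted anomalies), `truth` (data frame specimen -> true species),
#'   `anomalies` (records of planted anomalies with the flag each must
#'   trigger) and `params`.
#' @export
simulate_barcodes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  p <- params
  counts <- p$n_per_species
  if (is.null(counts)) {
    counts <- ifelse(stats::runif(p$n_species) < p$prop_singletons, 1L,
                     2L + stats::rpois(p$n_species, 5))
  } else {
    counts <- as.integer(rep_len(counts, p$n_species))
  }
  sp_names <- sprintf("Species_%03d", seq_len(p$n_species))
  L <- p$aln_length
  root <- sample.int(4L, L, replace = TRUE, prob = p$base_freqs)
  # species ancestors
  if (p$n_species == 1) {
    anc <- list(root)
  } else if (p$n_species == 2) {
    half <- p$inter_range[1] / 200
    anc <- list(.evolve_k80(root, half, p$kappa),
                .evolve_k80(root, half, p$kappa))
  } else {
    # random coalescent species tree; node depths mapped linearly onto
    # the target range so every interspecific divergence (2 x MRCA
    # depth) lies in [inter_lo, inter_hi] and the tree stays ultrametric
    tre <- ape::rcoal(p$n_species, tip.label = sp_names)
    bt <- ape::branching.times(tre)
    lo <- p$inter_range[1] / 200
    hi <- p$inter_range[2] / 200
    # map node-depth *ranks* uniformly onto the range: raw coalescent
    # times bunch near the present, which would push every species pair
    # to the lower bound; rank mapping keeps the topology-consistent
    # depth order while spreading split depths evenly over the range
    depth <- if (length(bt) > 1)
      lo + (rank(bt, ties.method = "first") - 1) / (length(bt) - 1) *
        (hi - lo)
    else rep((lo + hi) / 2, length(bt))
    names(depth) <- names(bt)
    nt <- p$n_species
    node_depth <- c(rep(0, nt), depth[as.character(seq(nt + 1,
                                                       nt + tre$Nnode))])
    tre$edge.length <- node_depth[tre$edge[, 1]] -
      node_depth[tre$edge[, 2]]
    seqs_at <- vector("list", nt + tre$Nnode)
    seqs_at[[nt + 1L]] <- root
    tre <- ape::reorder.phylo(tre, "cladewise")
    for (k in seq_len(nrow(tre$edge)))
      seqs_at[[tre$edge[k, 2]]] <- .evolve_k80(seqs_at[[tre$edge[k, 1]]],
                                               tre$edge.length[k],
                                               p$kappa)
    anc <- seqs_at[match(sp_names, tre$tip.label)]
  }
  # individuals
  ids <- character(0)
  seq_rows <- list()
  truth_sp <- character(0)
  spec_counter <- 0L
  for (i in seq_len(p$n_species)) {
    for (j in seq_len(counts[i])) {
      spec_counter <- spec_counter + 1L
      id <- sprintf("SP%04d", spec_counter)
      br <- min(stats::rexp(1, rate = 200 / max(p$intra_mean, 1e-9)),
                p$intra_max / 200)
      if (p$intra_mean == 0) br <- 0
      seq_rows[[spec_counter]] <- .evolve_k80(anc[[i]], br, p$kappa)
      ids <- c(ids, id)
      truth_sp <- c(truth_sp, sp_names[i])
    }
  }
  enc <- do.call(rbind, seq_rows)
  specimens <- data.frame(
    specimen_id = ids,
    species_label = truth_sp,
    sex = sample(c("M", "F"), length(ids), replace = TRUE),
    region = ifelse(stats::runif(length(ids)) < p$prop_focal,
                    p$focal_region, "Other"),
    stringsAsFactors = FALSE)
  charmat <- matrix(.int_to_chars(enc), nrow = nrow(enc))
  rownames(charmat) <- ids
  # terminal missing-data runs
  if (p$missing_rate > 0) {
    for (i in seq_along(ids)) {
      if (stats::runif(1) >= p$missing_rate) next
      run <- sample(seq(p$missing_run[1], p$missing_run[2]), 1)
      run <- min(run, L - 1)
      if (stats::runif(1) < 0.5) charmat[i, seq_len(run)] <- "N"
      else charmat[i, seq(L - run + 1, L)] <- "N"
    }
  }
  sim <- structure(list(
    alignment = new_alignment(charmat, ids),
    specimens = specimens,
    truth = data.frame(specimen_id = ids, true_species = truth_sp,
                       stringsAsFactors = FALSE),
    anomalies = list(),
    params = p), class = "barcode_sim")
  an <- p$anomalies
  for (kind in c("label_swap", "cryptic_split", "shared_haplotype"))
    for (r in seq_len(an[[kind]]))
      sim <- plant_anomaly(sim, kind, d_c = an$d_c)
  sim
}

#' @export
print.barcode_sim <- function(x, ...) {
  cat("Synthetic barcode dataset:", length(x$alignment$ids),
      "specimens,", length(unique(x$truth$true_species)), "species,",
      x$alignment$length, "bp;", length(x$anomalies),
      "planted anomalies\n")
  invisible(x)
}

#' Plant an anomaly into a synthetic dataset
#'
#' * `label_swap`: one specimen's label moves to another species
#'   (a misidentification).  Expected signal: the recipient species'
#'   maximum intraspecific distance exceeds its nearest-neighbour
#'   distance (`OVERLAP` flag) and it becomes non-monophyletic.
#' * `cryptic_split`: one labeled species is rebuilt from two ancestors
#'   at divergence `d_c`.  Expected signal for `d_c` > 2%: `HIGH_INTRA`.
#' * `shared_haplotype`: one species' sequences are replaced by copies
#'   drawn from another species' gene pool (two labels over one pool).
#'   Expected signal: nearest-neighbour distance 0 (`LOW_INTER`, mixed
#'   cluster).
#'
#' Species are chosen at random among those large enough (never
#' singletons; re-using the generator's RNG stream, so planting is
#' reproducible given the dataset seed).  Each planted anomaly is
#' recorded in `x$anomalies` together with the flag it must trigger.
#'
#' @param x A `barcode_sim`.
#' @param kind `"label_swap"`, `"cryptic_split"` or
#'   `"shared_haplotype"`.
#' @param d_c Cryptic-split divergence in percent (default 4).
#' @param species Optional species to target (label; default random
#'   eligible species).
#' @return The modified `barcode_sim`.
#' @export
plant_anomaly <- function(x, kind = c("label_swap", "cryptic_split",
                                      "shared_haplotype"),
                          d_c = 4, species = NULL) {
  kind <- match.arg(kind)
  p <- x$params
  tab <- table(x$specimens$species_label)
  touched <- unique(unlist(lapply(x$anomalies, function(a) a$species)))
  eligible <- function(min_n) {
    cand <- names(tab)[tab >= min_n]
    setdiff(cand, touched)
  }
  pick <- function(pool) {
    if (length(pool) == 0) stop("no eligible species for ", kind,
                                " (anomalies need non-singleton species)")
    pool[sample.int(length(pool), 1)]
  }
  if (kind == "label_swap") {
    donor <- if (is.null(species)) pick(eligible(2)) else species
    if (tab[donor] < 2) stop("cannot plant label_swap on a singleton")
    recip <- pick(setdiff(eligible(2), donor))
    sel <- which(x$specimens$species_label == donor)
    mover <- x$specimens$specimen_id[sel[sample.int(length(sel), 1)]]
    x$specimens$species_label[x$specimens$specimen_id == mover] <- recip
    rec <- list(type = "label_swap", specimens = mover,
                species = c(donor, recip), expected_flag = "OVERLAP",
                flag_species = recip)
  } else if (kind == "cryptic_split") {
    target <- if (is.null(species)) pick(eligible(4)) else species
    if (tab[target] < 2) stop("cannot plant cryptic_split on a singleton")
    sel <- which(x$specimens$species_label == target)
    half <- sel[seq_len(ceiling(length(sel) / 2))]
    base_id <- x$specimens$specimen_id[sel[length(sel)]]
    base <- match(x$alignment$seq[base_id, ], .BASES)
    base[is.na(base)] <- sample.int(4L, sum(is.na(base)), replace = TRUE)
    anc2 <- .evolve_k80(base, d_c / 100, p$kappa)
    for (i in half) {
      br <- min(stats::rexp(1, rate = 200 / max(p$intra_mean, 1e-9)),
                p$intra_max / 200)
      x$alignment$seq[x$specimens$specimen_id[i], ] <-
        .int_to_chars(.evolve_k80(anc2, br, p$kappa))
    }
    rec <- list(type = "cryptic_split",
                specimens = x$specimens$specimen_id[half],
                species = target, d_c = d_c,
                expected_flag = "HIGH_INTRA", flag_species = target)
  } else { # shared_haplotype
    a <- if (is.null(species)) pick(eligible(2)) else species
    if (tab[a] < 2) stop("cannot plant shared_haplotype on a singleton")
    b <- pick(setdiff(eligible(2), a))
    pool <- x$specimens$specimen_id[x$specimens$species_label == a]
    bsel <- x$specimens$specimen_id[x$specimens$species_label == b]
    for (id in bsel) {
      src <- pool[sample.int(length(pool), 1)]
      x$alignment$seq[id, ] <- x$alignment$seq[src, ]
    }
    rec <- list(type = "shared_haplotype", specimens = bsel,
                species = c(a, b), expected_flag = "LOW_INTER",
                flag_species = b)
  }
  x$anomalies <- c(x$anomalies, list(rec))
  x
}

#' Write a synthetic dataset to disk
#'
#' Emits the FASTA alignment, the specimen TSV and a JSON truth file
#' (true species per specimen plus planted-anomaly records).
#'
#' @param x A `barcode_sim`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem (default `"synthetic"`).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_sim <- function(x, dir, stem = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(stem, ".fasta"))
  tsv <- file.path(dir, paste0(stem, "_specimens.tsv"))
  js <- file.path(dir, paste0(stem, "_truth.json"))
  write_alignment(x$alignment, fa)
  write_specimens(x$specimens, tsv)
  jsonlite::write_json(list(truth = x$truth, anomalies = x$anomalies,
                            seed = x$params$seed),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, specimens = tsv, truth = js))
}
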