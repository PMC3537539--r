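# Species-level barcode-gap summaries, flagging, and assignment of
# unknowns.  All values in these tables are percentages.

# per-species index list over labeled specimens present in D, sorted by name
.species_index <- function(D, S) {
  S <- S[S$species_label != .UNKNOWN, ]
  missing_ids <- setdiff(S$specimen_id, D$ids)
  if (length(missing_ids))
    stop("specimens absent from distance matrix: ",
         paste(missing_ids, collapse = ", "))
  idx <- split(match(S$specimen_id, D$ids), S$species_label)
  idx[order(names(idx))]
}

#' Species-level distance summaries
#'
#' For every labeled species: intraspecific maximum and mean (over all
#' within-species specimen pairs; undefined for singletons) and the
#' nearest-neighbour interspecific minimum (over all pairs against every
#' other species, singletons included as potential neighbours).
#' Nearest-neighbour ties resolve toward the alphabetically first species.
#'
#' @param D A `barcode_dist`.
#' @param S Specimen data frame; `UNKNOWN` specimens are excluded.
#' @return Data frame of class `species_summary` with columns `species`,
#'   `n_specimens`, `n_haplotypes`, `max_intra`, `mean_intra`,
#'   `nn_species`, `min_inter` (percent).
#' @export
species_summaries <- function(D, S) {
  idx <- .species_index(D, S)
  if (length(idx) == 0) stop("no labeled specimens")
  dpct <- 100 * D$d
  ns <- length(idx)
  species <- names(idx)
  n_spec <- lengths(idx)
  max_intra <- mean_intra <- rep(NA_real_, ns)
  warned <- FALSE
  for (k in seq_len(ns)) {
    if (n_spec[k] < 2) next
    sub <- dpct[idx[[k]], idx[[k]]]
    vals <- sub[upper.tri(sub)]
    if (anyNA(vals)) {
      if (!warned) {
        warning("undefined distances excluded from species summaries")
        warned <- TRUE
      }
      vals <- vals[!is.na(vals)]
    }
    if (length(vals)) {
      max_intra[k] <- max(vals)
      mean_intra[k] <- mean(vals)
    }
  }
  # species x species matrix of cross-minima
  cross_min <- matrix(NA_real_, ns, ns)
  for (a in seq_len(ns - 1)) {
    for (b in seq(a + 1, ns)) {
      vals <- dpct[idx[[a]], idx[[b]]]
      if (!all(is.na(vals)))
        cross_min[a, b] <- cross_min[b, a] <- min(vals, na.rm = TRUE)
    }
  }
  nn_species <- rep(NA_character_, ns)
  min_inter <- rep(NA_real_, ns)
  if (ns >= 2) {
    for (k in seq_len(ns)) {
      row <- cross_min[k, ]
      if (all(is.na(row))) next
      min_inter[k] <- min(row, na.rm = TRUE)
      nn_species[k] <- species[which(row == min_inter[k])[1]]
    }
  }
  hap <- collapse_haplotypes(D, S)
  out <- data.frame(species = species,
                    n_specimens = as.integer(n_spec),
                    n_haplotypes = hap$per_species$n_haplotypes[
                      match(species, hap$per_species$species)],
                    max_intra = max_intra,
                    mean_intra = mean_intra,
                    nn_species = nn_species,
                    min_inter = min_inter,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("species_summary", "data.frame")
  out
}

#' Flag taxa with anomalous divergence values
#'
#' Three flags drive the taxonomic-reassessment loop:
#' `OVERLAP` (max intraspecific >= minimum interspecific; the inclusive
#' rule deliberately flags exact equality for review), `HIGH_INTRA`
#' (max intraspecific strictly above `intra_cut`) and `LOW_INTER`
#' (nearest-neighbour distance strictly below `inter_cut`).  Singletons
#' can only receive `LOW_INTER`.
#'
#' @param ss A `species_summary` data frame.
#' @param intra_cut,inter_cut Cutoffs in percent (default 2.0).
#' @return Data frame with `species`, logical columns `overlap`,
#'   `high_intra`, `low_inter`, and a comma-separated `flags` string.
#' @export
flag_taxa <- function(ss, intra_cut = 2.0, inter_cut = 2.0) {
  overlap <- !is.na(ss$max_intra) & !is.na(ss$min_inter) &
    ss$max_intra >= ss$min_inter
  high_intra <- !is.na(ss$max_intra) & ss$max_intra > intra_cut
  low_inter <- !is.na(ss$min_inter) & ss$min_inter < inter_cut
  flags <- vapply(seq_len(nrow(ss)), function(i) {
    paste(c("OVERLAP", "HIGH_INTRA", "LOW_INTER")[
      c(overlap[i], high_intra[i], low_inter[i])], collapse = ",")
  }, character(1))
  data.frame(species = ss$species, overlap = overlap,
             high_intra = high_intra, low_inter = low_inter,
             flags = flags, stringsAsFactors = FALSE, row.names = NULL)
}

#' Barcode-gap histogram
#'
#' Bins maximum intraspecific distances (species with >= 2 specimens) and
#' nearest-neighbour minimum interspecific distances (all species) into
#' half-open intervals `[k*w, (k+1)*w)`; a value exactly on a boundary
#' falls in the upper bin.
#'
#' @param ss A `species_summary` data frame.
#' @param bin_width Bin width in percent (default 0.25).
#' @return Data frame with `bin_lo`, `bin_hi`, `intra_count`,
#'   `inter_count`.
#' @export
gap_histogram <- function(ss, bin_width = 0.25) {
  stopifnot(bin_width > 0)
  intra <- ss$max_intra[!is.na(ss$max_intra) & ss$n_specimens >= 2]
  inter <- ss$min_inter[!is.na(ss$min_inter)]
  if (length(c(intra, inter)) == 0) stop("no distances to bin")
  nb <- floor(max(c(intra, inter)) / bin_width) + 1
  bin_of <- function(v) pmin(floor(v / bin_width), nb - 1) + 1
  data.frame(bin_lo = (seq_len(nb) - 1) * bin_width,
             bin_hi = seq_len(nb) * bin_width,
             intra_count = tabulate(bin_of(intra), nb),
             inter_count = tabulate(bin_of(inter), nb))
}

#' Assign unknown specimens by genetic matching
#'
#' Assigns each `UNKNOWN` specimen (e.g. a morphologically ambiguous
#' female) to the species of its nearest labeled neighbour, but only when
#' its single-linkage cluster at `threshold` contains labeled specimens of
#' exactly that one species; an unknown falling in a mixed or empty
#' cluster, or whose nearest neighbour disagrees with the cluster, is
#' reported `AMBIGUOUS`.
#'
#' @param D A `barcode_dist` covering the unknowns and references.
#' @param S Specimen data frame with at least one `UNKNOWN` specimen and
#'   at least one labeled specimen.
#' @param threshold Single-linkage threshold in percent (default 2.0).
#' @return Data frame with `specimen_id`, `assigned` (species label or
#'   `"AMBIGUOUS"`), `nn_species`, `nn_distance` (percent).
#' @export
assign_unknowns <- function(D, S, threshold = 2.0) {
  unk <- S$specimen_id[S$species_label == .UNKNOWN]
  lab <- S[S$species_label != .UNKNOWN, ]
  if (length(unk) == 0) stop("no UNKNOWN specimens to assign")
  if (nrow(lab) == 0) stop("no labeled reference specimens")
  dpct <- 100 * D$d
  out <- lapply(unk, function(u) {
    dl <- dpct[u, lab$specimen_id]
    if (all(is.na(dl)))
      return(data.frame(specimen_id = u, assigned = "AMBIGUOUS",
                        nn_species = NA_character_,
                        nn_distance = NA_real_))
    nn_i <- which.min(dl)
    nn_sp <- lab$species_label[nn_i]
    ids <- c(lab$specimen_id, u)
    part <- single_linkage(D, threshold, ids = ids, warn = FALSE)
    cl_u <- part$membership[u]
    members <- names(part$membership)[part$membership == cl_u]
    cluster_sp <- unique(lab$species_label[lab$specimen_id %in% members])
    assigned <- if (length(cluster_sp) == 1 && cluster_sp == nn_sp)
      nn_sp else "AMBIGUOUS"
    data.frame(specimen_id = u, assigned = assigned, nn_species = nn_sp,
               nn_distance = unname(dl[nn_i]), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write species summaries and flags as TSV
#'
#' @param ss A `species_summary` data frame.
#' @param path Output path; distances are rounded to 2 decimals.
#' @param flags Optional output of [flag_taxa()] to merge in.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(ss, path, flags = NULL) {
  out <- ss
  for (col in c("max_intra", "mean_intra", "min_inter"))
    out[[col]] <- round(out[[col]], 2)
  if (!is.null(flags))
    out$flags <- flags$flags[match(out$species, flags$species)]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "-")
  invisible(path)
}
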