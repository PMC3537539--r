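# Single-linkage clustering at a divergence threshold and the
# threshold-sweep error analysis (erroneous lumping/splitting, species
# discrimination success, richness estimation).

#' Single-linkage partition at a distance threshold
#'
#' Clusters are the connected components of the graph linking specimen
#' pairs with distance `<= t` (inclusive, so identical haplotypes merge
#' even at t = 0).  Undefined distances are treated as above the
#' threshold, with a warning.
#'
#' @param D A `barcode_dist`.
#' @param t Threshold in percent (>= 0).
#' @param ids Optional subset of specimen ids to cluster (default: all).
#' @param warn Emit the undefined-distance warning (default `TRUE`).
#' @return Object of class `barcode_partition`: list with `threshold`,
#'   `membership` (named integer vector; cluster ids are numbered by the
#'   sort order of each cluster's smallest member id) and `n_clusters`.
#' @export
single_linkage <- function(D, t, ids = NULL, warn = TRUE) {
  stopifnot(t >= 0)
  if (is.null(ids)) ids <- D$ids
  dpct <- 100 * D$d[ids, ids, drop = FALSE]
  if (warn && anyNA(dpct[upper.tri(dpct)]))
    warning("undefined distances treated as exceeding the threshold")
  adj <- !is.na(dpct) & dpct <= t
  diag(adj) <- TRUE
  comp <- .components(adj)
  # relabel clusters by their smallest member id
  first_id <- vapply(seq_len(max(comp)),
                     function(k) min(ids[comp == k]), character(1))
  relab <- order(order(first_id)) # rank of each cluster's smallest id
  membership <- relab[comp]
  names(membership) <- ids
  structure(list(threshold = t, membership = membership,
                 n_clusters = max(comp)),
            class = "barcode_partition")
}

#' @export
print.barcode_partition <- function(x, ...) {
  cat(sprintf("Single-linkage partition at %.2f%%: %d specimens in %d clusters\n",
              x$threshold, length(x$membership), x$n_clusters))
  invisible(x)
}

#' Threshold sweep of lumping/splitting error rates
#'
#' For each threshold on the grid, specimens are clustered by single
#' linkage and every species is scored: *lumped* if any of its clusters
#' also contains another species' specimens, *split* if its specimens
#' occupy two or more clusters (a species can be both), and *perfect* if
#' neither.  The success rate is the percentage of perfect species; the
#' richness error is the absolute difference between the cluster count
#' and the number of species.
#'
#' @param D A `barcode_dist`.
#' @param S Specimen data frame; `UNKNOWN` specimens are excluded.
#' @param grid Ascending thresholds in percent
#'   (default `seq(0.1, 3.0, by = 0.1)`).
#' @param min_n Restrict scored species to those with at least this many
#'   specimens (default 1, i.e. singletons included; a singleton is
#'   perfect iff it sits alone in its cluster).  Clustering always uses
#'   all labeled specimens.
#' @return Data frame of class `threshold_sweep`: one row per threshold
#'   with `threshold`, `n_clusters`, `n_lumped`, `n_split`, `n_perfect`,
#'   `success_rate` (percent) and `richness_error`.
#' @export
threshold_sweep <- function(D, S, grid = seq(0.1, 3.0, by = 0.1),
                            min_n = 1) {
  if (length(grid) == 0 || is.unsorted(grid))
    stop("`grid` must be non-empty and ascending")
  Slab <- S[S$species_label != .UNKNOWN & S$specimen_id %in% D$ids, ]
  ids <- Slab$specimen_id
  label <- Slab$species_label
  n_total_species <- length(unique(label))
  counts <- table(label)
  scored <- names(counts)[counts >= min_n]
  if (anyNA(100 * D$d[ids, ids][upper.tri(D$d[ids, ids])]))
    warning("undefined distances treated as exceeding every threshold")
  rows <- lapply(grid, function(t) {
    part <- single_linkage(D, t, ids = ids, warn = FALSE)
    cl <- part$membership[ids]
    # cluster -> number of species it contains
    mixed_cluster <- vapply(split(label, cl),
                            function(x) length(unique(x)) > 1, logical(1))
    by_species <- split(cl, label)
    lumped <- vapply(by_species, function(x)
      any(mixed_cluster[as.character(unique(x))]), logical(1))
    splitv <- vapply(by_species, function(x)
      length(unique(x)) > 1, logical(1))
    lumped <- lumped[scored]
    splitv <- splitv[scored]
    perfect <- !lumped & !splitv
    data.frame(threshold = t,
               n_clusters = part$n_clusters,
               n_lumped = sum(lumped),
               n_split = sum(splitv),
               n_perfect = sum(perfect),
               success_rate = 100 * sum(perfect) / length(scored),
               richness_error = abs(part$n_clusters - n_total_species))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_species_scored") <- length(scored)
  attr(out, "n_species_total") <- n_total_species
  attr(out, "min_n") <- min_n
  class(out) <- c("threshold_sweep", "data.frame")
  out
}

#' Optimal identification threshold
#'
#' The threshold maximising the species-discrimination success rate
#' (equivalently, minimising the number of species that are lumped or
#' split, each erroneous species counted once).  Ties resolve toward the
#' smallest threshold.
#'
#' @param rows A `threshold_sweep` data frame.
#' @return List with `threshold` and `success_rate` (percent).
#' @export
optimal_threshold <- function(rows) {
  if (nrow(rows) == 0) stop("empty sweep")
  i <- which.max(rows$success_rate) # first max = smallest t on ties
  list(threshold = rows$threshold[i], success_rate = rows$success_rate[i])
}

#' Best threshold for species-richness estimation
#'
#' The threshold whose cluster count is closest to the true species
#' count; ties resolve toward the smallest threshold.
#'
#' @param rows A `threshold_sweep` data frame.
#' @return List with `threshold` and `richness_error`.
#' @export
richness_threshold <- function(rows) {
  if (nrow(rows) == 0) stop("empty sweep")
  i <- which.min(rows$richness_error)
  list(threshold = rows$threshold[i],
       richness_error = rows$richness_error[i])
}

#' Write a threshold sweep (or partition) as TSV
#'
#' @param x A `threshold_sweep` data frame or `barcode_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(x, path) {
  if (inherits(x, "barcode_partition"))
    x <- data.frame(specimen_id = names(x$membership),
                    cluster = unname(x$membership))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
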