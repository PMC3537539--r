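# Auxiliary inference: does adding material from other localities raise
# maximum intraspecific distances, and does sampling depth predict them?

#' Paired maximum intraspecific distances with and without non-focal
#' material
#'
#' For every species with at least two specimens from the focal region
#' and at least one from elsewhere: the maximum intraspecific distance
#' over all specimens versus over focal-region specimens only.
#'
#' @param D A `barcode_dist`.
#' @param S Specimen data frame with a `region` column.
#' @param focal_region Name of the focal region (e.g. `"Churchill"`).
#' @return Data frame with `species`, `max_intra_all`,
#'   `max_intra_local` (percent), `n_local`, `n_other`.
#' @export
paired_max_intra <- function(D, S, focal_region) {
  S <- S[S$species_label != .UNKNOWN & S$specimen_id %in% D$ids, ]
  dpct <- 100 * D$d
  rows <- lapply(split(S, S$species_label), function(grp) {
    local <- grp$specimen_id[grp$region == focal_region]
    other <- grp$specimen_id[grp$region != focal_region]
    if (length(local) < 2 || length(other) < 1) return(NULL)
    all_ids <- grp$specimen_id
    sub_all <- dpct[all_ids, all_ids]
    sub_loc <- dpct[local, local]
    data.frame(species = grp$species_label[1],
               max_intra_all = max(sub_all[upper.tri(sub_all)],
                                   na.rm = TRUE),
               max_intra_local = max(sub_loc[upper.tri(sub_loc)],
                                     na.rm = TRUE),
               n_local = length(local), n_other = length(other),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out) || nrow(out) == 0)
    stop("no species with >= 2 focal and >= 1 non-focal specimens")
  out
}

#' Locality permutation test on maximum intraspecific distance
#'
#' Observed statistic: the mean over species of
#' `max_intra_all - max_intra_local`.  The null distribution is built by
#' relabeling, per species and per permutation, which `n_other` of its
#' specimens count as "other" and recomputing the focal-only maximum.
#' The one-tailed p-value uses add-one smoothing,
#' `p = (1 + #{perm >= obs}) / (1 + n_perm)`, so it is never exactly
#' zero.  Bit-reproducible for a fixed seed.
#'
#' @param D A `barcode_dist`.
#' @param S Specimen data frame with a `region` column.
#' @param focal_region Focal region name.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed (default 1).
#' @return List with `p_value`, `observed` (mean difference, percent),
#'   `n_species`, `n_perm`, and the `paired` table.
#' @export
locality_permutation_test <- function(D, S, focal_region,
                                      n_perm = 1000, seed = 1) {
  pm <- paired_max_intra(D, S, focal_region)
  if (nrow(pm) < 2) stop("need >= 2 species for the permutation test")
  observed <- mean(pm$max_intra_all - pm$max_intra_local)
  S <- S[S$species_label != .UNKNOWN & S$specimen_id %in% D$ids, ]
  dpct <- 100 * D$d
  subs <- lapply(pm$species, function(sp) {
    ids <- S$specimen_id[S$species_label == sp]
    dpct[ids, ids]
  })
  n_other <- pm$n_other
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  perm_stats <- vapply(seq_len(n_perm), function(p) {
    diffs <- vapply(seq_along(subs), function(k) {
      m <- subs[[k]]
      oth <- sample.int(nrow(m), n_other[k])
      loc <- m[-oth, -oth, drop = FALSE]
      pm$max_intra_all[k] - max(loc[upper.tri(loc)], na.rm = TRUE)
    }, numeric(1))
    mean(diffs)
  }, numeric(1))
  list(p_value = (1 + sum(perm_stats >= observed)) / (1 + n_perm),
       observed = observed,
       n_species = nrow(pm), n_perm = n_perm, paired = pm)
}

#' Regression of maximum intraspecific distance on sample size
#'
#' Ordinary least squares of `max_intra` on the number of specimens per
#' species, typically restricted to a single region upstream so sampling
#' depth is not confounded with geography.
#'
#' @param ss A `species_summary` data frame (species with fewer than two
#'   specimens are dropped).
#' @return List with `r_squared`, `p_value` (two-sided F test), `slope`,
#'   `n_species`, and the underlying `lm` fit.
#' @export
regress_n_vs_maxintra <- function(ss) {
  dat <- ss[!is.na(ss$max_intra) & ss$n_specimens >= 2, ]
  if (nrow(dat) < 3) stop("need >= 3 species with >= 2 specimens")
  if (stats::var(dat$n_specimens) == 0)
    stop("no variance in specimen counts")
  fit <- stats::lm(max_intra ~ n_specimens, data = dat)
  sm <- summary(fit)
  p <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                 lower.tail = FALSE)
  list(r_squared = unname(sm$r.squared),
       p_value = unname(p),
       slope = unname(stats::coef(fit)[2]),
       n_species = nrow(dat), fit = fit)
}
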