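# The central analysis constructor: one call running QC, composition,
# distances, barcode-gap summaries and flags, the NJ tree with monophyly
# (and optionally bootstrap support), and the threshold sweep; plus the
# report-bundle orchestrator behind the command-line interface.

#' Barcode-gap species-limits analysis
#'
#' Fits the whole distance-based species-limits workflow to an aligned
#' barcode matrix and its specimen table: quality filtering, nucleotide
#' composition, pairwise distances (pairwise deletion), haplotype and
#' species-level summaries with anomaly flags, the barcode-gap
#' histogram, the neighbour-joining tree with monophyly assessment (and
#' bootstrap support when `bootstrap > 0`), and the single-linkage
#' threshold sweep with its optimal identification and richness
#' thresholds.  `UNKNOWN` specimens are excluded from species-level
#' statistics and, when present, assigned by genetic matching.
#'
#' @param alignment A `barcode_aln`.
#' @param specimens Specimen data frame covering the alignment ids.
#' @param metric `"K2P"` (default) or `"p"`.
#' @param min_len,max_n_frac Quality-filter settings (see
#'   [qc_filter()]).
#' @param intra_cut,inter_cut Flagging cutoffs in percent (default 2).
#' @param bin_width Histogram bin width in percent (default 0.25).
#' @param grid Threshold grid in percent (default 0.1-3.0 by 0.1).
#' @param min_n Minimum specimens for a species to be scored in the
#'   sweep (default 1).
#' @param tree Build the NJ tree and assess monophyly (default `TRUE`;
#'   needs >= 3 labeled specimens and fully defined distances).
#' @param bootstrap Bootstrap replicates for cluster support (default 0
#'   = skip).
#' @param focal_region Optional region name; when given, the locality
#'   permutation test and the sample-size regression (focal material
#'   only) are run.
#' @param n_perm Permutations for the locality test (default 1000).
#' @param seed Integer seed governing bootstrap and permutations
#'   (default 1).
#' @return Object of class `barcode_gap` collecting all components
#'   (`qc`, `composition`, `distances`, `haplotypes`, `summaries`,
#'   `flags`, `histogram`, `tree`, `monophyly`, `support`, `sweep`,
#'   `optimal`, `richness`, `unknowns`, `locality_test`, `regression`,
#'   `call`, `settings`).
#' @examples
#' sim <- simulate_barcodes(sim_params(n_species = 5,
#'   n_per_species = 4, inter_range = c(4, 8), seed = 7))
#' fit <- barcode_gap(sim$alignment, sim$specimens, tree = FALSE)
#' fit$optimal
#' @export
barcode_gap <- function(alignment, specimens, metric = c("K2P", "p"),
                        min_len = 600, max_n_frac = 0.01,
                        intra_cut = 2, inter_cut = 2, bin_width = 0.25,
                        grid = seq(0.1, 3.0, by = 0.1), min_n = 1,
                        tree = TRUE, bootstrap = 0,
                        focal_region = NULL, n_perm = 1000, seed = 1) {
  metric <- match.arg(metric)
  check_specimens(alignment, specimens)
  qc <- qc_filter(alignment, min_len = min_len, max_n_frac = max_n_frac)
  aln <- qc$alignment
  S <- specimens[specimens$specimen_id %in% aln$ids, ]
  comp <- composition(aln)
  D <- distance_matrix(aln, metric = metric)
  hap <- collapse_haplotypes(D, S)
  ss <- species_summaries(D, S)
  flags <- flag_taxa(ss, intra_cut = intra_cut, inter_cut = inter_cut)
  hist <- gap_histogram(ss, bin_width = bin_width)
  sweep <- threshold_sweep(D, S, grid = grid, min_n = min_n)
  opt <- optimal_threshold(sweep)
  rich <- richness_threshold(sweep)
  lab_ids <- S$specimen_id[S$species_label != .UNKNOWN]
  phy <- mono <- sup <- NULL
  if (tree && length(lab_ids) >= 3) {
    dl <- D$d[lab_ids, lab_ids]
    if (anyNA(dl[upper.tri(dl)])) {
      warning("undefined distances among labeled specimens; ",
              "skipping tree construction")
    } else {
      Dlab <- structure(list(ids = lab_ids, d = dl, metric = metric),
                        class = "barcode_dist")
      phy <- nj_tree(Dlab)
      mono <- monophyly(phy, S)
      if (bootstrap > 0)
        sup <- bootstrap_support(aln, S, B = bootstrap, seed = seed,
                                 metric = metric)
    }
  }
  unknowns <- NULL
  if (any(S$species_label == .UNKNOWN) &&
      any(S$species_label != .UNKNOWN))
    unknowns <- assign_unknowns(D, S, threshold = inter_cut)
  loc <- reg <- NULL
  if (!is.null(focal_region)) {
    loc <- tryCatch(
      locality_permutation_test(D, S, focal_region, n_perm = n_perm,
                                seed = seed),
      error = function(e) {
        warning("locality test skipped: ", conditionMessage(e))
        NULL
      })
    Sf <- S[S$region == focal_region | S$species_label == .UNKNOWN, ]
    reg <- tryCatch({
      ssf <- species_summaries(D, Sf[Sf$species_label != .UNKNOWN, ])
      regress_n_vs_maxintra(ssf)
    }, error = function(e) {
      warning("sample-size regression skipped: ", conditionMessage(e))
      NULL
    })
  }
  structure(list(qc = qc$report, composition = comp, distances = D,
                 haplotypes = hap, summaries = ss, flags = flags,
                 histogram = hist, tree = phy, monophyly = mono,
                 support = sup, sweep = sweep, optimal = opt,
                 richness = rich, unknowns = unknowns,
                 locality_test = loc, regression = reg,
                 specimens = S, call = match.call(),
                 settings = list(metric = metric, min_len = min_len,
                                 max_n_frac = max_n_frac,
                                 intra_cut = intra_cut,
                                 inter_cut = inter_cut,
                                 bin_width = bin_width, grid = grid,
                                 min_n = min_n, bootstrap = bootstrap,
                                 focal_region = focal_region,
                                 n_perm = n_perm, seed = seed)),
            class = "barcode_gap")
}

#' @export
print.barcode_gap <- function(x, ...) {
  cat("Barcode-gap species-limits analysis (", x$distances$metric,
      " distances)\n", sep = "")
  cat(sprintf("  %d specimens retained (%d removed by QC), %d species\n",
              length(x$distances$ids), attr(x$qc, "removed"),
              nrow(x$summaries)))
  cat(sprintf("  optimal threshold %.1f%% (success %.1f%%); richness threshold %.1f%%\n",
              x$optimal$threshold, x$optimal$success_rate,
              x$richness$threshold))
  if (!is.null(x$monophyly)) {
    nm <- sum(x$monophyly$status == "monophyletic")
    cat(sprintf("  %d/%d species monophyletic on the NJ tree\n",
                nm, nrow(x$monophyly)))
  }
  invisible(x)
}

#' @export
summary.barcode_gap <- function(object, ...) {
  x <- object
  print(x)
  ok <- !is.na(x$summaries$max_intra)
  cat(sprintf("  max intraspecific: range %.2f-%.2f%% (mean of maxima %.2f%%), %d species with n >= 2\n",
              min(x$summaries$max_intra[ok]),
              max(x$summaries$max_intra[ok]),
              mean(x$summaries$max_intra[ok]), sum(ok)))
  oi <- !is.na(x$summaries$min_inter)
  cat(sprintf("  nearest-neighbour interspecific: range %.2f-%.2f%% (mean %.2f%%)\n",
              min(x$summaries$min_inter[oi]),
              max(x$summaries$min_inter[oi]),
              mean(x$summaries$min_inter[oi])))
  flagged <- x$flags$species[x$flags$flags != ""]
  cat("  flagged taxa:", if (length(flagged))
    paste(flagged, collapse = ", ") else "none", "\n")
  if (!is.null(x$support)) {
    hi <- sum(x$support$support >= 0.95)
    cat(sprintf("  bootstrap: %d/%d species with support >= 95%% (B = %d)\n",
                hi, nrow(x$support), attr(x$support, "B")))
  }
  if (!is.null(x$locality_test))
    cat(sprintf("  locality permutation test: observed diff %.3f%%, one-tailed p = %.3f\n",
                x$locality_test$observed, x$locality_test$p_value))
  if (!is.null(x$regression))
    cat(sprintf("  max-intra ~ n regression: R^2 = %.3f, p = %.3g, slope %.4f\n",
                x$regression$r_squared, x$regression$p_value,
                x$regression$slope))
  invisible(x)
}

#' Plot a barcode-gap analysis
#'
#' Two base-graphics panels: the barcode-gap histogram (maximum
#' intraspecific vs nearest-neighbour distances) and the threshold
#' sweep (lumped/split counts and the success curve, with the optimal
#' threshold marked).
#'
#' @param x A `barcode_gap` object.
#' @param ... Unused.
#' @export
plot.barcode_gap <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  h <- x$histogram
  mids <- (h$bin_lo + h$bin_hi) / 2
  ylim <- c(0, max(h$intra_count, h$inter_count))
  graphics::plot(mids, h$intra_count, type = "h", lwd = 4,
                 col = "steelblue", xlab = "distance (%)",
                 ylab = "species", main = "barcode gap", ylim = ylim)
  graphics::lines(mids + 0.05, h$inter_count, type = "h", lwd = 4,
                  col = "tomato")
  graphics::legend("topright", c("max intra", "min inter (NN)"),
                   fill = c("steelblue", "tomato"), bty = "n")
  sw <- x$sweep
  graphics::plot(sw$threshold, sw$n_lumped, type = "b", pch = 1,
                 col = "tomato", xlab = "threshold (%)",
                 ylab = "species in error",
                 ylim = c(0, max(sw$n_lumped, sw$n_split)),
                 main = "threshold sweep")
  graphics::lines(sw$threshold, sw$n_split, type = "b", pch = 2,
                  col = "steelblue")
  graphics::par(new = TRUE)
  graphics::plot(sw$threshold, sw$success_rate, type = "l", lwd = 2,
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 100))
  graphics::axis(4)
  graphics::mtext("success (%)", side = 4, line = 2.5)
  graphics::abline(v = x$optimal$threshold, lty = 3)
  graphics::legend("right", c("lumped", "split", "success"),
                   col = c("tomato", "steelblue", "black"),
                   pch = c(1, 2, NA), lty = c(1, 1, 1), bty = "n")
  invisible(x)
}

#' Run the full pipeline and write a report bundle
#'
#' Orchestrates the workflow over files on disk: reads the alignment and
#' specimen table, fits [barcode_gap()], optionally replays a
#' reassessment change set and regenerates the pre/post table, and
#' writes every result as TSV/Newick into `outdir` together with a
#' run log (settings, seed, package version, input checksums).  A stage
#' failure halts with a stage-named diagnostic; outputs written before
#' the failure are retained.
#'
#' @param fasta,specimens Input paths (aligned FASTA; specimen TSV).
#' @param outdir Output directory (created if needed).
#' @param changeset Optional change-set TSV to replay.
#' @param ... Further arguments passed to [barcode_gap()]
#'   (e.g. `metric`, `bootstrap`, `focal_region`, `seed`).
#' @return The fitted `barcode_gap` object, invisibly.
#' @export
run_pipeline <- function(fasta, specimens, outdir, changeset = NULL,
                         ...) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  aln <- stage("read", read_alignment(fasta))
  S <- stage("read", read_specimens(specimens, alignment = aln))
  fit <- stage("analyse", barcode_gap(aln, S, ...))
  out <- function(f) file.path(outdir, f)
  utils::write.table(fit$qc, out("qc_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(base = c("A", "T", "C", "G", "A+T", "C+G"),
               percent = round(c(fit$composition$A, fit$composition$T,
                                 fit$composition$C, fit$composition$G,
                                 fit$composition$AT,
                                 fit$composition$CG), 1)),
    out("composition.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_distance_matrix(fit$distances, out("distances.tsv"),
                        flagged_path = out("distances_flagged.tsv"))
  write_summaries(fit$summaries, out("species_summaries.tsv"),
                  flags = fit$flags)
  utils::write.table(fit$histogram, out("gap_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_sweep(fit$sweep, out("threshold_sweep.tsv"))
  if (!is.null(fit$tree)) {
    stage("tree", write_tree_newick(fit$tree, out("nj_tree.nwk"),
                                    support = fit$support,
                                    S = fit$specimens))
    utils::write.table(fit$monophyly, out("monophyly.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(fit$support))
      utils::write.table(fit$support, out("bootstrap_support.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fit$unknowns))
    utils::write.table(fit$unknowns, out("unknown_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(changeset)) {
    cs <- stage("reassess", read_changeset(changeset))
    S_post <- stage("reassess", apply_changes(fit$specimens, cs))
    outcomes <- NULL
    pp <- stage("reassess",
                pre_post_table(fit$distances, fit$specimens, S_post))
    utils::write.table(pp, out("pre_post_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_specimens(S_post, out("specimens_post.tsv"))
  }
  stats_lines <- character(0)
  if (!is.null(fit$locality_test))
    stats_lines <- c(stats_lines, sprintf(
      "locality_permutation\tobserved=%.4f\tp=%.4f\tn_species=%d\tn_perm=%d",
      fit$locality_test$observed, fit$locality_test$p_value,
      fit$locality_test$n_species, fit$locality_test$n_perm))
  if (!is.null(fit$regression))
    stats_lines <- c(stats_lines, sprintf(
      "regression_n_vs_maxintra\tR2=%.4f\tp=%.4g\tslope=%.5f\tn_species=%d",
      fit$regression$r_squared, fit$regression$p_value,
      fit$regression$slope, fit$regression$n_species))
  if (length(stats_lines))
    writeLines(stats_lines, out("stats.tsv"))
  cfg <- fit$settings
  cfg$fasta <- fasta
  cfg$specimens <- specimens
  cfg$changeset <- changeset
  cfg$checksums <- as.list(tools::md5sum(c(fasta, specimens)))
  cfg$package_version <-
    as.character(utils::packageVersion("barcodegap"))
  jsonlite::write_json(cfg, out("run_config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(fit)
}
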