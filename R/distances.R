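# Pairwise K2P and p-distances under pairwise deletion.
#
# A column contributes to a pair only when both sequences carry an
# unambiguous base there; gaps, Ns and IUPAC ambiguity codes are missing.
# Distances are held internally as proportions; user-facing tables report
# percent.

# purine/pyrimidine class for the A,C,G,T encoding (1..4)
.BASE_CLASS <- c(1L, 2L, 1L, 2L)

.as_chars <- function(x) {
  if (length(x) == 1 && nchar(x) > 1) x <- strsplit(x, "")[[1]]
  toupper(as.character(x))
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Counts transition (`P`) and transversion (`Q`) proportions over the
#' columns where both sequences carry an unambiguous base (pairwise
#' deletion) and applies
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#'
#' @param x,y Aligned sequences of equal length: character vectors or
#'   single strings.
#' @return List with `distance` (proportion), `P`, `Q` and `n`
#'   (comparable sites).  Errors if no site is comparable or if either
#'   logarithm argument is non-positive (saturated pair: the distance is
#'   undefined rather than clamped).
#' @examples
#' pair_k2p("AATT", "AGTT")
#' @export
pair_k2p <- function(x, y) {
  x <- .as_chars(x); y <- .as_chars(y)
  if (length(x) != length(y)) stop("sequences differ in length")
  bx <- match(x, .BASES); by <- match(y, .BASES)
  ok <- !is.na(bx) & !is.na(by)
  n <- sum(ok)
  if (n == 0) stop("no comparable sites: distance undefined")
  diff <- ok & bx != by
  same_class <- .BASE_CLASS[bx] == .BASE_CLASS[by]
  P <- sum(diff & same_class) / n
  Q <- sum(diff & !same_class) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("saturated pair: K2P distance undefined (log argument <= 0)")
  list(distance = -0.5 * log(w1) - 0.25 * log(w2) + 0, P = P, Q = Q,
       n = n)
}

#' p-distance between two aligned sequences
#'
#' Proportion of mismatches over comparable sites (pairwise deletion).
#'
#' @inheritParams pair_k2p
#' @return List with `distance` and `n`.
#' @export
pair_p <- function(x, y) {
  x <- .as_chars(x); y <- .as_chars(y)
  if (length(x) != length(y)) stop("sequences differ in length")
  bx <- match(x, .BASES); by <- match(y, .BASES)
  ok <- !is.na(bx) & !is.na(by)
  n <- sum(ok)
  if (n == 0) stop("no comparable sites: distance undefined")
  list(distance = sum(ok & bx != by) / n, n = n)
}

# All-pairs transition/transversion/comparable-site counts via 0/1
# indicator cross-products; `w` optionally reweights alignment columns
# (used by the bootstrap, which resamples columns with replacement).
.pair_counts <- function(enc, w = NULL) {
  n <- nrow(enc)
  ind <- lapply(1:4, function(b) {
    x <- enc == b
    storage.mode(x) <- "double"
    x
  })
  wt <- function(I) if (is.null(w)) I else I * rep(w, each = n)
  ts <- ind[[1]] %*% t(wt(ind[[3]])) + ind[[3]] %*% t(wt(ind[[1]])) +
        ind[[2]] %*% t(wt(ind[[4]])) + ind[[4]] %*% t(wt(ind[[2]]))
  same <- Reduce(`+`, lapply(1:4, function(b) ind[[b]] %*% t(wt(ind[[b]]))))
  pres <- ind[[1]] + ind[[2]] + ind[[3]] + ind[[4]]
  tot <- pres %*% t(wt(pres))
  list(ts = ts, tv = tot - same - ts, n = tot)
}

# Distance matrix from precomputed counts; shared by distance_matrix()
# and the bootstrap.
.dist_from_counts <- function(cc, metric) {
  n <- cc$n
  if (metric == "K2P") {
    P <- cc$ts / n
    Q <- cc$tv / n
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    d <- suppressWarnings(-0.5 * log(w1) - 0.25 * log(w2)) + 0 # +0 clears IEEE -0
    saturated <- n > 0 & (w1 <= 0 | w2 <= 0)
    d[saturated] <- NA_real_
  } else {
    d <- (cc$ts + cc$tv) / n
    saturated <- matrix(FALSE, nrow(n), ncol(n))
  }
  d[n == 0] <- NA_real_
  diag(d) <- 0
  list(d = d, saturated = saturated)
}

#' All-pairs distance matrix
#'
#' Computes every unordered pair under pairwise deletion.  Pairs whose
#' distance is undefined (no comparable site, or K2P saturation) are kept
#' as `NA` entries with a warning rather than aborting the matrix.
#'
#' @param aln A `barcode_aln` with at least two sequences.
#' @param metric `"K2P"` (default) or `"p"`.
#' @return An object of class `barcode_dist`: list with `ids`, `d`
#'   (symmetric matrix of proportions, zero diagonal, `NA` where
#'   undefined), `n_sites` (comparable columns per pair), `saturated`
#'   (logical matrix) and `metric`.
#' @export
distance_matrix <- function(aln, metric = c("K2P", "p")) {
  metric <- match.arg(metric)
  if (length(aln$ids) < 2) stop("need at least 2 sequences")
  enc <- .encode_aln(aln)
  cc <- .pair_counts(enc)
  dd <- .dist_from_counts(cc, metric)
  d <- dd$d
  dimnames(d) <- list(aln$ids, aln$ids)
  bad <- sum(is.na(d[upper.tri(d)]))
  if (bad > 0)
    warning(bad, " pair(s) with undefined ", metric,
            " distance flagged as NA")
  structure(list(ids = aln$ids, d = d, n_sites = cc$n,
                 saturated = dd$saturated, metric = metric),
            class = "barcode_dist")
}

#' @export
print.barcode_dist <- function(x, ...) {
  cat("Pairwise", x$metric, "distance matrix:", length(x$ids),
      "specimens\n")
  off <- x$d[upper.tri(x$d)]
  cat(sprintf("  range %.2f%% - %.2f%% (%d undefined pairs)\n",
              100 * min(off, na.rm = TRUE), 100 * max(off, na.rm = TRUE),
              sum(is.na(off))))
  invisible(x)
}

# connected components of a logical adjacency matrix (indices)
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Collapse specimens into haplotypes
#'
#' Within each species, haplotypes are the connected components of the
#' zero-distance graph, so sequences differing only by missing data are
#' not split artificially.  Specimens with undefined within-species
#' distances fall into their own component (with a warning).
#'
#' @param D A `barcode_dist`.
#' @param S Specimen data frame (see [read_specimens()]); `UNKNOWN`
#'   specimens are skipped.
#' @return List with `assignments` (specimen, species, haplotype index)
#'   and `per_species` (species, n_specimens, n_haplotypes).
#' @export
collapse_haplotypes <- function(D, S) {
  S <- S[S$species_label != .UNKNOWN & S$specimen_id %in% D$ids, ]
  sp_list <- split(S$specimen_id, S$species_label)
  hap <- 0L
  assign_rows <- list()
  per_species <- data.frame(species = names(sp_list),
                            n_specimens = lengths(sp_list),
                            n_haplotypes = 0L,
                            stringsAsFactors = FALSE, row.names = NULL)
  warned <- FALSE
  for (k in seq_along(sp_list)) {
    ids <- sp_list[[k]]
    sub <- D$d[ids, ids, drop = FALSE]
    if (anyNA(sub) && !warned) {
      warning("undefined within-species distance(s); affected specimens ",
              "isolated into their own haplotype")
      warned <- TRUE
    }
    adj <- !is.na(sub) & sub == 0
    diag(adj) <- TRUE
    comp <- .components(adj)
    assign_rows[[k]] <- data.frame(specimen_id = ids,
                                   species = names(sp_list)[k],
                                   haplotype = hap + comp,
                                   stringsAsFactors = FALSE)
    per_species$n_haplotypes[k] <- max(comp)
    hap <- hap + max(comp)
  }
  list(assignments = do.call(rbind, c(assign_rows,
                                      list(make.row.names = FALSE))),
       per_species = per_species)
}

#' Write a distance matrix to disk
#'
#' @param D A `barcode_dist`.
#' @param path Output path.
#' @param format `"square"` (tab-delimited, percent to 2 decimals) or
#'   `"phylip"` (lower-triangle PHYLIP style, proportions).
#' @param flagged_path Optional sidecar TSV listing pairs with undefined
#'   distances and the reason.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path, format = c("square", "phylip"),
                                  flagged_path = NULL) {
  format <- match.arg(format)
  if (format == "square") {
    m <- round(100 * D$d, 2)
    df <- data.frame(specimen_id = D$ids, m, check.names = FALSE)
    colnames(df) <- c("specimen_id", D$ids)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(D$ids)), con)
    for (i in seq_along(D$ids)) {
      row <- if (i > 1)
        paste(sprintf("%.6f", D$d[i, seq_len(i - 1)]), collapse = " ")
      else ""
      writeLines(trimws(paste(sprintf("%-10s", D$ids[i]), row)), con)
    }
  }
  if (!is.null(flagged_path)) {
    bad <- which(is.na(D$d) & upper.tri(D$d), arr.ind = TRUE)
    flags <- data.frame(
      id1 = D$ids[bad[, 1]], id2 = D$ids[bad[, 2]],
      reason = ifelse(D$n_sites[bad] == 0, "no_comparable_sites",
                      "saturated"),
      stringsAsFactors = FALSE)
    utils::write.table(flags, flagged_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
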