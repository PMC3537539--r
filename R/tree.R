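# Neighbour-joining tree construction, column-resampling bootstrap, and
# per-species monophyly assessment on the unrooted tree.
#
# NJ is implemented here (rather than delegated) because the analysis
# pins down reproducibility details: ids are sorted lexicographically
# before agglomeration, ties in the Q criterion break toward the lowest
# index pair, and a negative branch length is set to zero with the
# deficit moved to the sister branch so path lengths are preserved.

# Saitou-Nei agglomeration with the Studier-Keppler Q criterion.
# Returns the newick string plus the leaf set behind each internal edge
# (exactly n - 3 of them), which is what the bootstrap consumes.
.nj_core <- function(d, labels) {
  ord <- order(labels)
  d <- d[ord, ord, drop = FALSE]
  labels <- labels[ord]
  n <- length(labels)
  if (n < 3) stop("need at least 3 taxa")
  if (anyNA(d[upper.tri(d)]))
    stop("undefined distances in matrix; exclude or impute upstream")
  fmt <- function(v) sprintf("%.15g", v)
  nwk <- labels
  sets <- as.list(labels)
  clusters <- list()
  D <- d
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    dij <- D[i, j]
    li <- 0.5 * dij + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    dnew <- 0.5 * (D[i, ] + D[j, ] - dij)
    keep <- setdiff(seq_len(m), c(i, j))
    newlab <- paste0("(", nwk[i], ":", fmt(li), ",", nwk[j], ":",
                     fmt(lj), ")")
    newset <- c(sets[[i]], sets[[j]])
    clusters[[length(clusters) + 1L]] <- sort(newset)
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nwk <- c(nwk[keep], newlab)
    sets <- c(sets[keep], list(newset))
  }
  dab <- D[1, 2]; dac <- D[1, 3]; dbc <- D[2, 3]
  la <- (dab + dac - dbc) / 2
  lb <- dab - la
  lc <- dac - la
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  newick <- paste0("(", nwk[1], ":", fmt(la), ",", nwk[2], ":", fmt(lb),
                   ",", nwk[3], ":", fmt(lc), ");")
  list(newick = newick, clusters = clusters, labels = labels)
}

#' Neighbour-joining tree
#'
#' Builds the unrooted NJ tree from a distance matrix.  Deterministic:
#' taxa are sorted lexicographically and Q-criterion ties break toward
#' the lowest index pair, so the same matrix always yields the same tree.
#' Negative branch lengths are zeroed with the deficit shifted to the
#' sister branch, preserving path lengths.
#'
#' @param D A `barcode_dist`, or a symmetric numeric matrix with
#'   dimnames.  All pairwise distances must be defined.
#' @return An [ape::read.tree()] `phylo` object (branch lengths in the
#'   units of `D`, i.e. proportions for a `barcode_dist`).
#' @export
nj_tree <- function(D) {
  if (inherits(D, "barcode_dist")) {
    d <- D$d
    labels <- D$ids
  } else {
    d <- as.matrix(D)
    labels <- rownames(d)
    if (is.null(labels)) stop("distance matrix needs dimnames")
  }
  res <- .nj_core(d, labels)
  ape::read.tree(text = res$newick)
}

# canonical key for a set of ids (bipartition membership tests)
.set_key <- function(ids) paste(sort(ids), collapse = "\r")

#' Bootstrap support for species clusters
#'
#' Felsenstein column bootstrap: each replicate resamples alignment
#' columns with replacement, recomputes the distance matrix and the NJ
#' tree, and scores, for every species, whether some edge bipartition
#' separates exactly that species' specimens from everything else.
#' Support is the fraction of retained replicates containing the
#' bipartition.  Replicates with undefined distances are dropped and
#' counted; more than 10% dropped aborts with diagnostics.  Each
#' replicate runs on its own RNG substream derived from `(seed,
#' replicate)`, so results do not depend on evaluation order.
#'
#' @param aln A `barcode_aln`.
#' @param S Specimen data frame; `UNKNOWN` specimens are excluded.
#' @param B Number of replicates (default 1000).
#' @param seed Integer seed (default 1).
#' @param metric `"K2P"` or `"p"`.
#' @return Data frame with `species`, `n_specimens`, `support` (in
#'   `[0, 1]`); attributes `B` and `dropped`.
#' @export
bootstrap_support <- function(aln, S, B = 1000, seed = 1,
                              metric = c("K2P", "p")) {
  metric <- match.arg(metric)
  stopifnot(B >= 1, aln$length >= 1)
  Slab <- S[S$species_label != .UNKNOWN & S$specimen_id %in% aln$ids, ]
  sub <- aln[Slab$specimen_id]
  ids <- sub$ids
  if (length(ids) < 3) stop("need at least 3 labeled specimens")
  enc <- .encode_aln(sub)
  L <- sub$length
  sp_sets <- split(ids, Slab$species_label)
  sp_keys <- vapply(sp_sets, .set_key, character(1))
  comp_keys <- vapply(sp_sets, function(s) .set_key(setdiff(ids, s)),
                      character(1))
  trivial <- lengths(sp_sets) <= 1 | lengths(sp_sets) >= length(ids) - 1
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, B)
  hits <- integer(length(sp_sets))
  dropped <- 0L
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    w <- tabulate(sample.int(L, L, replace = TRUE), L)
    cc <- .pair_counts(enc, w)
    dd <- .dist_from_counts(cc, metric)
    if (anyNA(dd$d[upper.tri(dd$d)])) {
      dropped <- dropped + 1L
      next
    }
    dimnames(dd$d) <- list(ids, ids)
    res <- .nj_core(dd$d, ids)
    keys <- vapply(res$clusters, .set_key, character(1))
    hits <- hits + (trivial | sp_keys %in% keys | comp_keys %in% keys)
  }
  if (dropped > 0.1 * B)
    stop("bootstrap aborted: ", dropped, " of ", B,
         " replicates had undefined distances; ",
         "filter short/saturated sequences upstream")
  kept <- B - dropped
  out <- data.frame(species = names(sp_sets),
                    n_specimens = lengths(sp_sets),
                    support = hits / kept,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$species), ]
  rownames(out) <- NULL
  attr(out, "B") <- B
  attr(out, "dropped") <- dropped
  out
}

#' Species monophyly on an unrooted tree
#'
#' A species is monophyletic when some edge bipartition isolates exactly
#' its specimens (no outgroup is assumed; the NJ tree is unrooted).  For
#' non-monophyletic species the number of maximal all-conspecific clades
#' is counted after rooting on the longest edge.  Singletons are
#' trivially monophyletic and flagged as such.
#'
#' @param phy A `phylo` tree whose tips are specimen ids.
#' @param S Specimen data frame labelling every tip (`UNKNOWN` tips are
#'   not allowed; drop them before tree building).
#' @return Data frame with `species`, `n_specimens`, `status`
#'   (`"monophyletic"`/`"non-monophyletic"`), `n_clades`, `singleton`.
#' @export
monophyly <- function(phy, S) {
  tips <- phy$tip.label
  lab <- S$species_label[match(tips, S$specimen_id)]
  if (anyNA(lab)) stop("unlabeled tips: ",
                       paste(tips[is.na(lab)], collapse = ", "))
  if (any(lab == .UNKNOWN))
    stop("UNKNOWN tips present; exclude them before monophyly assessment")
  names(lab) <- tips
  sp_sets <- split(tips, lab)
  n <- length(tips)
  # bipartitions present in the tree (clades of the stored orientation)
  parts <- ape::prop.part(phy)
  part_keys <- vapply(parts, function(p) .set_key(tips[p]), character(1))
  comp_part_keys <- vapply(parts, function(p) .set_key(tips[-p]),
                           character(1))
  clade_counts <- .max_conspecific_clades(phy, lab)
  rows <- lapply(names(sp_sets), function(sp) {
    set <- sp_sets[[sp]]
    k <- length(set)
    mono <- k == 1 || k == n ||
      .set_key(set) %in% c(part_keys, comp_part_keys)
    data.frame(species = sp, n_specimens = k,
               status = if (mono) "monophyletic" else "non-monophyletic",
               n_clades = if (mono) 1L else clade_counts[[sp]],
               singleton = k == 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Root the tree on its longest edge and count, per species, the maximal
# clades whose tips all belong to that species.
.max_conspecific_clades <- function(phy, lab) {
  nt <- length(phy$tip.label)
  E <- phy$edge
  nb <- vector("list", max(E))
  for (k in seq_len(nrow(E))) {
    nb[[E[k, 1]]] <- c(nb[[E[k, 1]]], E[k, 2])
    nb[[E[k, 2]]] <- c(nb[[E[k, 2]]], E[k, 1])
  }
  len <- phy$edge.length
  if (is.null(len)) len <- rep(1, nrow(E))
  e <- which.max(len)
  counts <- structure(integer(length(unique(lab))),
                      names = sort(unique(lab)))
  # returns the species if the subtree under `node` is pure, else NA,
  # crediting maximal pure child subtrees of mixed nodes as it unwinds
  dfs <- function(node, parent) {
    if (node <= nt) return(lab[node])
    subs <- vapply(setdiff(nb[[node]], parent),
                   function(ch) dfs(ch, node), character(1))
    u <- unique(subs)
    if (length(u) == 1 && !is.na(u)) return(u)
    for (s in subs) if (!is.na(s)) counts[s] <<- counts[s] + 1L
    NA_character_
  }
  a <- E[e, 1]; b <- E[e, 2]
  top_a <- dfs(a, b)
  top_b <- dfs(b, a)
  if (!is.na(top_a)) counts[top_a] <- counts[top_a] + 1L
  if (!is.na(top_b)) counts[top_b] <- counts[top_b] + 1L
  if (!is.na(top_a) && !is.na(top_b) && top_a == top_b)
    counts[top_a] <- 1L # whole tree one species
  counts
}

#' Write an NJ tree with per-species support as Newick
#'
#' Internal nodes whose clade corresponds exactly to a species with a
#' bootstrap support value are labelled with that support (percent).
#'
#' @param phy A `phylo` object.
#' @param path Output path.
#' @param support Optional data frame from [bootstrap_support()].
#' @param S Specimen table (required when `support` is given).
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(phy, path, support = NULL, S = NULL) {
  if (!is.null(support)) {
    if (is.null(S)) stop("`S` required to map support onto nodes")
    tips <- phy$tip.label
    lab <- S$species_label[match(tips, S$specimen_id)]
    parts <- ape::prop.part(phy)
    node_lab <- rep("", phy$Nnode)
    sp_keys <- vapply(split(tips, lab), .set_key, character(1))
    sup <- structure(support$support, names = support$species)
    for (i in seq_along(parts)) {
      key <- .set_key(tips[parts[[i]]])
      hit <- names(sp_keys)[sp_keys == key]
      if (length(hit) == 1 && hit %in% names(sup))
        node_lab[i] <- sprintf("%.0f", 100 * sup[[hit]])
    }
    phy$node.label <- node_lab
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}
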