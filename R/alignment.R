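# Alignment container and sequence-level quality control.
#
# Sequences are stored as an uppercase character matrix (specimens x columns)
# over {A,C,G,T,N,-} plus IUPAC ambiguity codes.  Everything outside A/C/G/T
# is treated as missing for composition and distance purposes; '-' is a gap
# (not a sequenced base) and is distinguished only by the QC length count.

.BASES <- c("A", "C", "G", "T")
.UNKNOWN <- "UNKNOWN"

#' Construct an alignment object
#'
#' Low-level constructor used by [read_alignment()] and the synthetic-data
#' generator.  Most users read alignments from FASTA instead.
#'
#' @param seqmat Character matrix, one row per specimen, one column per
#'   alignment position, uppercase.
#' @param ids Character vector of unique specimen identifiers
#'   (defaults to `rownames(seqmat)`).
#' @return An object of class `barcode_aln` with elements `ids`, `seq`
#'   (the character matrix) and `length` (number of columns).
#' @export
new_alignment <- function(seqmat, ids = rownames(seqmat)) {
  if (!is.matrix(seqmat) || !is.character(seqmat))
    stop("`seqmat` must be a character matrix")
  if (is.null(ids) || length(ids) != nrow(seqmat))
    stop("alignment requires one id per sequence")
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate specimen ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rownames(seqmat) <- ids
  structure(list(ids = ids, seq = seqmat, length = ncol(seqmat)),
            class = "barcode_aln")
}

#' Read a pre-aligned FASTA file
#'
#' Reads an aligned nucleotide FASTA (the barcode matrix must be aligned
#' upstream; no alignment is performed here).  Sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A `barcode_aln` object.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGTACGT", ">s2", "ACGTACGA"), fa)
#' aln <- read_alignment(fa)
#' aln$length
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE)
  if (length(recs) == 0) stop("no sequences found in ", path)
  ids <- names(recs)
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- vapply(recs, length, integer(1))
  if (length(unique(lens)) > 1) {
    mode_len <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    bad <- ids[lens != mode_len]
    stop("ragged alignment (expected ", mode_len, " columns): ",
         paste(bad, collapse = ", "))
  }
  m <- matrix(toupper(unlist(recs, use.names = FALSE)),
              nrow = length(recs), byrow = TRUE)
  new_alignment(m, ids)
}

#' Write an alignment to FASTA
#'
#' @param aln A `barcode_aln` object.
#' @param path Output path; sequences are wrapped at 80 columns.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- lapply(seq_len(nrow(aln$seq)), function(i) aln$seq[i, ])
  seqinr::write.fasta(seqs, names = aln$ids, file.out = path, nbchar = 80)
  invisible(path)
}

#' @export
print.barcode_aln <- function(x, ...) {
  cat("Barcode alignment:", length(x$ids), "sequences x", x$length,
      "columns\n")
  invisible(x)
}

#' Subset an alignment by specimen id
#'
#' @param x A `barcode_aln`.
#' @param i Character vector of specimen ids (or integer/logical index).
#' @param ... Unused.
#' @export
`[.barcode_aln` <- function(x, i, ...) {
  if (is.character(i)) {
    i <- match(i, x$ids)
    if (anyNA(i)) stop("unknown specimen id(s) in alignment subset")
  }
  new_alignment(x$seq[i, , drop = FALSE], x$ids[i])
}

# Integer encoding used by the distance machinery: A=1, C=2, G=3, T=4,
# anything else (gap, N, IUPAC ambiguity) = 0 / missing.
.encode_aln <- function(aln) {
  code <- match(aln$seq, .BASES)
  code[is.na(code)] <- 0L
  matrix(as.integer(code), nrow = nrow(aln$seq),
         dimnames = list(aln$ids, NULL))
}

# ---------------------------------------------------------------------------
# Specimen metadata

#' Read a specimen metadata table
#'
#' Tab-separated table with header
#' `specimen_id  species_label  sex  region`.  Specimens without a
#' morphological determination carry the label `"UNKNOWN"`.
#'
#' @param path Path to a TSV file.
#' @param alignment Optional `barcode_aln`; if given, the table is checked
#'   to cover exactly the alignment's ids.
#' @return A data frame with the four columns above.
#' @export
read_specimens <- function(path, alignment = NULL) {
  S <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("specimen_id", "species_label", "sex", "region")
  if (!all(need %in% names(S)))
    stop("specimen table must have columns: ", paste(need, collapse = ", "))
  S <- S[, need]
  if (anyDuplicated(S$specimen_id))
    stop("duplicate specimen ids in ", path)
  if (!is.null(alignment)) check_specimens(alignment, S)
  S
}

#' Write a specimen metadata table
#'
#' @param S Specimen data frame (see [read_specimens()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(S, path) {
  utils::write.table(S, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that a specimen table matches an alignment
#'
#' Errors unless every alignment id occurs exactly once in the table.
#'
#' @param aln A `barcode_aln`.
#' @param S Specimen data frame.
#' @return `TRUE`, invisibly.
#' @export
check_specimens <- function(aln, S) {
  missing_ids <- setdiff(aln$ids, S$specimen_id)
  if (length(missing_ids))
    stop("specimens absent from metadata: ",
         paste(missing_ids, collapse = ", "))
  if (anyDuplicated(S$specimen_id))
    stop("duplicate specimen ids in metadata")
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Quality control

#' Sequence quality filter
#'
#' Retains sequences of at least `min_len` sequenced bases whose fraction of
#' missing nucleotides (Ns and other ambiguity codes) is below `max_n_frac`.
#' The length counts non-gap columns (including Ns); the missing fraction
#' uses that same length as denominator, so "1% missing" refers to the
#' sequence itself, not to alignment columns.
#'
#' @param aln A `barcode_aln`.
#' @param min_len Minimum sequenced length in bp (default 600; a 600 bp
#'   sequence passes, 599 does not).
#' @param max_n_frac Maximum tolerated missing fraction (default 0.01,
#'   strict: a fraction equal to the cutoff fails).
#' @return A list with `alignment` (the retained `barcode_aln`) and
#'   `report`, a data frame with one row per input specimen: sequenced
#'   length, missing count and fraction, stop-codon summary (see
#'   [check_translation()]), pass flag and removal reason.
#' @export
qc_filter <- function(aln, min_len = 600, max_n_frac = 0.01) {
  stopifnot(min_len > 0, max_n_frac >= 0, max_n_frac <= 1)
  m <- aln$seq
  not_gap <- matrix(m != "-", nrow(m))
  is_base <- matrix(m %in% .BASES, nrow(m))
  ungapped <- rowSums(not_gap)
  n_missing <- rowSums(not_gap & !is_base)
  n_frac <- ifelse(ungapped > 0, n_missing / ungapped, 1)
  tr <- check_translation(aln)
  pass <- ungapped >= min_len & n_frac < max_n_frac
  reason <- character(length(pass))
  reason[ungapped < min_len] <- sprintf("length < %d bp", min_len)
  reason[n_frac >= max_n_frac] <-
    trimws(paste(reason[n_frac >= max_n_frac],
                 sprintf("missing fraction >= %g", max_n_frac), sep = "; "))
  reason <- sub("^; ", "", reason)
  report <- data.frame(specimen_id = aln$ids,
                       ungapped_len = ungapped,
                       n_missing = n_missing,
                       n_frac = n_frac,
                       best_frame = tr$best_frame,
                       min_stops = tr$min_stops,
                       pass = pass,
                       reason = reason,
                       stringsAsFactors = FALSE, row.names = NULL)
  attr(report, "retained") <- sum(pass)
  attr(report, "removed") <- sum(!pass)
  if (!any(pass))
    warning("no sequences pass the quality filter; returning an empty alignment")
  list(alignment = aln[pass], report = report)
}

#' Reading-frame and stop-codon check
#'
#' Translates each ungapped sequence in the three forward frames under the
#' invertebrate mitochondrial code and reports the frame minimising the
#' number of stop codons (ties resolved toward the lowest frame).  Codons
#' containing missing bases translate as unknown (`X`), never as stops.
#' A specimen whose best frame still contains stops is flagged: a clean COI
#' barcode is expected to be stop-free in some frame.
#'
#' @param aln A `barcode_aln` with at least one sequence.
#' @param numcode NCBI genetic-code number (default 5, invertebrate
#'   mitochondrial).
#' @return Data frame with `specimen_id`, `best_frame` (1-3), `min_stops`,
#'   and logical `flagged`.
#' @export
check_translation <- function(aln, numcode = 5) {
  if (length(aln$ids) == 0) stop("empty alignment")
  res <- t(vapply(seq_along(aln$ids), function(i) {
    chars <- aln$seq[i, ]
    chars <- chars[chars != "-"]
    if (length(chars) < 3) return(c(1L, 0L))
    stops <- vapply(0:2, function(fr) {
      if (length(chars) - fr < 3) return(0L)
      aa <- seqinr::translate(chars, frame = fr, numcode = numcode,
                              ambiguous = TRUE)
      sum(aa == "*")
    }, integer(1))
    best <- which.min(stops) # ties -> lowest frame
    c(best, stops[best])
  }, integer(2)))
  data.frame(specimen_id = aln$ids,
             best_frame = res[, 1],
             min_stops = res[, 2],
             flagged = res[, 2] > 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean nucleotide composition
#'
#' Per-sequence base frequencies over non-missing sites, averaged across
#' sequences, as percentages.  Sequences with no scorable site are excluded
#' with a warning.
#'
#' @param aln A `barcode_aln` with at least one sequence.
#' @return An object of class `composition_summary`: a list with per-base
#'   percentages `A`, `T`, `C`, `G` and the pooled `AT` and `CG` values.
#' @export
composition <- function(aln) {
  if (length(aln$ids) == 0) stop("empty alignment")
  enc <- .encode_aln(aln)
  counts <- vapply(1:4, function(b) rowSums(enc == b),
                   numeric(nrow(enc)))
  counts <- matrix(counts, nrow = nrow(enc)) # specimens x ACGT
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    warning("excluding sequence(s) with no non-missing site: ",
            paste(aln$ids[tot == 0], collapse = ", "))
    counts <- counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  freq <- 100 * colMeans(counts / tot)
  out <- list(A = freq[1], C = freq[2], G = freq[3], T = freq[4],
              AT = freq[1] + freq[4], CG = freq[2] + freq[3],
              n_sequences = length(tot))
  class(out) <- "composition_summary"
  out
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf(
    "Mean nucleotide content (%d sequences): A %.1f%%  T %.1f%%  C %.1f%%  G %.1f%%  (A+T %.1f%%, C+G %.1f%%)\n",
    x$n_sequences, x$A, x$T, x$C, x$G, x$AT, x$CG))
  invisible(x)
}
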