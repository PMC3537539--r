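# Replayable taxonomic-reassessment change sets.
#
# Changes are data, never in-place edits: a change set is an ordered data
# frame that can be written to / read from TSV, applied to a specimen
# table, and audited afterwards, so every reassessment round is
# reproducible.

#' Build one reassessment change
#'
#' Actions:
#' * `RENAME`: relabel a species (`old` -> `new`).  With `specimens`
#'   given, only those specimens move (the misidentified-specimen case;
#'   the target label may already exist).  Without `specimens`, the whole
#'   label is renamed and renaming onto an existing label is an error
#'   (use `LUMP` for that intent).
#' * `SPLIT`: split `old` into `new` (two or more labels, comma
#'   separated) with `specimens` holding one semicolon-separated specimen
#'   list per new label; the lists must partition the species.
#' * `LUMP`: merge the labels in `old` (comma separated) into `new`.
#' * `EXCLUDE`: drop the listed `specimens` from the table.
#'
#' @param action One of `"RENAME"`, `"SPLIT"`, `"LUMP"`, `"EXCLUDE"`.
#' @param old,new Species labels (comma separated where several).
#' @param specimens Specimen ids: comma separated; for `SPLIT`,
#'   semicolons separate the per-label lists.
#' @param note Free-text audit note (e.g. the reassessment outcome).
#' @return One-row data frame; bind rows to form a change set.
#' @export
change <- function(action = c("RENAME", "SPLIT", "LUMP", "EXCLUDE"),
                   old = "", new = "", specimens = "", note = "") {
  action <- match.arg(action)
  data.frame(action = action, old = old, new = new,
             specimens = specimens, note = note,
             stringsAsFactors = FALSE)
}

.split_csv <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Apply a change set to a specimen table
#'
#' Changes are applied in order; each is validated against the current
#' state (referenced labels and specimens must exist, `SPLIT` lists must
#' partition the species).  The specimen count is conserved except under
#' `EXCLUDE`.
#'
#' @param S Specimen data frame.
#' @param cs Change-set data frame (rows built with [change()] or read
#'   with [read_changeset()]).
#' @return The new specimen table, with an `audit` attribute: one row
#'   per change listing the affected specimen ids.
#' @export
apply_changes <- function(S, cs) {
  out <- S
  audit <- character(nrow(cs))
  for (i in seq_len(nrow(cs))) {
    row <- cs[i, ]
    act <- row$action
    if (act == "RENAME") {
      if (!row$old %in% out$species_label)
        stop("RENAME: no such label: ", row$old)
      spec <- .split_csv(row$specimens)
      if (length(spec)) {
        bad <- spec[!(spec %in% out$specimen_id[
          out$species_label == row$old])]
        if (length(bad))
          stop("RENAME: specimens not in ", row$old, ": ",
               paste(bad, collapse = ", "))
        sel <- out$specimen_id %in% spec
      } else {
        if (row$new %in% out$species_label)
          stop("RENAME of whole label onto existing label '", row$new,
               "'; use LUMP if merging is intended")
        sel <- out$species_label == row$old
      }
      affected <- out$specimen_id[sel]
      out$species_label[sel] <- row$new
    } else if (act == "SPLIT") {
      news <- .split_csv(row$new)
      lists <- lapply(trimws(strsplit(row$specimens, ";",
                                      fixed = TRUE)[[1]]), .split_csv)
      if (length(news) < 2 || length(news) != length(lists))
        stop("SPLIT needs >= 2 new labels with one specimen list each")
      members <- out$specimen_id[out$species_label == row$old]
      if (!setequal(unlist(lists), members) ||
          anyDuplicated(unlist(lists)))
        stop("SPLIT lists do not partition species ", row$old)
      for (k in seq_along(news))
        out$species_label[out$specimen_id %in% lists[[k]]] <- news[k]
      affected <- members
    } else if (act == "LUMP") {
      olds <- .split_csv(row$old)
      missing_lab <- olds[!olds %in% out$species_label]
      if (length(missing_lab))
        stop("LUMP: no such label(s): ",
             paste(missing_lab, collapse = ", "))
      sel <- out$species_label %in% olds
      affected <- out$specimen_id[sel]
      out$species_label[sel] <- row$new
    } else { # EXCLUDE
      spec <- .split_csv(row$specimens)
      bad <- spec[!spec %in% out$specimen_id]
      if (length(bad))
        stop("EXCLUDE: no such specimen(s): ",
             paste(bad, collapse = ", "))
      affected <- spec
      out <- out[!out$specimen_id %in% spec, ]
    }
    audit[i] <- paste(affected, collapse = ",")
  }
  rownames(out) <- NULL
  attr(out, "audit") <- cbind(cs, affected = audit)
  out
}

#' Read / write a change-set TSV
#'
#' Columns: `action`, `old`, `new`, `specimens`, `note`.
#'
#' @param path File path.
#' @return The change-set data frame (`read_changeset`), or `path`
#'   invisibly (`write_changeset`).
#' @export
read_changeset <- function(path) {
  cs <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  need <- c("action", "old", "new", "specimens", "note")
  if (!all(need %in% names(cs)))
    stop("change set must have columns: ", paste(need, collapse = ", "))
  cs[, need]
}

#' @rdname read_changeset
#' @param cs Change-set data frame.
#' @export
write_changeset <- function(cs, path) {
  utils::write.table(cs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pre/post reassessment comparison table
#'
#' Recomputes species summaries under both labellings (same distance
#' matrix) and joins them by species label, mirroring the familiar
#' pre/post max-intraspecific / min-interspecific layout.  Labels absent
#' from one side (created or retired by the change set) get `NA` there.
#'
#' @param D A `barcode_dist` covering both tables.
#' @param S_pre,S_post Specimen tables before / after [apply_changes()].
#' @param outcomes Optional named character vector (species -> outcome
#'   text) used to fill the `outcome` column.
#' @return Data frame with `species`, `pre_max_intra`, `pre_min_inter`,
#'   `post_max_intra`, `post_min_inter`, `outcome`.
#' @export
pre_post_table <- function(D, S_pre, S_post, outcomes = NULL) {
  pre <- species_summaries(D, S_pre)
  post <- species_summaries(D, S_post[S_post$specimen_id %in% D$ids, ])
  species <- sort(union(pre$species, post$species))
  out <- data.frame(
    species = species,
    pre_max_intra = pre$max_intra[match(species, pre$species)],
    pre_min_inter = pre$min_inter[match(species, pre$species)],
    post_max_intra = post$max_intra[match(species, post$species)],
    post_min_inter = post$min_inter[match(species, post$species)],
    outcome = "",
    stringsAsFactors = FALSE)
  if (!is.null(outcomes)) {
    hit <- species %in% names(outcomes)
    out$outcome[hit] <- outcomes[species[hit]]
  }
  out
}
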