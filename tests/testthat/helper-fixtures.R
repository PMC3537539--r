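# Small fixtures built in code.

# alignment from named strings
aln_from_strings <- function(...) {
  seqs <- c(...)
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  new_alignment(m, names(seqs))
}

# minimal specimen table; species vector named by specimen id
spec_table <- function(species, sex = "M", region = "Churchill") {
  data.frame(specimen_id = names(species),
             species_label = unname(species),
             sex = rep_len(sex, length(species)),
             region = rep_len(region, length(species)),
             stringsAsFactors = FALSE)
}

# a clean two-cluster gap dataset used across modules
gap_sim <- function(seed = 1, n_species = 5, n_per_species = 4,
                    inter = c(5, 9), intra = 0.3) {
  simulate_barcodes(sim_params(n_species = n_species,
                               n_per_species = n_per_species,
                               intra_mean = intra,
                               inter_range = inter, seed = seed))
}

# independent scalar K2P oracle: naive per-column loop, no shared code
# with the package implementation's vectorised counting
oracle_k2p <- function(x, y) {
  x <- strsplit(x, "")[[1]]; y <- strsplit(y, "")[[1]]
  pur <- c("A", "G")
  ts <- tv <- n <- 0
  for (k in seq_along(x)) {
    a <- x[k]; b <- y[k]
    if (!a %in% c("A", "C", "G", "T") || !b %in% c("A", "C", "G", "T"))
      next
    n <- n + 1
    if (a == b) next
    if ((a %in% pur) == (b %in% pur)) ts <- ts + 1 else tv <- tv + 1
  }
  P <- ts / n; Q <- tv / n
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

random_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                       replace = TRUE), collapse = "")

# mutate a string at given positions to given bases
mutate_at <- function(s, pos, to) {
  v <- strsplit(s, "")[[1]]
  v[pos] <- to
  paste(v, collapse = "")
}
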