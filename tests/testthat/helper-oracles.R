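# Independent brute-force oracles and small in-code fixture builders.

# Per-EC scan: an ACTIVE EC is an orphan iff no unflagged, full-EC evidence
# row cites it in any source. Written as the plainest possible loop, kept
# independent of reconcile()'s set algebra.
brute_force_census <- function(catalog, evidence) {
  orphans <- character(0); sequenced <- character(0)
  for (act in catalog) {
    if (act$status != "ACTIVE") next
    ec <- format(act$ec)
    found <- FALSE
    if (!is.null(evidence) && nrow(evidence)) {
      for (r in seq_len(nrow(evidence))) {
        if (evidence$flagged[r]) next
        ev_ec <- tryCatch(format(as_ec(evidence$ec[r])), error = function(e) NA)
        if (is.na(ev_ec) || is_class_level(ev_ec)) next
        if (ev_ec == ec) { found <- TRUE; break }
      }
    }
    if (found) sequenced <- c(sequenced, ec) else orphans <- c(orphans, ec)
  }
  list(orphans = sort(orphans), sequenced = sort(sequenced))
}

# All placements of each variant on each protein at the anchored offsets,
# Hamming-counted character by character.
brute_force_scan <- function(peptides, proteome, max_mismatch,
                             max_start_offset = 1L, met_start = TRUE) {
  rows <- list()
  for (p in peptides) {
    pc <- strsplit(p, "")[[1]]
    for (i in seq_len(nrow(proteome))) {
      s <- proteome$sequence[i]
      offs <- 0:max_start_offset
      if (met_start && substr(s, 1, 1) == "M") offs <- unique(c(offs, 1L))
      for (o in offs) {
        if (o + length(pc) > nchar(s)) next
        w <- strsplit(substring(s, o + 1, o + length(pc)), "")[[1]]
        mm <- sum(w != pc)
        if (mm <= max_mismatch) {
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = proteome$protein_id[i], variant = p,
            start_offset = o, mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(protein_id = character(), variant = character(),
                      start_offset = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$protein_id, out$variant, out$start_offset), , drop = FALSE]
}

# A tiny hand-rolled catalog used across tests.
tiny_catalog <- function() {
  structure(list(
    "1.1.1.1" = enzyme_activity("1.1.1.1", "alcohol dehydrogenase",
                                systematic_name = "alcohol:NAD+ oxidoreductase",
                                other_names = c("aldehyde reductase", "ADH")),
    "1.1.1.173" = enzyme_activity("1.1.1.173", "L-rhamnose 1-dehydrogenase"),
    "2.8.2.34" = enzyme_activity("2.8.2.34", "glycochenodeoxycholate sulfotransferase"),
    "3.1.1.1" = enzyme_activity("3.1.1.1", status = "DELETED"),
    "4.1.1.1" = enzyme_activity("4.1.1.1", status = "TRANSFERRED",
                                transferred_to = "4.1.1.99")),
    class = "enzyme_catalog")
}

# Random small evidence table over a set of EC strings.
random_evidence <- function(ecs, n_rows, class_level_frac = 0.1,
                            unknown_frac = 0.1, flagged_frac = 0.15) {
  if (n_rows == 0) {
    return(sequence_evidence(character(), character(), character()))
  }
  pick_ec <- function() {
    u <- runif(1)
    if (u < class_level_frac) {
      e <- as_ec(sample(ecs, 1)); sprintf("%d.%d.%d.-", e$c1, e$c2, e$c3)
    } else if (u < class_level_frac + unknown_frac) {
      "6.6.6.666"  # absent from every generated catalog below
    } else sample(ecs, 1)
  }
  sequence_evidence(
    source = sample(paste0("src", 1:3), n_rows, replace = TRUE),
    ec = vapply(seq_len(n_rows), function(i) pick_ec(), character(1)),
    accession = sprintf("A%05d", seq_len(n_rows)),
    submitter = sample(c("ctrA", "ctrB", NA), n_rows, replace = TRUE),
    flagged = runif(n_rows) < flagged_frac)
}

random_catalog <- function(n) {
  ecs <- unique(sprintf("%d.%d.%d.%d",
                        sample(1:6, 3 * n, replace = TRUE),
                        sample(1:9, 3 * n, replace = TRUE),
                        sample(1:9, 3 * n, replace = TRUE),
                        sample(1:99, 3 * n, replace = TRUE)))[seq_len(n)]
  acts <- lapply(seq_along(ecs), function(i) {
    enzyme_activity(ecs[i], accepted_name = paste("activity", i))
  })
  names(acts) <- ecs
  structure(acts, class = "enzyme_catalog")
}

random_proteome <- function(n, len_range = c(30L, 80L)) {
  data.frame(
    protein_id = sprintf("p%03d", seq_len(n)),
    organism = "Testus organismus",
    sequence = vapply(seq_len(n), function(i) {
      paste(sample(orphanEnzymes:::AA_STANDARD,
                   sample(len_range[1]:len_range[2], 1), replace = TRUE),
            collapse = "")
    }, character(1)),
    stringsAsFactors = FALSE)
}
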