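# Seeded synthetic-fixture generators with recorded ground truth, so every
# module is testable offline. Identical spec + seed produce byte-identical
# files: generation uses only R's integer-state RNG (sample) with a fixed
# seed and no float-dependent branching.

.substrate_words <- c(
  "rhamnose", "fluorenol", "mevaldate", "glycerol", "xylitol", "arabinitol",
  "sorbitol", "choline", "sarcosine", "putrescine", "glutamate", "malonate",
  "shikimate", "chorismate", "taurine", "betaine", "inositol", "trehalose",
  "maltose", "fucose", "galactonate", "gluconate", "quinate", "citramalate",
  "homoserine", "cystathionine", "ornithine", "agmatine", "spermidine",
  "cadaverine", "histamine", "tyramine", "indole", "anthranilate",
  "benzoate", "vanillate", "ferulate", "catechol", "phenol", "cresol")

.class_words <- c(
  "dehydrogenase", "reductase", "oxidase", "transferase", "hydrolase",
  "kinase", "synthase", "isomerase", "mutase", "ligase", "decarboxylase",
  "aminotransferase", "phosphatase", "epimerase", "aldolase", "sulfotransferase")

.submitter_pool <- paste0("center_", LETTERS[1:6])

#' Specify a synthetic fixture
#'
#' Collects all generator knobs with defaults emulating the data regimes the
#' methodology addresses: a few-hundred-activity catalog with a quarter of
#' activities orphaned, evidence spread over a handful of sources with rare
#' single-center systematic mis-assignment clusters, desk-scale proteomes of
#' 500 proteins, N-terminal reads of 15-25 cycles carrying up to two
#' injected Edman artifacts and two ambiguous cycles.
#'
#' @param seed integer RNG seed; same spec + seed reproduce files exactly.
#' @param n_activities catalog size.
#' @param orphan_fraction fraction of activities planted as orphans (floored
#'   to a whole count).
#' @param n_sources number of evidence sources.
#' @param systematic_error_clusters number of planted single-submitter
#'   mis-assignment clusters (on orphan ECs).
#' @param n_proteins proteome size.
#' @param protein_length_range integer length range for proteins.
#' @param read_length_range integer length range for N-terminal reads.
#' @param injected_errors_per_read number of injected sequencing errors.
#' @param ambiguity_positions_per_read number of ambiguous call sets.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_activities = 200L, orphan_fraction = 0.25,
                         n_sources = 3L, systematic_error_clusters = 1L,
                         n_proteins = 500L, protein_length_range = c(100L, 400L),
                         read_length_range = c(15L, 25L),
                         injected_errors_per_read = 2L,
                         ambiguity_positions_per_read = 2L) {
  stopifnot(n_activities >= 0, orphan_fraction >= 0, orphan_fraction <= 1,
            n_sources >= 0, systematic_error_clusters >= 0, n_proteins >= 0,
            injected_errors_per_read >= 0, ambiguity_positions_per_read >= 0,
            length(protein_length_range) == 2, length(read_length_range) == 2)
  structure(list(seed = as.integer(seed), n_activities = as.integer(n_activities),
                 orphan_fraction = orphan_fraction, n_sources = as.integer(n_sources),
                 systematic_error_clusters = as.integer(systematic_error_clusters),
                 n_proteins = as.integer(n_proteins),
                 protein_length_range = as.integer(protein_length_range),
                 read_length_range = as.integer(read_length_range),
                 injected_errors_per_read = as.integer(injected_errors_per_read),
                 ambiguity_positions_per_read = as.integer(ambiguity_positions_per_read)),
            class = "fixture_spec")
}

# sample() that is safe when x is a scalar count holder of length 1
.sample1 <- function(x, size = 1L) x[sample.int(length(x), size)]

.random_ecs <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    cand <- paste(sample.int(6, n, replace = TRUE),
                  sample.int(25, n, replace = TRUE),
                  sample.int(25, n, replace = TRUE),
                  sample.int(300, n, replace = TRUE), sep = ".")
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

.random_names <- function(n) {
  base <- paste(sample(.substrate_words, n, replace = TRUE),
                sample(.class_words, n, replace = TRUE))
  # disambiguate clashes with a locant-style decoration
  while (anyDuplicated(base)) {
    d <- which(duplicated(base))
    deco <- sprintf(" %d-", sample.int(99, length(d), replace = TRUE))
    base[d] <- mapply(function(x, y) sub(" ", y, x), base[d], deco,
                      USE.NAMES = FALSE)
  }
  base
}

#' Generate a census fixture with recorded ground truth
#'
#' Writes an ENZYME-dialect catalog, one evidence TSV per source, and a
#' truth TSV. A floor(`orphan_fraction * n_activities`) subset of ACTIVE
#' activities is planted orphan (no unflagged evidence anywhere); the rest
#' receive evidence rows spread over the sources. Planted systematic-error
#' clusters put `>= 3` accessions from a single submitter and single source
#' on orphan ECs, so the orphan set is recovered only after
#' [flag_systematic()]. A small number of DELETED/TRANSFERRED entries is
#' included to exercise the removal path.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, list with `catalog_path`, `evidence_paths`,
#'   `truth_path`, and the `truth` data frame (`ec`, `role`
#'   (`orphan`/`sequenced`/`removed`), `cluster_submitter`).
#' @export
make_census_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  n <- spec$n_activities
  ecs <- .random_ecs(n)
  nms <- .random_names(n)
  n_removed <- min(n - 1L, round(0.03 * n))
  removed_idx <- if (n_removed > 0) sample.int(n, n_removed) else integer(0)
  status <- rep("ACTIVE", n)
  if (n_removed > 0) {
    status[removed_idx] <- sample(c("DELETED", "TRANSFERRED"), n_removed,
                                  replace = TRUE)
  }

  catalog <- structure(lapply(seq_len(n), function(i) {
    if (status[i] == "ACTIVE") {
      syn <- if (sample.int(2, 1) == 1L) gsub(" ", "-", nms[i]) else character(0)
      enzyme_activity(ecs[i], accepted_name = nms[i], other_names = syn)
    } else if (status[i] == "DELETED") {
      enzyme_activity(ecs[i], status = "DELETED")
    } else {
      enzyme_activity(ecs[i], status = "TRANSFERRED",
                      transferred_to = ecs[(i %% n) + 1L])
    }
  }), class = "enzyme_catalog")
  names(catalog) <- ecs

  active_idx <- which(status == "ACTIVE")
  n_orph <- floor(spec$orphan_fraction * n)
  if (n_orph > length(active_idx)) {
    stop("orphan_fraction leaves too few ACTIVE activities to plant")
  }
  orphan_idx <- sort(.sample1(active_idx, n_orph))
  sequenced_idx <- setdiff(active_idx, orphan_idx)

  sources <- paste0("source_", seq_len(max(spec$n_sources, 1L)))
  acc_counter <- 0L
  new_acc <- function(k) {
    acc_counter <<- acc_counter + k
    sprintf("ACC%06d", (acc_counter - k + 1L):acc_counter)
  }
  ev_rows <- list()
  for (i in sequenced_idx) {
    k_src <- sample.int(length(sources), 1L)
    for (s in sample(sources, k_src)) {
      n_acc <- sample.int(2L, 1L)  # <= 2 per (ec, source): below any cluster rule
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        source = s, ec = ecs[i], accession = new_acc(n_acc),
        submitter = .sample1(c(.submitter_pool, NA_character_)),
        flagged = FALSE, stringsAsFactors = FALSE)
    }
  }
  # systematic clusters on orphan ECs: single submitter, single source
  cluster_sub <- setNames(rep(NA_character_, n), ecs)
  n_clusters <- min(spec$systematic_error_clusters, length(orphan_idx))
  cluster_ecs <- if (n_clusters > 0) .sample1(orphan_idx, n_clusters) else integer(0)
  for (i in cluster_ecs) {
    s <- .sample1(sources)
    sub <- .sample1(.submitter_pool)
    sz <- 2L + sample.int(3L, 1L)  # 3..5 accessions
    ev_rows[[length(ev_rows) + 1L]] <- data.frame(
      source = s, ec = ecs[i], accession = new_acc(sz),
      submitter = sub, flagged = FALSE, stringsAsFactors = FALSE)
    cluster_sub[ecs[i]] <- sub
  }
  evidence <- do.call(rbind, ev_rows)
  evidence <- evidence[order(evidence$source, evidence$ec, evidence$accession), ,
                       drop = FALSE]

  catalog_path <- file.path(dir, "catalog.txt")
  write_enzyme_catalog(catalog, catalog_path)
  evidence_paths <- character(0)
  for (s in sources) {
    p <- file.path(dir, paste0("evidence_", s, ".tsv"))
    write_evidence_tsv(sequence_evidence(
      evidence$source[evidence$source == s], evidence$ec[evidence$source == s],
      evidence$accession[evidence$source == s],
      evidence$submitter[evidence$source == s],
      evidence$flagged[evidence$source == s]), p)
    evidence_paths <- c(evidence_paths, p)
  }
  role <- rep("sequenced", n)
  role[orphan_idx] <- "orphan"
  role[removed_idx] <- "removed"
  truth <- data.frame(ec = ecs, role = role,
                      cluster_submitter = unname(cluster_sub),
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$ec), , drop = FALSE]
  truth_path <- file.path(dir, "truth.tsv")
  con <- file(truth_path, "w")
  writeLines(sprintf("# planted_orphans=%d (floor of %g * %d)",
                     n_orph, spec$orphan_fraction, n), con)
  close(con)
  suppressWarnings(utils::write.table(truth, truth_path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      na = "", append = TRUE))
  invisible(list(catalog_path = catalog_path, evidence_paths = evidence_paths,
                 truth_path = truth_path, truth = truth))
}

#' Generate an N-terminal identification fixture
#'
#' Writes a random proteome FASTA, a single-line read file in the ambiguity
#' mini-format, and truth TSVs. One protein is designated the target; the
#' read is its N-terminal prefix with seeded injections: ambiguous call
#' sets (true residue plus one alternative), cysteine-loss events (a true C
#' written as `X`), deamidation flips (true N written as D, true Q as E),
#' and plain substitutions. The injection trace, the target's identity and
#' computed molecular weight are recorded in the truth files.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory.
#' @return invisibly, list with `proteome_path`, `read_path`, `truth_path`,
#'   `injections_path`, `truth` (one-row data frame), and `injections`.
#' @export
make_nterm_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  lens <- sample(spec$protein_length_range[1]:spec$protein_length_range[2],
                 spec$n_proteins, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste0("M", paste(sample(AA_STANDARD, L - 1L, replace = TRUE), collapse = ""))
  }, character(1))
  ids <- sprintf("prot%04d", seq_len(spec$n_proteins))
  proteome <- data.frame(protein_id = ids, organism = "Synthetica exempli",
                         sequence = seqs, stringsAsFactors = FALSE)

  target <- sample.int(spec$n_proteins, 1L)
  L <- .sample1(spec$read_length_range[1]:spec$read_length_range[2])
  if (L > nchar(seqs[target])) {
    stop("read length exceeds the target protein length")
  }
  true_prefix <- strsplit(substr(seqs[target], 1L, L), "")[[1]]
  cells <- as.list(true_prefix)  # per-cycle rendering, mutated below

  n_special <- spec$ambiguity_positions_per_read + spec$injected_errors_per_read
  pos_pool <- sample.int(L, min(L, n_special))
  amb_pos <- pos_pool[seq_len(min(spec$ambiguity_positions_per_read, length(pos_pool)))]
  err_pos <- setdiff(pos_pool, amb_pos)

  inj <- list()
  for (p in amb_pos) {
    alt <- .sample1(setdiff(AA_STANDARD, true_prefix[p]))
    cells[[p]] <- sort(c(true_prefix[p], alt))
    inj[[length(inj) + 1L]] <- data.frame(position = p, type = "ambiguity",
                                          true_residue = true_prefix[p],
                                          observed = paste(cells[[p]], collapse = "|"),
                                          stringsAsFactors = FALSE)
  }
  for (p in err_pos) {
    tr <- true_prefix[p]
    type <- if (tr == "C") "cys_loss"
            else if (tr == "N" || tr == "Q") .sample1(c("deamidation", "substitution"))
            else "substitution"
    obs <- switch(type,
      cys_loss = "X",
      deamidation = if (tr == "N") "D" else "E",
      substitution = .sample1(setdiff(AA_STANDARD, tr)))
    cells[[p]] <- obs
    inj[[length(inj) + 1L]] <- data.frame(position = p, type = type,
                                          true_residue = tr, observed = obs,
                                          stringsAsFactors = FALSE)
  }
  read_text <- paste(vapply(cells, function(cl) {
    if (length(cl) == 1L) cl else paste0("{", paste(cl, collapse = "|"), "}")
  }, character(1)), collapse = "")
  injections <- if (length(inj)) do.call(rbind, inj) else
    data.frame(position = integer(), type = character(),
               true_residue = character(), observed = character(),
               stringsAsFactors = FALSE)
  injections <- injections[order(injections$position), , drop = FALSE]

  proteome_path <- file.path(dir, "proteome.fasta")
  write_proteome(proteome, proteome_path)
  read_path <- file.path(dir, "read.txt")
  writeLines(read_text, read_path)
  truth <- data.frame(target_id = ids[target], start_offset = 0L,
                      read_length = L,
                      mw_kda = compute_mw(seqs[target]) / 1000,
                      n_injections = nrow(injections),
                      stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  write_tsv(truth, truth_path)
  injections_path <- file.path(dir, "truth_injections.tsv")
  write_tsv(injections, injections_path)
  invisible(list(proteome_path = proteome_path, read_path = read_path,
                 truth_path = truth_path, injections_path = injections_path,
                 truth = truth, injections = injections))
}
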