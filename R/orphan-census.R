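# Orphan census: reconcile the EC catalog against per-source sequence
# evidence to compute the putative-orphan set.

#' Build a sequence-evidence table
#'
#' One row per (source, EC, accession) assertion that a database `source`
#' links `ec` to protein `accession`. `submitter` is the originating
#' depositor (e.g. a sequencing center) when known; `flagged` marks evidence
#' judged to be a mis-assignment, which never counts toward de-orphaning.
#'
#' @param source,ec,accession character vectors (recycled to equal length).
#' @param submitter optional character vector; `NA` when unknown.
#' @param flagged logical vector, default `FALSE`.
#' @return data frame of class `sequence_evidence`.
#' @export
sequence_evidence <- function(source, ec, accession,
                              submitter = NA_character_, flagged = FALSE) {
  n <- max(length(source), length(ec), length(accession))
  df <- data.frame(source = rep_len(as.character(source), n),
                   ec = rep_len(as.character(ec), n),
                   accession = rep_len(as.character(accession), n),
                   submitter = rep_len(as.character(submitter), n),
                   flagged = rep_len(as.logical(flagged), n),
                   stringsAsFactors = FALSE)
  key <- paste(df$source, df$ec, df$accession, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (source, ec, accession) triples in evidence set")
  }
  class(df) <- c("sequence_evidence", "data.frame")
  df
}

#' Read / write an evidence TSV
#'
#' Columns: `source`, `ec`, `accession`, `submitter`, `flagged` (0/1).
#'
#' @param path TSV path.
#' @return for the reader, a `sequence_evidence` data frame.
#' @export
read_evidence_tsv <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  sequence_evidence(df$source, df$ec, df$accession,
                    submitter = df$submitter %||% NA_character_,
                    flagged = df$flagged %in% c("1", "TRUE", "true"))
}

#' @rdname read_evidence_tsv
#' @param evidence a `sequence_evidence` data frame.
#' @export
write_evidence_tsv <- function(evidence, path) {
  out <- evidence
  out$flagged <- as.integer(out$flagged)
  write_tsv(as.data.frame(out), path)
  invisible(nrow(out))
}

#' Flag systematic mis-assignment clusters
#'
#' Mechanizes the discard of systematic, incorrect EC assignments that
#' originate from a single depositor: an (EC, submitter) cluster is flagged
#' when (i) that submitter supports the EC with at least `min_cluster`
#' distinct accessions, and (ii) no corroborating evidence for that EC exists
#' from any other submitter or any other source. Items without submitter
#' metadata are never flagged; previously set flags are preserved. The
#' operation is idempotent and independent of row order.
#'
#' @param evidence a `sequence_evidence` data frame.
#' @param min_cluster minimum distinct accessions to count as a cluster
#'   (default 3; must be >= 2).
#' @return the evidence with `flagged` updated.
#' @export
flag_systematic <- function(evidence, min_cluster = 3L) {
  if (min_cluster < 2L) stop("min_cluster must be >= 2")
  ev <- evidence
  ec_c <- ec_canon(ev$ec)
  has_sub <- !is.na(ev$submitter)
  for (e in unique(ec_c[has_sub])) {
    in_ec <- ec_c == e
    for (s in unique(ev$submitter[in_ec & has_sub])) {
      cl <- in_ec & has_sub & ev$submitter == s
      if (length(unique(ev$accession[cl])) < min_cluster) next
      # corroboration: any row for this EC from another submitter (or with
      # no submitter), or the cluster itself spanning more than one source
      others <- in_ec & !cl
      if (any(others)) next
      if (length(unique(ev$source[cl])) > 1L) next
      ev$flagged[cl] <- TRUE
    }
  }
  ev
}

#' Reconcile a catalog against sequence evidence
#'
#' Partitions the ACTIVE activities of a catalog into `sequenced` (at least
#' one unflagged evidence row in any source) and `putative_orphans` (no
#' unflagged evidence across all sources). DELETED and TRANSFERRED entries
#' are set aside in `removed` and excluded from the census denominator.
#' Evidence annotated only to a class-level EC (`1.1.1.-`) is recorded but
#' never de-orphans a full EC; evidence citing an EC absent from the catalog
#' is collected into a warnings table rather than failing.
#'
#' @param catalog an `enzyme_catalog`.
#' @param evidence a `sequence_evidence` data frame (or a list of them,
#'   which are concatenated).
#' @return an object of class `census_result` with character-vector fields
#'   `evaluated`, `sequenced`, `putative_orphans`, `removed`, a data frame
#'   `warnings` (unknown-EC evidence rows), and `n_sources` (named count of
#'   distinct unflagged evidence sources per sequenced EC).
#' @export
reconcile <- function(catalog, evidence) {
  if (!length(catalog)) stop("catalog is empty")
  if (is.data.frame(evidence)) evidence <- list(evidence)
  ev <- do.call(rbind, lapply(evidence, as.data.frame))
  status <- unname(vapply(catalog, function(a) a$status, character(1)))
  ecs <- unname(vapply(catalog, function(a) format(a$ec), character(1)))
  active <- ecs[status == "ACTIVE"]
  removed <- ecs[status != "ACTIVE"]

  warn <- NULL
  seq_ecs <- character()
  n_sources <- integer()
  if (!is.null(ev) && nrow(ev)) {
    ev_ec <- ec_canon(ev$ec)
    class_lvl <- vapply(ev_ec, function(e) is_class_level(e), logical(1))
    unknown <- !(ev_ec %in% ecs) & !class_lvl
    warn <- ev[unknown, , drop = FALSE]
    usable <- !ev$flagged & !class_lvl & (ev_ec %in% active)
    if (any(usable)) {
      tab <- tapply(ev$source[usable], ev_ec[usable],
                    function(s) length(unique(s)))
      seq_ecs <- names(tab)
      n_sources <- as.integer(tab)
      names(n_sources) <- seq_ecs
    }
  }
  orphans <- setdiff(active, seq_ecs)
  structure(list(evaluated = active,
                 sequenced = sort(seq_ecs),
                 putative_orphans = sort(orphans),
                 removed = sort(removed),
                 warnings = warn,
                 n_sources = n_sources),
            class = "census_result")
}

#' @export
print.census_result <- function(x, ...) {
  cat(sprintf("<census_result> %d evaluated: %d sequenced, %d putative orphans (%d removed)\n",
              length(x$evaluated), length(x$sequenced),
              length(x$putative_orphans), length(x$removed)))
  if (!is.null(x$warnings) && nrow(x$warnings)) {
    cat(sprintf("  %d evidence rows cite ECs absent from the catalog\n", nrow(x$warnings)))
  }
  invisible(x)
}

#' Summarize a census
#'
#' Orphan burden as a share of evaluated activities, half-up rounded. The
#' headline statistic is conventionally reported at whole-percent precision
#' (`digits = 0`).
#'
#' @param result a `census_result`; alternatively pass explicit counts via
#'   `n_orphans` and `n_evaluated`.
#' @param digits decimals for the percentage (half-up; default 0).
#' @param n_orphans,n_evaluated explicit counts, used when `result` is NULL.
#' @return list with `n_evaluated`, `n_orphans`, `pct_orphans`.
#' @examples
#' census_summary(n_orphans = 1122, n_evaluated = 4858)  # 23%
#' @export
census_summary <- function(result = NULL, digits = 0,
                           n_orphans = NULL, n_evaluated = NULL) {
  if (!is.null(result)) {
    stopifnot(inherits(result, "census_result"))
    n_orphans <- length(result$putative_orphans)
    n_evaluated <- length(result$evaluated)
  }
  if (is.null(n_orphans) || is.null(n_evaluated)) {
    stop("provide either a census_result or explicit counts")
  }
  if (n_evaluated == 0) stop("n_evaluated is zero; no activities to summarize")
  list(n_evaluated = n_evaluated, n_orphans = n_orphans,
       pct_orphans = share_pct(n_orphans, n_evaluated, digits))
}

#' Write census assignments as TSV
#'
#' Columns: `ec`, `status` (`sequenced` / `putative_orphan` / `removed`),
#' `n_sources` (distinct unflagged evidence sources; 0 for orphans and
#' removed entries).
#'
#' @param result a `census_result`.
#' @param path output TSV path.
#' @return invisibly, the data frame written.
#' @export
census_to_tsv <- function(result, path) {
  df <- rbind(
    data.frame(ec = result$sequenced, status = "sequenced",
               n_sources = as.integer(result$n_sources[result$sequenced]),
               stringsAsFactors = FALSE),
    data.frame(ec = result$putative_orphans, status = "putative_orphan",
               n_sources = 0L, stringsAsFactors = FALSE),
    data.frame(ec = result$removed, status = "removed",
               n_sources = 0L, stringsAsFactors = FALSE))
  rownames(df) <- NULL
  write_tsv(df, path)
  invisible(df)
}
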