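# Name permutation for synonym-robust searching, and corpus matching.
#
# Enzyme names drift between sources: locants dropped ("fluoren-9-ol" vs
# "fluorenol"), hyphens spaced, cofactor parentheticals omitted, chirality
# prefixes stripped. Each rule below produces the candidate spellings a
# curator would try; permute_name() takes the closure of the rules.

.cofactor_tokens <- c("NAD\\+", "NADH", "NADP\\+", "NADPH", "FAD", "FMN",
                      "ATP", "GTP", "CoA", "quinone", "cytochrome[^)]*")
.cofactor_re <- paste0("[[:space:]]*\\((", paste(.cofactor_tokens, collapse = "|"),
                       ")\\)[[:space:]]*$")

.chirality_re <- "^(L-|D-|DL-|\\(R\\)-|\\(S\\)-|\\(±\\)-|\\(\\+/-\\)-|cis-|trans-|meso-)"

.squeeze <- function(x) gsub("[[:space:]]+", " ", trimws(x))

# Each rule maps one term to zero or more transformed terms.
.permute_rules <- list(
  # digit runs attached to hyphens (locants): both the fused form
  # ("fluoren-9-ol" -> "fluorenol") and the hyphen-kept form
  # ("rhamnose-1-dehydrogenase" -> "rhamnose-dehydrogenase"); digits inside
  # plain words (e.g. "Delta4") are left alone
  locant = function(x) {
    out <- c(
      gsub("-[0-9]+(,[0-9]+)*-", "", x),
      gsub("-[0-9]+(,[0-9]+)*-", "-", x),
      gsub("(^|[ (])[0-9]+(,[0-9]+)*-", "\\1", x),
      gsub("-[0-9]+(,[0-9]+)*(?=[ )]|$)", "", x, perl = TRUE))
    unique(.squeeze(out))
  },
  hyphen = function(x) .squeeze(gsub("-", " ", x)),
  cofactor = function(x) sub(.cofactor_re, "", x),
  chirality = function(x) sub(.chirality_re, "", x)
)

#' Generate name permutations for synonym-robust search
#'
#' Expands an enzyme name into the spellings under which heterogeneous
#' sources may list the same activity, by taking the closure of four rules:
#' `locant` (digit runs with their flanking hyphens removed), `hyphen`
#' (hyphens replaced by spaces), `cofactor` (a terminal parenthetical
#' cofactor token removed; recognized set: NAD+, NADH, NADP+, NADPH, FAD,
#' FMN, ATP, GTP, CoA, quinone, cytochrome), and `chirality` (a leading
#' L-, D-, DL-, (R)-, (S)-, (+/-)-, cis-, trans- or meso- prefix removed).
#' Rules compose: every output term is itself re-expanded until no new
#' normalized term appears.
#'
#' @param name the original enzyme name (always the first term of the
#'   result).
#' @param rules subset of `c("locant","hyphen","cofactor","chirality")` to
#'   apply.
#' @param max_terms cap on the closure size (default 64); when reached the
#'   result carries `overflow = TRUE` and a warning is issued.
#' @return object of class `term_set`: list with `origin`, `terms`
#'   (character, origin first, no duplicates after normalization),
#'   `rules_applied` (per-term character vector of the rule path), and
#'   `overflow` flag.
#' @examples
#' permute_name("fluoren-9-ol dehydrogenase")
#' permute_name("mevaldate reductase (NADPH)")
#' @export
permute_name <- function(name, rules = c("locant", "hyphen", "cofactor", "chirality"),
                         max_terms = 64L) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name))) {
    stop("name must be a single non-empty string")
  }
  rules <- match.arg(rules, names(.permute_rules), several.ok = TRUE)
  terms <- .squeeze(name)
  paths <- list(character(0))
  seen <- normalize_name(terms)
  overflow <- FALSE
  i <- 1L
  while (i <= length(terms)) {
    for (r in rules) {
      for (cand in .permute_rules[[r]](terms[i])) {
        if (!nzchar(cand)) next
        key <- normalize_name(cand)
        if (key %in% seen) next
        if (length(terms) >= max_terms) { overflow <- TRUE; break }
        terms <- c(terms, cand)
        paths <- c(paths, list(c(paths[[i]], r)))
        seen <- c(seen, key)
      }
      if (overflow) break
    }
    if (overflow) break
    i <- i + 1L
  }
  if (overflow) {
    warning(sprintf("permutation closure for '%s' capped at %d terms", name, max_terms))
  }
  structure(list(origin = terms[1], terms = terms, rules_applied = paths,
                 overflow = overflow),
            class = "term_set")
}

#' @export
print.term_set <- function(x, ...) {
  cat(sprintf("<term_set> %d terms from '%s'%s\n", length(x$terms), x$origin,
              if (x$overflow) " (capped)" else ""))
  for (i in seq_along(x$terms)) {
    rp <- x$rules_applied[[i]]
    cat(sprintf("  %s%s\n", x$terms[i],
                if (length(rp)) paste0("  [", paste(rp, collapse = "+"), "]") else ""))
  }
  invisible(x)
}

#' Search a document corpus with a term set
#'
#' Matches every term of a [permute_name()] term set against a corpus of
#' title/abstract records, with normalization-aware comparison (see
#' [normalize_name()]). `SUBSTRING` mode matches a term anywhere in the
#' text; `EXACT` mode requires the term as a whole phrase (not embedded in a
#' longer word). Documents are ranked by number of distinct matched terms
#' (descending), earliest match position (ascending), then `doc_id`.
#'
#' @param terms a `term_set` (or character vector of terms).
#' @param corpus data frame with columns `doc_id`, `title`, and optionally
#'   `abstract`; `doc_id` must be unique.
#' @param mode `"SUBSTRING"` (default) or `"EXACT"`.
#' @return data frame with columns `doc_id`, `rank`, `n_matched`,
#'   `first_pos`, `matched_terms` (pipe-joined); only matching documents,
#'   in rank order.
#' @export
search_corpus <- function(terms, corpus, mode = c("SUBSTRING", "EXACT")) {
  mode <- match.arg(mode)
  tvec <- if (inherits(terms, "term_set")) terms$terms else as.character(terms)
  if (!length(tvec)) stop("empty term set")
  if (!is.data.frame(corpus) || !nrow(corpus)) stop("corpus is empty")
  if (anyDuplicated(corpus$doc_id)) stop("duplicate doc_id in corpus")

  abstract <- if ("abstract" %in% names(corpus)) corpus$abstract else ""
  abstract[is.na(abstract)] <- ""
  text <- normalize_name(paste(corpus$title, abstract))
  tnorm <- unique(normalize_name(tvec))

  esc <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)
  hits <- lapply(tnorm, function(tm) {
    pat <- if (mode == "EXACT") {
      paste0("(?<![[:alnum:]])", esc(tm), "(?![[:alnum:]])")
    } else esc(tm)
    m <- regexpr(pat, text, perl = TRUE)
    as.integer(m)  # -1 for no match, else 1-based position
  })
  pos <- do.call(cbind, hits)  # docs x terms
  matched <- pos > 0
  n_matched <- as.integer(rowSums(matched))
  keep <- which(n_matched > 0)
  if (!length(keep)) {
    return(data.frame(doc_id = character(), rank = integer(),
                      n_matched = integer(), first_pos = integer(),
                      matched_terms = character(), stringsAsFactors = FALSE))
  }
  first_pos <- apply(pos[keep, , drop = FALSE], 1,
                     function(p) min(p[p > 0]))
  res <- data.frame(
    doc_id = as.character(corpus$doc_id[keep]),
    n_matched = n_matched[keep],
    first_pos = as.integer(first_pos),
    matched_terms = vapply(seq_along(keep), function(i) {
      paste(tnorm[matched[keep[i], ]], collapse = "|")
    }, character(1)),
    stringsAsFactors = FALSE)
  res <- res[order(-res$n_matched, res$first_pos, res$doc_id), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res[, c("doc_id", "rank", "n_matched", "first_pos", "matched_terms")]
}

#' Read / write a corpus TSV
#'
#' Columns: `doc_id`, `title`, `abstract`.
#' @param path TSV path.
#' @return the reader returns a data frame; the writer the row count.
#' @export
read_corpus_tsv <- function(path) read_tsv(path, colClasses = "character")

#' @rdname read_corpus_tsv
#' @param corpus corpus data frame.
#' @export
write_corpus_tsv <- function(corpus, path) {
  write_tsv(corpus, path)
  invisible(nrow(corpus))
}
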