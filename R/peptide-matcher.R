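# Identify full protein sequences from partial N-terminal (Edman) reads
# and/or experimental molecular weights.
#
# Edman degradation reads the first 10-33 residues of a protein but has
# characteristic artifacts: cysteine is destroyed (an unreadable cycle),
# asparagine/glutamine deamidate so that N is read as D and Q as E, and the
# database sequence may retain an initiator methionine the mature protein
# lacks. The matcher expands a read into its concrete variants under a
# configurable error model and scans them against a proteome with an
# exhaustive anchored placement search, which is exact at the proteome
# sizes this problem presents.

AA_STANDARD <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Average residue masses in Daltons (monomer mass minus one water), standard
# biochemical average-mass table; total protein mass adds one water.
AA_AVERAGE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326)
MASS_WATER <- 18.01528

#' Parse an N-terminal read in the ambiguity mini-format
#'
#' One line, one token per sequencing cycle: a single residue letter, an
#' ambiguity set in braces (`{S|T}` means the cycle read S or T), or `X` for
#' an unreadable cycle (any residue; commonly a destroyed cysteine).
#'
#' @param text e.g. `"MA{S|T}KXLD"`.
#' @return object of class `nterm_read`: list with `positions` (list of
#'   per-cycle call sets; the string `"X"` marks an unknown cycle) and
#'   `length`.
#' @examples
#' parse_nterm_read("A{S|T}G")
#' @export
parse_nterm_read <- function(text) {
  if (!is.character(text) || length(text) != 1L) stop("read must be a single string")
  s <- trimws(text)
  if (!nzchar(s)) stop("empty read")
  chars <- strsplit(s, "")[[1]]
  positions <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "{") {
      j <- i
      while (j <= length(chars) && chars[j] != "}") j <- j + 1L
      if (j > length(chars)) stop(sprintf("unclosed '{' at position %d", i))
      opts <- strsplit(paste(chars[(i + 1):(j - 1)], collapse = ""), "|",
                       fixed = TRUE)[[1]]
      if (!length(opts) || !all(opts %in% AA_STANDARD)) {
        stop(sprintf("invalid ambiguity set '{%s}' at position %d",
                     paste(opts, collapse = "|"), i))
      }
      positions <- c(positions, list(sort(unique(opts))))
      i <- j + 1L
    } else if (ch == "X") {
      positions <- c(positions, list("X"))
      i <- i + 1L
    } else if (ch %in% AA_STANDARD) {
      positions <- c(positions, list(ch))
      i <- i + 1L
    } else {
      stop(sprintf("invalid residue code '%s' at position %d", ch, i))
    }
  }
  structure(list(positions = positions, length = length(positions)),
            class = "nterm_read")
}

#' @export
#' @exportS3Method base::format
format.nterm_read <- function(x, ...) {
  paste(vapply(x$positions, function(p) {
    if (identical(p, "X")) "X"
    else if (length(p) == 1L) p
    else paste0("{", paste(p, collapse = "|"), "}")
  }, character(1)), collapse = "")
}

#' @export
print.nterm_read <- function(x, ...) {
  cat(sprintf("<nterm_read> %d cycles: %s\n", x$length, format(x)))
  invisible(x)
}

#' @export
length.nterm_read <- function(x) x$length

#' Edman sequencing error model
#'
#' Controls which residues an observed call may stand for, in the
#' observed-to-true direction (the artifacts corrupt the read, not the
#' database sequence).
#'
#' @param cys_loss unreadable cycles may be cysteine (`C` added to the
#'   unknown alphabet).
#' @param deamidation an observed D may be a true N, an observed E a true Q.
#' @param met_start the database sequence may carry an initiator methionine
#'   absent from the mature-protein read (used by [scan_proteome()]).
#' @param unknown_alphabet residues substituted for an `X` cycle; default
#'   all 20 standard residues.
#' @param variant_cap hard ceiling on the number of enumerated variants.
#' @return object of class `edman_error_model`.
#' @export
error_model <- function(cys_loss = TRUE, deamidation = TRUE, met_start = TRUE,
                        unknown_alphabet = AA_STANDARD, variant_cap = 10000L) {
  if (variant_cap < 1L) stop("variant_cap must be >= 1")
  stopifnot(all(unknown_alphabet %in% AA_STANDARD))
  structure(list(cys_loss = cys_loss, deamidation = deamidation,
                 met_start = met_start,
                 unknown_alphabet = sort(unique(unknown_alphabet)),
                 variant_cap = as.integer(variant_cap)),
            class = "edman_error_model")
}

#' Enumerate concrete read variants under an error model
#'
#' Cartesian expansion of the per-cycle option sets: the explicit call set,
#' plus model-induced additions (deamidation: observed D admits N, observed
#' E admits Q; an `X` cycle admits the unknown alphabet, plus C under
#' `cys_loss`). Variants are returned in lexicographic order; each carries a
#' trace of the model corrections it assumes.
#'
#' @param read an `nterm_read` (or a mini-format string).
#' @param model an [error_model()].
#' @return data frame with columns `peptide`, `n_corrections`, and a
#'   list-column `corrections` (each a data frame `position`, `rule`,
#'   `residue`). Errors out (reporting the would-be count) when the
#'   expansion would exceed `variant_cap`.
#' @examples
#' enumerate_variants(parse_nterm_read("AD"), error_model())
#' @export
enumerate_variants <- function(read, model = error_model()) {
  if (is.character(read)) read <- parse_nterm_read(read)
  stopifnot(inherits(read, "nterm_read"), inherits(model, "edman_error_model"))
  opts <- vector("list", read$length)
  rules <- vector("list", read$length)  # per-option rule label ("" = as called)
  for (i in seq_len(read$length)) {
    p <- read$positions[[i]]
    if (identical(p, "X")) {
      o <- model$unknown_alphabet
      r <- rep("unknown", length(o))
      if (model$cys_loss && !("C" %in% o)) {
        o <- c(o, "C"); r <- c(r, "cys_loss")
      } else if (model$cys_loss) {
        r[o == "C"] <- "cys_loss"
      }
    } else {
      o <- p
      r <- rep("", length(o))
      if (model$deamidation) {
        if ("D" %in% p && !("N" %in% o)) { o <- c(o, "N"); r <- c(r, "deamidation") }
        if ("E" %in% p && !("Q" %in% o)) { o <- c(o, "Q"); r <- c(r, "deamidation") }
      }
    }
    ord <- order(o)
    opts[[i]] <- o[ord]
    rules[[i]] <- r[ord]
  }
  n_var <- prod(lengths(opts))
  if (n_var > model$variant_cap) {
    stop(sprintf("read would expand to %.0f variants, exceeding the cap of %d",
                 n_var, model$variant_cap))
  }
  # expand.grid varies its first factor fastest; feeding positions reversed
  # and re-ordering columns makes row order lexicographic in the peptide
  grid <- expand.grid(rev(opts), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(opts)), drop = FALSE]
  idx <- expand.grid(lapply(rev(lengths(opts)), seq_len),
                     KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, rev(seq_along(opts)), drop = FALSE]
  peptides <- do.call(paste0, grid)
  corrections <- lapply(seq_len(nrow(grid)), function(v) {
    pos <- which(vapply(seq_along(opts),
                        function(i) nzchar(rules[[i]][idx[v, i]]), logical(1)))
    data.frame(position = pos,
               rule = vapply(pos, function(i) rules[[i]][idx[v, i]], character(1)),
               residue = vapply(pos, function(i) opts[[i]][idx[v, i]], character(1)),
               stringsAsFactors = FALSE)
  })
  out <- data.frame(peptide = peptides,
                    n_corrections = vapply(corrections, nrow, integer(1)),
                    stringsAsFactors = FALSE)
  out$corrections <- corrections
  class(out) <- c("variant_set", "data.frame")
  out
}

#' Read a proteome FASTA
#'
#' Headers follow `>protein_id organism=...`; the organism key is optional.
#'
#' @param path FASTA path.
#' @return data frame with columns `protein_id`, `organism`, `sequence`.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  protein_id <- sub("[[:space:]].*$", "", headers)
  organism <- ifelse(grepl("organism=", headers),
                     sub("^.*organism=", "", headers), NA_character_)
  data.frame(protein_id = protein_id, organism = organism,
             sequence = as.character(aa), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write a proteome FASTA
#'
#' @param proteome data frame with `protein_id`, `organism`, `sequence`.
#' @param path output path.
#' @return invisibly, the number of records written.
#' @export
write_proteome <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome$sequence)
  names(aa) <- ifelse(is.na(proteome$organism), proteome$protein_id,
                      paste0(proteome$protein_id, " organism=", proteome$organism))
  Biostrings::writeXStringSet(aa, path)
  invisible(nrow(proteome))
}

#' Scan a proteome with read variants
#'
#' Exhaustive anchored placement search: every variant is placed on every
#' protein at start offsets `0..max_start_offset` (0-based), plus the offset-1
#' placement when `met_start` and the protein begins with an initiator M.
#' Mismatches are counted position-wise (an `X` in the database sequence
#' never matches). Candidates within `max_mismatch` are ranked by
#' (mismatches, number of model corrections, start offset, protein id,
#' variant).
#'
#' @param variants a `variant_set` from [enumerate_variants()], or a
#'   character vector of peptides.
#' @param proteome data frame from [read_proteome()].
#' @param max_mismatch maximum Hamming mismatches allowed (default 2).
#' @param max_start_offset deepest anchored start tried (default 1,
#'   covering initiator-Met cleavage; signal-peptide-scale offsets need an
#'   explicit override).
#' @param met_start also try offset 1 on M-initial proteins even when
#'   `max_start_offset = 0`.
#' @return data frame of class `match_candidates` with columns
#'   `protein_id`, `variant`, `start_offset`, `mismatches`,
#'   `n_corrections`, `rank`, plus the `corrections` list-column carried
#'   over from the variant set.
#' @export
scan_proteome <- function(variants, proteome, max_mismatch = 2L,
                          max_start_offset = 1L, met_start = TRUE) {
  if (is.character(variants)) {
    variants <- data.frame(peptide = variants,
                           n_corrections = 0L, stringsAsFactors = FALSE)
    variants$corrections <- rep(list(data.frame()), nrow(variants))
  }
  if (!is.data.frame(proteome) || !nrow(proteome)) stop("empty proteome")
  if (max_mismatch < 0L || max_start_offset < 0L) {
    stop("max_mismatch and max_start_offset must be >= 0")
  }
  res <- list()
  for (L in unique(nchar(variants$peptide))) {
    vsub <- variants[nchar(variants$peptide) == L, , drop = FALSE]
    # collect all candidate windows of width L
    win_pid <- character(); win_off <- integer(); win_seq <- character()
    for (i in seq_len(nrow(proteome))) {
      seq_i <- proteome$sequence[i]
      offs <- 0:max_start_offset
      if (met_start && startsWith(seq_i, "M")) offs <- unique(c(offs, 1L))
      offs <- offs[offs + L <= nchar(seq_i)]  # variant longer: skip silently
      if (!length(offs)) next
      win_pid <- c(win_pid, rep(proteome$protein_id[i], length(offs)))
      win_off <- c(win_off, offs)
      win_seq <- c(win_seq, substring(seq_i, offs + 1L, offs + L))
    }
    if (!length(win_seq)) next
    W <- matrix(unlist(strsplit(win_seq, "")), ncol = L, byrow = TRUE)
    for (v in seq_len(nrow(vsub))) {
      vc <- strsplit(vsub$peptide[v], "")[[1]]
      mm <- rowSums(W != matrix(vc, nrow = nrow(W), ncol = L, byrow = TRUE))
      hit <- which(mm <= max_mismatch)
      if (!length(hit)) next
      cand <- data.frame(protein_id = win_pid[hit],
                         variant = vsub$peptide[v],
                         start_offset = win_off[hit],
                         mismatches = as.integer(mm[hit]),
                         n_corrections = vsub$n_corrections[v],
                         stringsAsFactors = FALSE)
      cand$corrections <- rep(vsub$corrections[v], length(hit))
      res[[length(res) + 1L]] <- cand
    }
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(protein_id = character(), variant = character(),
               start_offset = integer(), mismatches = integer(),
               n_corrections = integer(), stringsAsFactors = FALSE)
  }
  ord <- order(out$mismatches, out$n_corrections, out$start_offset,
               out$protein_id, out$variant)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("match_candidates", "data.frame")
  out
}

#' Average molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water, in Daltons. Average (not
#' monoisotopic) masses match gel-derived experimental molecular weights.
#'
#' @param sequence amino-acid string over the 20 standard one-letter codes
#'   (`X` is not allowed here).
#' @return mass in Daltons.
#' @examples
#' compute_mw("G")  # 75.07 Da
#' @export
compute_mw <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string")
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!(chars %in% AA_STANDARD))
  if (length(bad)) {
    stop(sprintf("non-standard residue '%s' at position %d", chars[bad[1]], bad[1]))
  }
  sum(AA_AVERAGE_MASS[chars]) + MASS_WATER
}

#' Cross-check a computed molecular weight against an experimental one
#'
#' @param calc_kda computed mass in kDa.
#' @param exp_kda experimentally determined mass in kDa (> 0).
#' @param rel_tolerance maximum relative deviation `|calc - exp| / exp`
#'   (default 0.15, a typical SDS-PAGE accuracy allowance).
#' @return list with `calc_kda`, `exp_kda`, `rel_dev`, `pass`.
#' @examples
#' mw_check(33, 30)  # rel_dev 0.10, pass
#' @export
mw_check <- function(calc_kda, exp_kda, rel_tolerance = 0.15) {
  if (exp_kda <= 0) stop("exp_kda must be positive")
  if (rel_tolerance <= 0 || rel_tolerance >= 1) stop("rel_tolerance must be in (0, 1)")
  rel_dev <- abs(calc_kda - exp_kda) / exp_kda
  list(calc_kda = calc_kda, exp_kda = exp_kda, rel_dev = rel_dev,
       pass = rel_dev <= rel_tolerance)
}

#' Validate a match candidate by molecular weight
#'
#' Computes the candidate protein's average mass and compares it against an
#' experimentally determined mass.
#'
#' @param candidate a one-row `match_candidates` slice (or any list with a
#'   `protein_id`).
#' @param sequence the candidate protein's full sequence.
#' @param exp_kda experimental mass in kDa.
#' @param rel_tolerance see [mw_check()].
#' @return the candidate with `mw_check` populated (list with `calc_kda`,
#'   `exp_kda`, `rel_dev`, `pass`).
#' @export
validate_mw <- function(candidate, sequence, exp_kda, rel_tolerance = 0.15) {
  chk <- mw_check(compute_mw(sequence) / 1000, exp_kda, rel_tolerance)
  if (is.data.frame(candidate)) {
    candidate$mw_calc_kda <- chk$calc_kda
    candidate$mw_exp_kda <- chk$exp_kda
    candidate$mw_rel_dev <- chk$rel_dev
    candidate$mw_pass <- chk$pass
  }
  attr(candidate, "mw_check") <- chk
  candidate
}

#' Identify proteins by molecular weight alone
#'
#' Lists every protein whose computed average mass lies within the relative
#' tolerance of the experimental mass, ranked by relative deviation. When
#' exactly one protein passes, the result is flagged unique — molecular
#' weight alone then suffices to identify the sequence.
#'
#' @param exp_kda experimental mass in kDa.
#' @param proteome data frame from [read_proteome()].
#' @param rel_tolerance see [mw_check()].
#' @return data frame with `protein_id`, `calc_kda`, `rel_dev`, ranked by
#'   `rel_dev`; attribute `"unique"` is `TRUE` iff exactly one protein
#'   passes.
#' @export
mw_only_match <- function(exp_kda, proteome, rel_tolerance = 0.15) {
  calc <- vapply(proteome$sequence, compute_mw, numeric(1), USE.NAMES = FALSE) / 1000
  rel_dev <- abs(calc - exp_kda) / exp_kda
  keep <- which(rel_dev <= rel_tolerance)
  out <- data.frame(protein_id = proteome$protein_id[keep],
                    calc_kda = calc[keep], rel_dev = rel_dev[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$rel_dev, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unique") <- nrow(out) == 1L
  out
}
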