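# EC activity catalog: identifiers, name sets, entry status, and the
# ENZYME-dialect flat-file reader/writer.

#' Parse an EC number
#'
#' Parses a four-component Enzyme Commission identifier. Accepts an optional
#' leading "EC" (with or without "#"), full identifiers (`1.1.1.3`),
#' preliminary serials (`1.1.1.n4`, issued while an activity awaits formal
#' review), and class-level identifiers whose serial is `-` (`1.1.1.-`).
#'
#' @param text a single string, e.g. `"EC # 1.1.1.3"` or `"2.8.2.34"`.
#' @return an object of class `ec_number` with fields `c1`, `c2`, `c3`
#'   (positive integers; `c1` is the top-level class 1-6) and `serial`
#'   (character, `NA` for class-level identifiers).
#' @examples
#' parse_ec("EC # 1.1.1.3")
#' parse_ec("1.1.1.-")
#' @export
parse_ec <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    stop("parse_ec expects a single character string")
  }
  raw <- trimws(text)
  x <- sub("^EC[[:space:]]*#?[[:space:]]*", "", raw, ignore.case = TRUE)
  parts <- strsplit(x, ".", fixed = TRUE)[[1]]
  if (length(parts) != 4L) {
    stop(sprintf("malformed EC number '%s': expected four dot-separated components, found %d",
                 raw, length(parts)))
  }
  labs <- c("class", "subclass", "sub-subclass")
  nums <- integer(3)
  for (i in 1:3) {
    if (!grepl("^[0-9]+$", parts[i]) || as.integer(parts[i]) < 1L) {
      stop(sprintf("malformed EC number '%s': %s component '%s' is not a positive integer",
                   raw, labs[i], parts[i]))
    }
    nums[i] <- as.integer(parts[i])
  }
  if (nums[1] > 6L) {
    stop(sprintf("malformed EC number '%s': class component '%d' outside 1-6", raw, nums[1]))
  }
  s <- parts[4]
  serial <-
    if (s == "-") NA_character_
    else if (grepl("^[0-9]+$", s) && as.integer(s) >= 1L) s
    else if (grepl("^n[0-9]+$", s)) s  # preliminary serial, kept verbatim
    else stop(sprintf("malformed EC number '%s': serial component '%s'", raw, s))
  structure(list(c1 = nums[1], c2 = nums[2], c3 = nums[3], serial = serial),
            class = "ec_number")
}

#' @export
#' @exportS3Method base::format
format.ec_number <- function(x, ...) {
  paste(x$c1, x$c2, x$c3, if (is.na(x$serial)) "-" else x$serial, sep = ".")
}

#' @export
print.ec_number <- function(x, ...) {
  cat("EC", format(x), if (is_class_level(x)) "(class-level)" else "", "\n")
  invisible(x)
}

#' @export
as.character.ec_number <- function(x, ...) format(x)

#' @export
`==.ec_number` <- function(e1, e2) {
  format(as_ec(e1)) == format(as_ec(e2))
}

#' Test whether an EC identifier is class-level
#'
#' @param ec an `ec_number` or EC string.
#' @return `TRUE` when the serial component is absent (`1.1.1.-`).
#' @export
is_class_level <- function(ec) is.na(as_ec(ec)$serial)

#' Coerce a string or ec_number to ec_number
#' @param x an `ec_number` or a parseable EC string.
#' @return an `ec_number`.
#' @export
as_ec <- function(x) {
  if (inherits(x, "ec_number")) x else parse_ec(x)
}

# Canonical string form, vectorized over a character vector of EC texts.
ec_canon <- function(x) {
  if (inherits(x, "ec_number")) return(format(x))
  vapply(x, function(e) format(as_ec(e)), character(1), USE.NAMES = FALSE)
}

ACTIVITY_STATUSES <- c("ACTIVE", "DELETED", "TRANSFERRED")

#' Construct an enzyme activity record
#'
#' @param ec full (non-class-level) `ec_number` or EC string.
#' @param accepted_name the accepted name (required for ACTIVE entries).
#' @param systematic_name optional systematic name.
#' @param other_names character vector of alternate names.
#' @param status one of `"ACTIVE"`, `"DELETED"`, `"TRANSFERRED"`.
#' @param transferred_to for TRANSFERRED entries, a pointer string to the
#'   target EC(s); otherwise `NA`.
#' @param ca,cc catalyzed-reaction and comment lines, stored verbatim.
#' @return an object of class `enzyme_activity`.
#' @export
enzyme_activity <- function(ec, accepted_name = NA_character_,
                            systematic_name = NA_character_,
                            other_names = character(),
                            status = "ACTIVE",
                            transferred_to = NA_character_,
                            ca = character(), cc = character()) {
  ec <- as_ec(ec)
  status <- match.arg(status, ACTIVITY_STATUSES)
  if (status == "ACTIVE") {
    if (is_class_level(ec)) {
      stop(sprintf("ACTIVE activity '%s' must have a full (non-class-level) EC number",
                   format(ec)))
    }
    if (is.na(accepted_name) || !nzchar(trimws(accepted_name))) {
      stop(sprintf("ACTIVE activity '%s' must have a non-empty accepted name", format(ec)))
    }
  }
  structure(list(ec = ec, accepted_name = accepted_name,
                 systematic_name = systematic_name,
                 other_names = unique(as.character(other_names)),
                 status = status, transferred_to = transferred_to,
                 ca = as.character(ca), cc = as.character(cc)),
            class = "enzyme_activity")
}

#' @export
print.enzyme_activity <- function(x, ...) {
  cat(sprintf("<enzyme_activity> EC %s [%s]\n", format(x$ec), x$status))
  if (!is.na(x$accepted_name)) cat("  accepted name:", x$accepted_name, "\n")
  if (!is.na(x$systematic_name)) cat("  systematic name:", x$systematic_name, "\n")
  if (length(x$other_names)) cat("  other names:", paste(x$other_names, collapse = "; "), "\n")
  invisible(x)
}

#' Full (normalized and raw) name set of an activity
#'
#' The accepted name, systematic name, and all alternate names. Membership is
#' case-insensitive and whitespace-normalized (see [normalize_name()]);
#' the accepted name is always a member.
#'
#' @param activity an `enzyme_activity`.
#' @param normalized return normalized names (default) or raw names.
#' @return character vector of unique names.
#' @export
activity_names <- function(activity, normalized = TRUE) {
  raw <- c(activity$accepted_name, activity$systematic_name, activity$other_names)
  raw <- raw[!is.na(raw) & nzchar(raw)]
  if (!normalized) return(unique(raw))
  unique(normalize_name(raw))
}

#' Parse an ENZYME-dialect flat-file catalog
#'
#' Reads a catalog of EC activities in the ENZYME flat-file dialect: records
#' terminated by `//`, with two-letter line codes `ID` (the EC number), `DE`
#' (accepted name, or a `Deleted entry.` / `Transferred entry: ...` marker),
#' `AN` (one alternate name per line), `SN` (optional systematic name, an
#' extension of this dialect), and `CA`/`CC` lines kept verbatim. Trailing
#' periods on names are stripped.
#'
#' @param path path to a flat file, or a character vector of lines via
#'   `lines`.
#' @param lines optional character vector of file lines (overrides `path`).
#' @return an object of class `enzyme_catalog`: a list of
#'   [enzyme_activity()] records.
#' @export
parse_enzyme_catalog <- function(path = NULL, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path, warn = FALSE)
  # split into records on "//" terminator lines
  term <- grepl("^//", lines)
  rec_id <- cumsum(c(TRUE, head(term, -1)))
  keep <- !term & nzchar(trimws(lines))
  recs <- split(lines[keep], rec_id[keep])
  recs <- recs[vapply(recs, length, 1L) > 0L]

  out <- list()
  seen <- character()
  for (k in seq_along(recs)) {
    rl <- recs[[k]]
    code <- sub("^([A-Z]{2}).*$", "\\1", rl)
    body <- sub("^[A-Z]{2}[[:space:]]+", "", rl)
    ok <- grepl("^[A-Z]{2}[[:space:]]", rl)
    code <- code[ok]; body <- body[ok]
    id_lines <- body[code == "ID"]
    if (length(id_lines) != 1L) {
      stop(sprintf("catalog record %d: expected exactly one ID line, found %d",
                   k, length(id_lines)))
    }
    ec <- parse_ec(id_lines)
    key <- format(ec)
    if (key %in% seen) stop(sprintf("duplicate EC number '%s' in catalog", key))
    seen <- c(seen, key)

    de <- paste(body[code == "DE"], collapse = " ")
    an <- sub("\\.$", "", trimws(body[code == "AN"]))
    sn <- body[code == "SN"]
    sn <- if (length(sn)) sub("\\.$", "", trimws(sn[1])) else NA_character_

    if (grepl("^Deleted entry", de)) {
      act <- enzyme_activity(ec, status = "DELETED",
                             ca = body[code == "CA"], cc = body[code == "CC"])
    } else if (grepl("^Transferred entry", de)) {
      target <- trimws(sub("^Transferred entry:?", "", sub("\\.$", "", de)))
      act <- enzyme_activity(ec, status = "TRANSFERRED", transferred_to = target,
                             ca = body[code == "CA"], cc = body[code == "CC"])
    } else {
      act <- enzyme_activity(ec, accepted_name = sub("\\.$", "", trimws(de)),
                             systematic_name = sn, other_names = an,
                             ca = body[code == "CA"], cc = body[code == "CC"])
    }
    out[[key]] <- act
  }
  structure(out, class = "enzyme_catalog")
}

#' @export
print.enzyme_catalog <- function(x, ...) {
  st <- table(factor(vapply(x, function(a) a$status, character(1)),
                     levels = ACTIVITY_STATUSES))
  cat(sprintf("<enzyme_catalog> %d activities (%d active, %d deleted, %d transferred)\n",
              length(x), st[["ACTIVE"]], st[["DELETED"]], st[["TRANSFERRED"]]))
  invisible(x)
}

#' Write a catalog in the ENZYME flat-file dialect
#'
#' Inverse of [parse_enzyme_catalog()]; writing then parsing reproduces the
#' catalog field for field.
#'
#' @param catalog an `enzyme_catalog`.
#' @param path output file path.
#' @return invisibly, the number of records written.
#' @export
write_enzyme_catalog <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- 0L
  for (act in catalog) {
    lines <- c(paste0("ID   ", format(act$ec)))
    de <- switch(act$status,
      ACTIVE      = paste0(act$accepted_name, "."),
      DELETED     = "Deleted entry.",
      TRANSFERRED = paste0("Transferred entry: ", act$transferred_to, "."))
    lines <- c(lines, paste0("DE   ", de))
    if (!is.na(act$systematic_name)) {
      lines <- c(lines, paste0("SN   ", act$systematic_name, "."))
    }
    for (an in act$other_names) lines <- c(lines, paste0("AN   ", an, "."))
    for (ca in act$ca) lines <- c(lines, paste0("CA   ", ca))
    for (cc in act$cc) lines <- c(lines, paste0("CC   ", cc))
    writeLines(c(lines, "//"), con)
    n <- n + 1L
  }
  invisible(n)
}

#' Export a catalog as TSV
#'
#' Columns: `ec`, `accepted_name`, `systematic_name`, `other_names`
#' (pipe-joined), `status`.
#'
#' @param catalog an `enzyme_catalog`.
#' @param path output TSV path.
#' @return invisibly, the data frame written.
#' @export
catalog_to_tsv <- function(catalog, path) {
  pick <- function(f) unname(vapply(catalog, f, character(1)))
  df <- data.frame(
    ec = pick(function(a) format(a$ec)),
    accepted_name = pick(function(a) a$accepted_name),
    systematic_name = pick(function(a) a$systematic_name),
    other_names = pick(function(a) paste(a$other_names, collapse = "|")),
    status = pick(function(a) a$status),
    row.names = NULL, stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(df)
}

#' Look up activities by name, reporting collisions
#'
#' Builds the normalized name -> EC index for a catalog. Normalization makes
#' the lookup injective for well-formed catalogs; where two activities share
#' a normalized name the collision is reported rather than silently resolved.
#'
#' @param catalog an `enzyme_catalog`.
#' @return data frame with columns `name` (normalized), `ec`; the attribute
#'   `"collisions"` holds the subset of names mapping to more than one EC.
#' @export
catalog_name_index <- function(catalog) {
  rows <- do.call(rbind, lapply(catalog, function(a) {
    nm <- activity_names(a)
    if (!length(nm)) return(NULL)
    data.frame(name = nm, ec = format(a$ec), stringsAsFactors = FALSE)
  }))
  rows <- unique(rows)
  rows <- rows[order(rows$name, rows$ec), , drop = FALSE]
  rownames(rows) <- NULL
  dup <- rows$name[duplicated(rows$name)]
  attr(rows, "collisions") <- rows[rows$name %in% dup, , drop = FALSE]
  rows
}
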