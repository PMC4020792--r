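# Resolution ledger: record, classify, and summarize curation outcomes, and
# emit identification-information tables.

RES_CATEGORIES <- c(
  # annotation updates: the sequence was present, its annotation out of date
  "CLASS_LEVEL_ONLY", "ADDITIONAL_ACTIVITY", "NO_ACTIVITY_ASSIGNED",
  "SIMILAR_ACTIVITY_REPLACED",
  # data labeling errors: the activity was nominally attached but unfindable
  "MISSING_EC", "MISSING_SYNONYM", "WRONG_EC")

RES_GROUPS <- c("ANNOTATION_UPDATE", "DATA_LABELING")

RES_METHODS <- c("LITERATURE_DATABASE", "NTERM_MATCH", "MW_MATCH")

#' Resolution category group
#'
#' Pure mapping from category to its group: the four annotation-state
#' categories form `ANNOTATION_UPDATE`; the three findability categories
#' form `DATA_LABELING`.
#'
#' @param category character vector of categories.
#' @return character vector of groups.
#' @export
category_group <- function(category) {
  stopifnot(all(is.na(category) | category %in% RES_CATEGORIES))
  ifelse(is.na(category), NA_character_,
         ifelse(category %in% RES_CATEGORIES[1:4], "ANNOTATION_UPDATE", "DATA_LABELING"))
}

#' Construct a resolution record
#'
#' A RESOLVED record must carry a category, a method, and a non-empty
#' accession or sequence; an OPEN record must carry none of the three.
#'
#' @param ec the orphan's EC number (string or `ec_number`).
#' @param status `"RESOLVED"` or `"OPEN"`.
#' @param category one of `r paste(RES_CATEGORIES, collapse = ", ")`.
#' @param method one of `"LITERATURE_DATABASE"`, `"NTERM_MATCH"`,
#'   `"MW_MATCH"`.
#' @param accession_or_sequence accession number or amino-acid sequence.
#' @param notes free text.
#' @return one-row data frame of class `resolution_record`.
#' @export
resolution_record <- function(ec, status = c("RESOLVED", "OPEN"),
                              category = NA_character_, method = NA_character_,
                              accession_or_sequence = NA_character_, notes = "") {
  status <- match.arg(status)
  if (status == "RESOLVED") {
    if (is.na(category) || !(category %in% RES_CATEGORIES)) {
      stop("a RESOLVED record requires a valid category")
    }
    if (is.na(method) || !(method %in% RES_METHODS)) {
      stop("a RESOLVED record requires a valid method")
    }
    if (is.na(accession_or_sequence) || !nzchar(accession_or_sequence)) {
      stop("a RESOLVED record requires a non-empty accession or sequence")
    }
  } else {
    if (!is.na(category) || !is.na(method) || !is.na(accession_or_sequence)) {
      stop("an OPEN record must not carry category, method, or accession")
    }
  }
  df <- data.frame(ec = ec_canon(ec), status = status, category = category,
                   category_group = category_group(category), method = method,
                   accession_or_sequence = accession_or_sequence,
                   notes = notes, stringsAsFactors = FALSE)
  class(df) <- c("resolution_record", "data.frame")
  df
}

#' Assemble a resolution ledger
#'
#' @param records list of [resolution_record()] rows (or a conforming data
#'   frame).
#' @return data frame of class `resolution_ledger`.
#' @export
resolution_ledger <- function(records) {
  df <- if (is.data.frame(records)) records else do.call(rbind, records)
  stopifnot(all(c("ec", "status", "category", "method",
                  "accession_or_sequence", "notes") %in% names(df)))
  df$category_group <- category_group(df$category)
  df <- df[, c("ec", "status", "category", "category_group", "method",
               "accession_or_sequence", "notes")]
  class(df) <- c("resolution_ledger", "data.frame")
  df
}

#' Classify a resolution outcome
#'
#' Applies the fixed decision ladder to the pre-existing annotation state of
#' the identified sequence, first match wins:
#' \enumerate{
#'   \item correct activity annotated under an official name but the EC
#'     number absent: `MISSING_EC`
#'   \item correct activity annotated under unlisted names only:
#'     `MISSING_SYNONYM`
#'   \item correct activity annotated but a wrong EC attached: `WRONG_EC`
#'   \item annotation only at class level (e.g. "aldehyde dehydrogenase"):
#'     `CLASS_LEVEL_ONLY`
#'   \item no activity annotated at all: `NO_ACTIVITY_ASSIGNED`
#'   \item a different activity the enzyme genuinely also catalyzes:
#'     `ADDITIONAL_ACTIVITY`
#'   \item a different specific same-class activity replaced:
#'     `SIMILAR_ACTIVITY_REPLACED`
#' }
#'
#' The state is explicitly coded, as a curator would record it; when
#' `same_activity` / `names_listed` are not coded they are derived by
#' normalized comparison of the annotated names against the official name
#' set of the new assignment.
#'
#' @param old_state list describing the sequence's prior annotation:
#'   `level` (`"specific"`, `"class"`, or `"none"`), `names` (character
#'   vector of annotated activity names), `ec_state` (`"absent"`,
#'   `"correct"`, or `"wrong"`), `same_activity` (logical: the annotated
#'   activity is the orphan activity), `names_listed` (logical: the
#'   annotated names are among the official EC names), `also_catalyzed`
#'   (logical: the annotated different activity is genuinely also carried
#'   out by the enzyme).
#' @param new_assignment list for the orphan activity being assigned:
#'   `ec` and `official_names` (character vector).
#' @return a category string.
#' @examples
#' classify(list(level = "class", names = "aldehyde dehydrogenase"),
#'          list(ec = "1.2.1.69", official_names = "fluoroacetaldehyde dehydrogenase"))
#' @export
classify <- function(old_state, new_assignment) {
  level <- match.arg(old_state$level %||% "none", c("specific", "class", "none"))
  nms <- old_state$names %||% character()
  ec_state <- match.arg(old_state$ec_state %||% "absent",
                        c("absent", "correct", "wrong"))
  official <- new_assignment$official_names %||% character()

  derived_match <- length(nms) > 0 && length(official) > 0 &&
    any(normalize_name(nms) %in% normalize_name(official))
  same_activity <- old_state$same_activity %||%
    (level == "specific" && derived_match)
  names_listed <- old_state$names_listed %||% derived_match
  also_catalyzed <- isTRUE(old_state$also_catalyzed)

  # contradictory states
  if (level == "none" && (length(nms) > 0 || isTRUE(same_activity))) {
    stop("contradictory state: no annotation level but activity names present")
  }
  if (level == "class" && isTRUE(same_activity)) {
    stop("contradictory state: class-level annotation cannot be the specific orphan activity")
  }
  if (isTRUE(same_activity) && isTRUE(names_listed) && ec_state == "correct") {
    stop("contradictory state: sequence already findable under the correct EC and names")
  }

  if (same_activity && names_listed && ec_state == "absent") return("MISSING_EC")
  if (same_activity && !names_listed) return("MISSING_SYNONYM")
  if (same_activity && ec_state == "wrong") return("WRONG_EC")
  if (level == "class") return("CLASS_LEVEL_ONLY")
  if (level == "none") return("NO_ACTIVITY_ASSIGNED")
  if (also_catalyzed) return("ADDITIONAL_ACTIVITY")
  "SIMILAR_ACTIVITY_REPLACED"
}

#' Summarize a resolution ledger
#'
#' Counts and half-up 2-decimal percentages for outcomes, categories,
#' category groups, and identification methods. Resolved/open shares use the
#' total ledger size as denominator; category, group, and method shares use
#' the resolved count. All denominators are echoed in the result.
#'
#' @param object a `resolution_ledger`.
#' @param digits decimals for percentages (default 2).
#' @param ... unused.
#' @return object of class `ledger_summary`: list with `n_total`,
#'   `n_resolved`, `n_open`, `resolved_pct`, `open_pct`, and data frames
#'   `categories` (category, group, n, pct), `groups`, `methods`, plus
#'   `denominators`.
#' @export
#' @exportS3Method base::summary
summary.resolution_ledger <- function(object, digits = 2, ...) {
  if (!nrow(object)) stop("ledger is empty")
  n_total <- nrow(object)
  resolved <- object[object$status == "RESOLVED", , drop = FALSE]
  n_resolved <- nrow(resolved)
  n_open <- n_total - n_resolved

  count_pct <- function(values, levels) {
    n <- as.integer(table(factor(values, levels = levels)))
    data.frame(level = levels, n = n,
               pct = vapply(n, share_pct, numeric(1),
                            total = max(n_resolved, 1L), digits = digits),
               stringsAsFactors = FALSE)
  }
  categories <- count_pct(resolved$category, RES_CATEGORIES)
  names(categories)[1] <- "category"
  categories$group <- category_group(categories$category)
  categories <- categories[, c("category", "group", "n", "pct")]
  groups <- count_pct(category_group(resolved$category), RES_GROUPS)
  names(groups)[1] <- "group"
  methods <- count_pct(resolved$method, RES_METHODS)
  names(methods)[1] <- "method"

  structure(list(
    n_total = n_total, n_resolved = n_resolved, n_open = n_open,
    resolved_pct = share_pct(n_resolved, n_total, digits),
    open_pct = share_pct(n_open, n_total, digits),
    categories = categories, groups = groups, methods = methods,
    denominators = list(outcome = n_total, category = n_resolved,
                        group = n_resolved, method = n_resolved),
    digits = digits), class = "ledger_summary")
}

#' @rdname summary.resolution_ledger
#' @param ledger a `resolution_ledger`.
#' @export
summarize_ledger <- function(ledger, digits = 2) {
  summary.resolution_ledger(resolution_ledger(ledger), digits = digits)
}

#' @export
print.ledger_summary <- function(x, ...) {
  cat(sprintf("<ledger_summary> %d activities: %d resolved (%.2f%%), %d open (%.2f%%)\n",
              x$n_total, x$n_resolved, x$resolved_pct, x$n_open, x$open_pct))
  cat("Groups (of resolved):\n")
  print(x$groups, row.names = FALSE)
  cat("Categories (of resolved):\n")
  print(x$categories, row.names = FALSE)
  cat("Methods (of resolved):\n")
  print(x$methods, row.names = FALSE)
  invisible(x)
}

#' Write a ledger summary
#'
#' `summary_to_tsv()` writes a long-format TSV (`section`, `level`, `n`,
#' `pct`, `denominator`); `summary_to_json()` writes the summary as JSON.
#'
#' @param s a `ledger_summary`.
#' @param path output path.
#' @return invisibly, the object written.
#' @export
summary_to_tsv <- function(s, path) {
  rows <- rbind(
    data.frame(section = "outcome", level = c("RESOLVED", "OPEN"),
               n = c(s$n_resolved, s$n_open), pct = c(s$resolved_pct, s$open_pct),
               denominator = s$denominators$outcome, stringsAsFactors = FALSE),
    data.frame(section = "group", level = s$groups$group, n = s$groups$n,
               pct = s$groups$pct, denominator = s$denominators$group,
               stringsAsFactors = FALSE),
    data.frame(section = "category", level = s$categories$category,
               n = s$categories$n, pct = s$categories$pct,
               denominator = s$denominators$category, stringsAsFactors = FALSE),
    data.frame(section = "method", level = s$methods$method, n = s$methods$n,
               pct = s$methods$pct, denominator = s$denominators$method,
               stringsAsFactors = FALSE))
  write_tsv(rows, path)
  invisible(rows)
}

#' @rdname summary_to_tsv
#' @export
summary_to_json <- function(s, path) {
  jsonlite::write_json(unclass(s), path, auto_unbox = TRUE, digits = NA)
  invisible(s)
}

#' Read / write a resolution ledger TSV
#'
#' Columns: `ec`, `status` (`resolved` / `open` in the file), `category`,
#' `method`, `accession_or_sequence`, `notes`. Writing then reading
#' round-trips the ledger.
#'
#' @param path TSV path.
#' @return the reader returns a `resolution_ledger`.
#' @export
read_ledger_tsv <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  df$status <- toupper(df$status)
  df$notes[is.na(df$notes)] <- ""
  resolution_ledger(df[, c("ec", "status", "category", "method",
                           "accession_or_sequence", "notes")])
}

#' @rdname read_ledger_tsv
#' @param ledger a `resolution_ledger`.
#' @export
write_ledger_tsv <- function(ledger, path) {
  out <- as.data.frame(ledger)[, c("ec", "status", "category", "method",
                                   "accession_or_sequence", "notes")]
  out$status <- tolower(out$status)
  write_tsv(out, path)
  invisible(nrow(out))
}

#' Construct identification-information rows
#'
#' One row of per-publication evidence for an activity: source organism,
#' whether the publication describes purification and assay, sequence
#' information (accession or partial sequence), molecular weight in kDa,
#' isoelectric point, and whether kinetics data are given.
#'
#' @param ec,citation,organism character vectors (recycled).
#' @param has_purification,has_assay,has_kinetics logical, never `NA`.
#' @param sequence_info optional accession or sequence text.
#' @param mw_kda,isoelectric_point optional numerics.
#' @param notes free text.
#' @return data frame of class `identification_info`.
#' @export
identification_info <- function(ec, citation, organism,
                                has_purification = FALSE, has_assay = FALSE,
                                sequence_info = NA_character_,
                                mw_kda = NA_real_, isoelectric_point = NA_real_,
                                has_kinetics = FALSE, notes = "") {
  df <- data.frame(ec = ec_canon(ec), citation = as.character(citation),
                   organism = as.character(organism),
                   has_purification = as.logical(has_purification),
                   has_assay = as.logical(has_assay),
                   sequence_info = as.character(sequence_info),
                   mw_kda = as.numeric(mw_kda),
                   isoelectric_point = as.numeric(isoelectric_point),
                   has_kinetics = as.logical(has_kinetics),
                   notes = as.character(notes), stringsAsFactors = FALSE)
  if (anyNA(df$has_purification) || anyNA(df$has_assay) || anyNA(df$has_kinetics)) {
    stop("purification/assay/kinetics indicators must be TRUE or FALSE, never NA")
  }
  key <- paste(df$ec, df$citation, df$organism, df$sequence_info, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (ec, citation, organism, sequence_info) combination")
  }
  class(df) <- c("identification_info", "data.frame")
  df
}

#' Write / read an identification-information table
#'
#' TSV with column order: EC, citation, organism, purification, assay,
#' sequence, molecular weight (kDa), isoelectric point, kinetics, notes.
#' Booleans are written as 1/0; absent optional values as empty cells,
#' never as 0. Reading the file back reproduces the records.
#'
#' @param rows an `identification_info` data frame.
#' @param path output path.
#' @return the number of rows written.
#' @export
write_identification_table <- function(rows, path) {
  out <- data.frame(ec = rows$ec, citation = rows$citation,
                    organism = rows$organism,
                    purification = as.integer(rows$has_purification),
                    assay = as.integer(rows$has_assay),
                    sequence = rows$sequence_info,
                    mw_kda = rows$mw_kda, pi = rows$isoelectric_point,
                    kinetics = as.integer(rows$has_kinetics),
                    notes = rows$notes, stringsAsFactors = FALSE)
  write_tsv(out, path)
  nrow(out)
}

#' @rdname write_identification_table
#' @export
read_identification_table <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  df$notes[is.na(df$notes)] <- ""
  identification_info(df$ec, df$citation, df$organism,
                      has_purification = df$purification == "1",
                      has_assay = df$assay == "1",
                      sequence_info = df$sequence,
                      mw_kda = as.numeric(df$mw_kda),
                      isoelectric_point = as.numeric(df$pi),
                      has_kinetics = df$kinetics == "1",
                      notes = df$notes)
}
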