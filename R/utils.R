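# Internal helpers shared across modules.

# Half-up decimal rounding (base round() is half-to-even). The small epsilon
# absorbs binary representation error in values like 49.085 stored as
# 49.0849999...; counts/denominator ratios never land closer than 1e-9 to a
# half boundary at the digit counts used here.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  trunc(abs(x) * p + 0.5 + 1e-9) * sign(x) / p
}

#' Percentage share with half-up rounding
#'
#' Computes `100 * count / total` rounded half-up to `digits` decimals, the
#' rounding convention used by every summary statistic in this package.
#'
#' @param count numerator count.
#' @param total denominator; must be positive.
#' @param digits decimals to keep (half-up).
#' @return numeric percentage.
#' @examples
#' share_pct(275, 1122, 2)  # 24.51
#' @export
share_pct <- function(count, total, digits = 2) {
  if (!is.numeric(total) || total <= 0) stop("total must be a positive number")
  round_half_up(100 * count / total, digits)
}

.greek_map <- c(
  "α" = "alpha",  "β" = "beta",  "γ" = "gamma",
  "δ" = "delta",  "ε" = "epsilon", "ζ" = "zeta",
  "η" = "eta",    "θ" = "theta", "ι" = "iota",
  "κ" = "kappa",  "λ" = "lambda", "μ" = "mu",
  "ν" = "nu",     "ξ" = "xi",    "π" = "pi",
  "ρ" = "rho",    "σ" = "sigma", "τ" = "tau",
  "υ" = "upsilon", "φ" = "phi",  "χ" = "chi",
  "ψ" = "psi",    "ω" = "omega",
  "Δ" = "Delta",  "Ω" = "Omega"
)

#' Normalize an enzyme name for comparison
#'
#' Applies the normalization used for all name matching in this package:
#' Greek letters are transliterated (\eqn{\alpha \to} "alpha", ...), internal
#' whitespace is collapsed, a trailing period is stripped, and the result is
#' lower-cased. Heterogeneously formatted sources (catalog files, abstracts,
#' annotation strings) compare equal after this mapping.
#'
#' @param x character vector of names.
#' @return character vector of normalized names.
#' @examples
#' normalize_name("Alcohol  dehydrogenase.")  # "alcohol dehydrogenase"
#' @export
normalize_name <- function(x) {
  for (g in names(.greek_map)) x <- gsub(g, .greek_map[[g]], x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", trimws(x))
  x <- sub("\\.$", "", x)
  tolower(x)
}

# TSV conventions used everywhere: tab-separated, no quoting, "" for NA.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "", check.names = FALSE,
                    colClasses = colClasses, comment.char = "#")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
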