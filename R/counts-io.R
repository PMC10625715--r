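#' Construct a per-site A/G count table
#'
#' The central data structure of the package: one row per strand-resolved
#' genomic A site with the number of reads observing a persistent `A`
#' (unconverted), a `G` (deaminated to inosine, read as G), or any other base.
#' Coordinates are 0-based. `other_count` is carried through but never enters
#' the binomial model, which is defined on A vs G only.
#'
#' @param x A data frame with columns `contig`, `pos` (0-based integer),
#'   `strand` (`"+"` or `"-"`), `a_count`, `g_count` and optionally
#'   `other_count` (defaults to 0).
#' @param role Sample role: `"treated"` (deaminated mRNA), `"ivt"`
#'   (modification-free in-vitro-transcribed control), `"fto_minus"`
#'   (deaminated, demethylase-untreated) or `"fto_plus"` (deaminated after
#'   FTO demethylation).
#' @param label Free-text sample label.
#' @param conversion_rate Optional sample-level conversion rate in `[0, 1]`;
#'   usually filled in later by [estimate_conversion_rate()] via
#'   [set_conversion_rate()].
#'
#' @return A tibble of class `etam_counts` with attributes `role`, `label`
#'   and `conversion_rate`, sorted by (contig, pos, strand).
#' @seealso [read_site_counts()], [estimate_conversion_rate()], [call_sites()]
#' @export
#' @examples
#' site_counts(
#'   data.frame(contig = "tx1", pos = 99L, strand = "+",
#'              a_count = 3L, g_count = 97L),
#'   role = "treated"
#' )
site_counts <- function(x, role = c("treated", "ivt", "fto_minus", "fto_plus"),
                        label = role, conversion_rate = NULL) {
  role <- match.arg(role)
  x <- as_tibble(x)
  needed <- c("contig", "pos", "strand", "a_count", "g_count")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    abort(sprintf("count table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"other_count" %in% names(x)) x$other_count <- 0L
  assert_strand(x$strand)
  for (col in c("pos", "a_count", "g_count", "other_count")) {
    assert_count_vec(x[[col]], col)
    x[[col]] <- as.integer(x[[col]])
  }
  key <- site_key(x$contig, x$pos, x$strand)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    abort(sprintf("duplicate site(s) in count table: %s",
                  paste(head(dups, 5L), collapse = ", ")))
  }
  if (!is.null(conversion_rate)) {
    assert_scalar_prob(conversion_rate, "conversion_rate")
  }
  x <- dplyr::arrange(x[, c(needed, "other_count")], .data$contig, .data$pos,
                      .data$strand)
  structure(x,
            class = c("etam_counts", class(tibble())),
            role = role, label = label,
            conversion_rate = conversion_rate)
}

#' @rdname site_counts
#' @param table An `etam_counts` table.
#' @export
sample_role <- function(table) attr(table, "role") %||% NA_character_

#' @rdname site_counts
#' @export
conversion_rate <- function(table) attr(table, "conversion_rate")

#' @rdname site_counts
#' @param value Conversion rate in `[0, 1]`.
#' @export
set_conversion_rate <- function(table, value) {
  assert_scalar_prob(value, "conversion_rate")
  attr(table, "conversion_rate") <- value
  table
}

# dplyr verbs strip subclass attributes; re-attach when needed internally
restore_counts_attrs <- function(x, template) {
  structure(as_tibble(x),
            class = c("etam_counts", class(tibble())),
            role = attr(template, "role"),
            label = attr(template, "label"),
            conversion_rate = attr(template, "conversion_rate"))
}

#' Read a per-site A/G count table from TSV
#'
#' Expects a tab-separated file with header columns `contig`, `pos`,
#' `strand`, `a_count`, `g_count`, `other_count` (0-based positions).
#' Duplicate (contig, pos, strand) rows and negative or non-integer counts
#' are rejected.
#'
#' @inheritParams site_counts
#' @param path Path to the TSV file.
#' @return An `etam_counts` tibble; see [site_counts()].
#' @export
read_site_counts <- function(path, role = c("treated", "ivt", "fto_minus", "fto_plus"),
                             label = basename(path), conversion_rate = NULL) {
  role <- match.arg(role)
  x <- readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(),
    pos = readr::col_double(),
    strand = readr::col_character(),
    a_count = readr::col_double(),
    g_count = readr::col_double(),
    other_count = readr::col_double()
  ), progress = FALSE)
  probs <- readr::problems(x)
  if (nrow(probs)) {
    abort(sprintf("malformed count table %s: parse failure at line %d (%s)",
                  path, probs$row[1] + 1L, probs$expected[1]))
  }
  site_counts(x, role = role, label = label, conversion_rate = conversion_rate)
}

#' Write a per-site count table to TSV
#'
#' @param table An `etam_counts` tibble (or any data frame with the same
#'   columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_counts <- function(table, path) {
  cols <- c("contig", "pos", "strand", "a_count", "g_count", "other_count")
  readr::write_tsv(as_tibble(table)[, cols], path, progress = FALSE)
  invisible(path)
}

#' @export
print.etam_counts <- function(x, ...) {
  cr <- conversion_rate(x)
  cat(sprintf("<etam_counts> role=%s label=%s sites=%d conversion_rate=%s\n",
              attr(x, "role"), attr(x, "label"), nrow(x),
              if (is.null(cr)) "unset" else format(cr, digits = 4)))
  NextMethod()
}
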