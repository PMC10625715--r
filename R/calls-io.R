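call_columns <- c("contig", "pos", "strand", "apparent_m", "accessibility",
                  "true_m", "exposed_m", "p_value", "q_value",
                  "a_treated", "g_treated", "a_control", "g_control",
                  "motif5", "motif_class", "passed")

#' Write a methylation call set to disk
#'
#' `format = "tsv"` writes all call columns; `format = "bed"` writes BED6
#' with name `"m6A"` and score `round(1000 * true_m)` (half-open 0-based
#' interval of width 1). Output is sorted by (contig, pos).
#'
#' @param calls A call tibble as returned by [call_sites()].
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @param passed_only For BED output, keep only sites with `passed = TRUE`
#'   (default); TSV always writes every evaluated site.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, format = c("tsv", "bed"), passed_only = format == "bed") {
  format <- match.arg(format)
  calls <- dplyr::arrange(as_tibble(calls), .data$contig, .data$pos)
  if (format == "tsv") {
    cols <- intersect(call_columns, names(calls))
    readr::write_tsv(calls[, cols], path, progress = FALSE)
  } else {
    if (passed_only) calls <- calls[calls$passed, , drop = FALSE]
    bed <- tibble(
      chrom = calls$contig,
      start = calls$pos,
      end = calls$pos + 1L,
      name = "m6A",
      score = as.integer(round(1000 * calls$true_m)),
      strand = calls$strand
    )
    readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}

#' Read a methylation call set written by [write_calls()]
#'
#' @param path Path to a call TSV.
#' @return A tibble of per-site calls.
#' @export
read_calls <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(),
    strand = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE)
  x$pos <- as.integer(x$pos)
  x
}
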