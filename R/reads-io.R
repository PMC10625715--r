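#' Construct a read-observation table
#'
#' A simplified representation of aligned, UMI-deduplicated reads: for each
#' read only the bases observed at its reference-A positions are kept, which
#' is all the deamination model needs. Positions are 0-based and strictly
#' increasing within a read; observed bases are in the RNA alphabet
#' (`A`, `G`, `C`, `U`, `N`; `T` on input is normalised to `U`).
#'
#' @param x A data frame with columns `read_id`, `umi` (optional, `NA` or
#'   `"-"` for absent), `contig`, `strand`, and list-columns (or
#'   comma-joined strings) `ref_a_positions` and `observed`.
#' @return A tibble of class `etam_reads` with list-columns
#'   `ref_a_positions` (integer) and `observed` (character).
#' @seealso [read_reads()], [filter_reads()], [count_sites()]
#' @export
read_observations <- function(x) {
  x <- as_tibble(x)
  needed <- c("read_id", "contig", "strand", "ref_a_positions", "observed")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    abort(sprintf("reads table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"umi" %in% names(x)) x$umi <- NA_character_
  x$umi <- dplyr::if_else(is.na(x$umi) | x$umi == "-", NA_character_, x$umi)
  assert_strand(x$strand)

  split_field <- function(v, f) {
    if (is.list(v)) return(v)
    lapply(strsplit(as.character(v), ",", fixed = TRUE),
           function(s) if (length(s) == 1L && (is.na(s) || s == "")) character(0) else f(s))
  }
  x$ref_a_positions <- lapply(split_field(x$ref_a_positions, identity), as.integer)
  x$observed <- lapply(split_field(x$observed, identity),
                       function(b) chartr("T", "U", toupper(b)))

  n_pos <- lengths(x$ref_a_positions)
  n_obs <- lengths(x$observed)
  bad_len <- which(n_pos != n_obs)
  if (length(bad_len)) {
    abort(sprintf("read %s: %d positions but %d observed bases",
                  x$read_id[bad_len[1]], n_pos[bad_len[1]], n_obs[bad_len[1]]))
  }
  bad_inc <- which(vapply(x$ref_a_positions,
                          function(p) length(p) > 1L && any(diff(p) <= 0L),
                          logical(1)))
  if (length(bad_inc)) {
    abort(sprintf("read %s: ref_a_positions must be strictly increasing",
                  x$read_id[bad_inc[1]]))
  }
  bad_base <- which(vapply(x$observed,
                           function(b) any(!b %in% c("A", "G", "C", "U", "N")),
                           logical(1)))
  if (length(bad_base)) {
    abort(sprintf("read %s: observed bases must be one of A, G, C, U, N",
                  x$read_id[bad_base[1]]))
  }
  class(x) <- c("etam_reads", class(tibble()))
  x[, c("read_id", "umi", "contig", "strand", "ref_a_positions", "observed")]
}

#' Read a reads table from TSV
#'
#' The on-disk format has one row per read with `ref_a_positions` and
#' `observed` comma-joined; a `umi` of `"-"` denotes an absent UMI.
#'
#' @param path Path to the TSV file.
#' @return An `etam_reads` tibble; see [read_observations()].
#' @export
read_reads <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    read_id = readr::col_character(),
    umi = readr::col_character(),
    contig = readr::col_character(),
    strand = readr::col_character(),
    ref_a_positions = readr::col_character(),
    observed = readr::col_character()
  ), progress = FALSE, na = character())
  probs <- readr::problems(x)
  if (nrow(probs)) {
    abort(sprintf("malformed reads table %s: parse failure at line %d",
                  path, probs$row[1] + 1L))
  }
  read_observations(x)
}

#' Write a reads table to TSV
#'
#' @param reads An `etam_reads` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  out <- tibble(
    read_id = reads$read_id,
    umi = dplyr::coalesce(reads$umi, "-"),
    contig = reads$contig,
    strand = reads$strand,
    ref_a_positions = vapply(reads$ref_a_positions, paste, "", collapse = ","),
    observed = vapply(reads$observed, paste, "", collapse = ",")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
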