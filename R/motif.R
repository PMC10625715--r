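#' Fetch the 5-mer sequence context of genomic A sites
#'
#' Returns the 5-nt window centred on each site, in the RNA alphabet
#' (`T` rendered as `U`), reverse-complemented for minus-strand sites so
#' that the motif always reads 5'-to-3' on the transcribed strand. The
#' centre character must be `A`; anything else is a reference mismatch.
#'
#' @param reference A `Biostrings::DNAStringSet`, a named character vector of
#'   sequences, or a path to a FASTA file.
#' @param contig,pos,strand Vectors describing the sites (0-based positions,
#'   strand `"+"` or `"-"`). Recycled to a common length.
#' @return A character vector of 5-mers, e.g. `"GGACU"`.
#' @export
#' @examples
#' ref <- c(tx1 = "TTGGACTTT")
#' fetch_motif(ref, "tx1", 4, "+")  # "GGACU"
fetch_motif <- function(reference, contig, pos, strand) {
  seqs <- load_reference(reference)
  n <- max(length(contig), length(pos), length(strand))
  contig <- rep_len(as.character(contig), n)
  pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(as.character(strand), n)
  assert_strand(strand)

  missing_ctg <- setdiff(unique(contig), names(seqs))
  if (length(missing_ctg)) {
    abort(sprintf("contig(s) not in reference: %s",
                  paste(head(missing_ctg, 5L), collapse = ", ")))
  }
  len <- nchar(seqs)[contig]
  bad <- which(pos < 2L | pos > len - 3L)
  if (length(bad)) {
    abort(sprintf("site %s:%d is within 2 nt of a contig end",
                  contig[bad[1]], pos[bad[1]]))
  }
  # 0-based centre pos -> 1-based window [pos-1, pos+3]
  win <- substr(seqs[contig], pos - 1L, pos + 3L)
  minus <- strand == "-"
  if (any(minus)) {
    win[minus] <- chartr("ACGT", "TGCA",
                         vapply(strsplit(win[minus], "", fixed = TRUE),
                                function(ch) paste(rev(ch), collapse = ""), ""))
  }
  motif <- chartr("T", "U", toupper(win))
  centre <- substr(motif, 3L, 3L)
  bad_centre <- which(centre != "A")
  if (length(bad_centre)) {
    abort(sprintf("reference mismatch: site %s:%d:%s has centre base %s, expected A",
                  contig[bad_centre[1]], pos[bad_centre[1]],
                  strand[bad_centre[1]], centre[bad_centre[1]]))
  }
  unname(motif)
}

#' @rdname fetch_motif
#' @param x A data frame with columns `contig`, `pos`, `strand`; a `motif5`
#'   column is added (and a `motif_class` column when `classify = TRUE`).
#' @param classify Also add the DRACH / non-DRACH class.
#' @export
add_motifs <- function(x, reference, classify = TRUE) {
  x <- as_tibble(x)
  x$motif5 <- fetch_motif(reference, x$contig, x$pos, x$strand)
  if (classify) x$motif_class <- classify_motif(x$motif5)
  x
}

#' Classify a 5-mer as DRACH or non-DRACH
#'
#' DRACH is the consensus sequence context of m6A in eukaryotes:
#' D = A/G/U, R = A/G, then the methylated A, then C, then H = A/C/U.
#'
#' @param motif5 Character vector of 5-mers with `A` at the centre
#'   (`T` accepted and treated as `U`).
#' @return Character vector, `"DRACH"` or `"non-DRACH"`.
#' @export
#' @examples
#' classify_motif(c("GGACU", "GGAUU", "CGACU"))
classify_motif <- function(motif5) {
  motif5 <- chartr("T", "U", toupper(motif5))
  if (any(nchar(motif5) != 5L)) abort("motifs must be 5 characters long")
  if (any(substr(motif5, 3L, 3L) != "A")) {
    abort("motif centre base must be A")
  }
  is_drach <- substr(motif5, 1L, 1L) %in% c("A", "G", "U") &
    substr(motif5, 2L, 2L) %in% c("A", "G") &
    substr(motif5, 4L, 4L) == "C" &
    substr(motif5, 5L, 5L) %in% c("A", "C", "U")
  ifelse(is_drach, "DRACH", "non-DRACH")
}

# Accept a DNAStringSet, a FASTA path, or a named character vector;
# return a named character vector of DNA-alphabet sequences.
load_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    return(setNames(as.character(reference), names(reference)))
  }
  if (is.character(reference) && length(reference) == 1L && is.null(names(reference)) &&
      file.exists(reference)) {
    ss <- Biostrings::readDNAStringSet(reference)
    # FASTA headers may carry descriptions; keep the first token
    return(setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
  }
  if (is.character(reference) && !is.null(names(reference))) {
    return(chartr("U", "T", toupper(reference)))
  }
  abort("`reference` must be a DNAStringSet, a named character vector, or a FASTA path")
}

#' Write reference sequences to FASTA
#'
#' @param reference Named character vector or `DNAStringSet`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  seqs <- load_reference(reference)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
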