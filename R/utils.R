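# internal helpers shared across modules

clip01 <- function(x) pmin(pmax(x, 0), 1)

# RNA alphabet: T on input is normalised to U in motif strings
rna_chars <- c("A", "C", "G", "U")

assert_scalar_prob <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` must lie in %s0, 1%s (got %g).", name,
                  if (allow_zero) "[" else "(", if (allow_one) "]" else ")", x))
  }
  invisible(x)
}

assert_count_vec <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
    abort(sprintf("`%s` must contain non-negative integers.", name))
  }
  invisible(x)
}

assert_strand <- function(strand) {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    abort(sprintf("strand must be '+' or '-' (got %s).",
                  paste(unique(strand[bad]), collapse = ", ")))
  }
  invisible(strand)
}

site_key <- function(contig, pos, strand) paste(contig, pos, strand, sep = ":")
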