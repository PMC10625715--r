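#' Remove reads from poorly deaminated RNA fragments
#'
#' Fragments that largely escaped the deaminase carry mostly unconverted A
#' and would masquerade as dense methylation. A read is removed when the
#' fraction of its reference-A positions still observed as `A` exceeds
#' `max_unconverted_fraction` (strictly). Reads covering no reference-A
#' positions carry no evidence either way and are kept.
#'
#' @param reads An `etam_reads` tibble (see [read_observations()]).
#' @param max_unconverted_fraction Removal threshold on the per-read
#'   unconverted-A fraction; default 0.5, i.e. reads with > 50% unconverted
#'   A are dropped.
#' @return The filtered `etam_reads` tibble.
#' @export
filter_reads <- function(reads, max_unconverted_fraction = 0.5) {
  assert_scalar_prob(max_unconverted_fraction, "max_unconverted_fraction")
  n_a <- vapply(reads$observed, function(b) sum(b == "A"), integer(1))
  n_pos <- lengths(reads$ref_a_positions)
  frac <- ifelse(n_pos == 0L, 0, n_a / pmax(n_pos, 1L))
  reads[frac <= max_unconverted_fraction, , drop = FALSE]
}

#' Tally per-site A/G counts from read observations
#'
#' Produces the per-site count table the estimators consume: for every
#' reference-A position covered by at least one read, the number of reads
#' observing `A`, `G`, or any other base. Reads should already be filtered
#' with [filter_reads()].
#'
#' @param reads An `etam_reads` tibble.
#' @inheritParams site_counts
#' @return An `etam_counts` tibble.
#' @export
count_sites <- function(reads, role = c("treated", "ivt", "fto_minus", "fto_plus"),
                        label = role) {
  role <- match.arg(role)
  if (nrow(reads) == 0L) {
    return(site_counts(tibble(contig = character(), pos = integer(),
                              strand = character(), a_count = integer(),
                              g_count = integer(), other_count = integer()),
                       role = role, label = label))
  }
  long <- tibble(
    contig = rep(reads$contig, lengths(reads$ref_a_positions)),
    strand = rep(reads$strand, lengths(reads$ref_a_positions)),
    pos = unlist(reads$ref_a_positions, use.names = FALSE),
    base = unlist(reads$observed, use.names = FALSE)
  )
  tallied <- long |>
    dplyr::group_by(.data$contig, .data$pos, .data$strand) |>
    dplyr::summarise(
      a_count = sum(.data$base == "A"),
      g_count = sum(.data$base == "G"),
      other_count = sum(!.data$base %in% c("A", "G")),
      .groups = "drop"
    )
  site_counts(tallied, role = role, label = label)
}

#' Estimate the sample-level conversion rate
#'
#' Under the assumption that the vast majority of A sites are unmethylated
#' and accessible, the sample conversion rate c is the pooled fraction of
#' converted (G) reads, `sum(g) / sum(a + g)`, over sites with coverage at
#' least `min_coverage`. An optional symmetric trim of the per-site
#' conversion-rate distribution guards against methylated or edited
#' outliers before pooling.
#'
#' @param table An `etam_counts` tibble (typically the IVT control or, for
#'   mRNA, all sites, dominated by unmethylated A).
#' @param min_coverage Minimum `a + g` for a site to enter the estimate.
#' @param trim Fraction trimmed from each tail of the per-site conversion
#'   distribution before pooling (0 = plain pooled ratio).
#' @return The estimated conversion rate, a number in `[0, 1]`.
#' @export
estimate_conversion_rate <- function(table, min_coverage = 20L, trim = 0) {
  if (!is.numeric(trim) || trim < 0 || trim >= 0.5) {
    abort("`trim` must lie in [0, 0.5)")
  }
  cov <- table$a_count + table$g_count
  keep <- cov >= min_coverage
  if (!any(keep)) {
    abort(sprintf("no sites with coverage >= %d; cannot estimate conversion rate",
                  min_coverage))
  }
  a <- table$a_count[keep]
  g <- table$g_count[keep]
  if (trim > 0) {
    rate <- g / (a + g)
    qs <- quantile(rate, c(trim, 1 - trim), names = FALSE, type = 7)
    inner <- rate >= qs[1] & rate <= qs[2]
    a <- a[inner]
    g <- g[inner]
  }
  sum(g) / sum(a + g)
}

#' Binomial maximum-likelihood estimate of apparent methylation
#'
#' At a fully accessible site the probability that a read shows a
#' persistent A is `pi = m + (1 - m) * (1 - c)`: either the molecule is
#' methylated (probability m) or it escaped conversion (probability 1 - c).
#' The MLE of m given `a` persistent-A reads out of `a + g` is the observed
#' A fraction corrected for the conversion background and clipped to the
#' parameter space:
#' \deqn{\hat m = \mathrm{clip}\left(\frac{a/(a+g) - (1-c)}{c},\; 0,\; 1\right)}
#'
#' @param a,g Persistent-A and converted-G read counts (vectors recycled).
#' @param c Sample conversion rate in `(0, 1]`.
#' @return Apparent methylation level(s) in `[0, 1]`.
#' @export
#' @examples
#' apparent_methylation(261, 739, 0.9831)
apparent_methylation <- function(a, g, c) {
  assert_scalar_prob(c, "c", allow_zero = FALSE)
  assert_count_vec(a, "a")
  assert_count_vec(g, "g")
  if (any(a + g < 1)) abort("apparent_methylation requires a + g >= 1")
  clip01((a / (a + g) - (1 - c)) / c)
}

#' Raw per-site deaminase accessibility from a modification-free control
#'
#' In an IVT (modification-free) control every A is unmethylated, so the
#' converted fraction at a site reflects only the sample conversion rate
#' and the site's accessibility s: `P(G) = c * s`. The raw estimate is the
#' observed G fraction divided by the control conversion rate, clipped to
#' `[0, 1]`; 0 means fully blocked, 1 fully accessible.
#'
#' @param a,g Persistent-A and converted-G read counts in the control.
#' @param c_control Control-sample conversion rate in `(0, 1]`.
#' @return Accessibility estimate(s) in `[0, 1]`.
#' @export
raw_accessibility <- function(a, g, c_control) {
  assert_scalar_prob(c_control, "c_control", allow_zero = FALSE)
  assert_count_vec(a, "a")
  assert_count_vec(g, "g")
  if (any(a + g < 1)) abort("raw_accessibility requires a + g >= 1")
  clip01((g / (a + g)) / c_control)
}

#' Accessibility-adjusted (true and exposed) methylation
#'
#' The apparent methylation of a partially blocked site underestimates the
#' molecular stoichiometry: only the accessible fraction of molecules can
#' report. True methylation divides the apparent level by accessibility
#' (clipped to `[0, 1]`); exposed methylation multiplies back,
#' `exposed = true * s = min(apparent, s)`, and is the quantity the >= 10%
#' call filter acts on. Accessibility 0 leaves true methylation undefined
#' (`NA`) and exposed methylation 0.
#'
#' @param apparent_m Apparent methylation in `[0, 1]`.
#' @param accessibility Site accessibility in `[0, 1]`.
#' @return A tibble with columns `true_m` and `exposed_m`.
#' @export
adjust_methylation <- function(apparent_m, accessibility) {
  if (any(apparent_m < 0 | apparent_m > 1, na.rm = TRUE)) {
    abort("`apparent_m` must lie in [0, 1]")
  }
  if (any(accessibility < 0 | accessibility > 1, na.rm = TRUE)) {
    abort("`accessibility` must lie in [0, 1]")
  }
  true_m <- ifelse(accessibility > 0, clip01(apparent_m / accessibility), NA_real_)
  exposed_m <- ifelse(accessibility > 0, true_m * accessibility, 0)
  tibble(true_m = true_m, exposed_m = exposed_m)
}
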