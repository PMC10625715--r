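#' One-sided Fisher exact test for persistent-A excess
#'
#' Tests, per site, whether the treated sample's persistent-A proportion
#' exceeds the control's — the direction in which methylation acts, since
#' m6A can only protect A from deamination. The p-value is the upper
#' hypergeometric tail of the 2x2 table (treated/control x A/G),
#' conditioned on its margins; this is the one-sided Fisher exact test.
#'
#' @param a_treated,g_treated A/G counts in the treated sample (vectors).
#' @param a_control,g_control A/G counts in the control sample.
#' @return A vector of p-values in `(0, 1]`.
#' @export
#' @examples
#' fisher_persistence_test(5, 5, 5, 5)    # 0.6719
#' fisher_persistence_test(10, 0, 0, 10)  # 1 / choose(20, 10)
fisher_persistence_test <- function(a_treated, g_treated, a_control, g_control) {
  assert_count_vec(a_treated, "a_treated")
  assert_count_vec(g_treated, "g_treated")
  assert_count_vec(a_control, "a_control")
  assert_count_vec(g_control, "g_control")
  if (any(a_treated + g_treated < 1) || any(a_control + g_control < 1)) {
    abort("both samples need coverage >= 1 at every tested site")
  }
  k_a <- a_treated + a_control           # white balls: A observations
  k_g <- g_treated + g_control           # black balls: G observations
  n_draw <- a_treated + g_treated        # draws: treated reads
  phyper(a_treated - 1, k_a, k_g, n_draw, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the
#' input. Thin wrapper over [stats::p.adjust()] so the calling layer has a
#' single, explicit multiple-testing policy.
#'
#' @param p_values Numeric vector of p-values.
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  p.adjust(p_values, method = "BH")
}

#' Calling parameters
#'
#' Bundles the published cutoffs: coverage at least 10 reads in both
#' samples, Fisher FDR < 0.05, exposed methylation >= 10%.
#'
#' @param min_coverage Minimum `a + g` required in both samples.
#' @param fdr_threshold BH q-value cutoff.
#' @param exposed_threshold Minimum exposed methylation
#'   (`true_m * accessibility`).
#' @param mode `"ivt"` (accessibility from a modification-free control) or
#'   `"fto"` (joint fit against a demethylase-treated control).
#' @param exclusion_sites Optional data frame of `contig`, `pos`, `strand`
#'   to exclude (e.g. known endogenous A-to-I editing sites).
#' @param e FTO efficiency bound, required in `"fto"` mode; see
#'   [estimate_fto_efficiency()].
#' @param grid_step Grid spacing for the FTO joint fit.
#' @return A list of class `etam_call_params`.
#' @export
call_params <- function(min_coverage = 10L, fdr_threshold = 0.05,
                        exposed_threshold = 0.10, mode = c("ivt", "fto"),
                        exclusion_sites = NULL, e = NULL, grid_step = 0.005) {
  mode <- match.arg(mode)
  assert_scalar_prob(fdr_threshold, "fdr_threshold")
  assert_scalar_prob(exposed_threshold, "exposed_threshold")
  structure(list(min_coverage = as.integer(min_coverage),
                 fdr_threshold = fdr_threshold,
                 exposed_threshold = exposed_threshold,
                 mode = mode, exclusion_sites = exclusion_sites,
                 e = e, grid_step = grid_step),
            class = "etam_call_params")
}

#' Call m6A sites from treated and control count tables
#'
#' Evaluates every site with coverage at least `min_coverage` in both
#' tables and not on the exclusion list. In `"ivt"` mode, apparent
#' methylation from the treated sample is adjusted by per-site
#' accessibility estimated from the modification-free control (shrunken
#' via [shrink_accessibility()] unless precomputed estimates are passed).
#' In `"fto"` mode, methylation and accessibility are fitted jointly per
#' site against the demethylase-treated control ([fit_fto()]). Each
#' evaluated site gets a one-sided Fisher p-value
#' ([fisher_persistence_test()]) and a BH q-value; a site passes when
#' `q < fdr_threshold` and `exposed_m >= exposed_threshold`. Failed sites
#' are retained with `passed = FALSE` for downstream analyses.
#'
#' @param treated `etam_counts` for the deaminated mRNA sample, conversion
#'   rate set.
#' @param control `etam_counts` for the control: IVT in `"ivt"` mode, the
#'   FTO-treated arm in `"fto"` mode; conversion rate set.
#' @param accessibility Optional precomputed accessibility tibble (from
#'   [shrink_accessibility()]) for `"ivt"` mode; computed internally when
#'   `NULL`.
#' @param params An [call_params()] object.
#' @param reference Optional reference (FASTA path, `DNAStringSet` or named
#'   character) used to annotate each call with its 5-mer motif.
#' @param seed Seed for the internal shrinkage step.
#' @return A tibble of per-site calls (class `etam_calls`): coordinates,
#'   counts in both samples, `apparent_m`, `accessibility`, `true_m`,
#'   `exposed_m`, `p_value`, `q_value`, `passed` and optionally `motif5` /
#'   `motif_class`. The stage-wise site funnel is available via
#'   [call_funnel()].
#' @export
call_sites <- function(treated, control, accessibility = NULL,
                       params = call_params(), reference = NULL, seed = 1L) {
  c_treated <- conversion_rate(treated)
  c_control <- conversion_rate(control)
  if (is.null(c_treated) || is.null(c_control)) {
    abort("conversion rates missing; run estimate_conversion_rate() on both tables")
  }
  funnel <- c(treated_sites = nrow(treated), control_sites = nrow(control))

  joined <- dplyr::inner_join(
    as_tibble(treated)[, c("contig", "pos", "strand", "a_count", "g_count")],
    as_tibble(control)[, c("contig", "pos", "strand", "a_count", "g_count")],
    by = c("contig", "pos", "strand"), suffix = c("_treated", "_control")
  )
  joined <- dplyr::filter(
    joined,
    .data$a_count_treated + .data$g_count_treated >= params$min_coverage,
    .data$a_count_control + .data$g_count_control >= params$min_coverage
  )
  funnel["coverage_pass"] <- nrow(joined)

  if (!is.null(params$exclusion_sites)) {
    excl <- site_key(params$exclusion_sites$contig, params$exclusion_sites$pos,
                     params$exclusion_sites$strand)
    joined <- joined[!site_key(joined$contig, joined$pos, joined$strand) %in% excl, ,
                     drop = FALSE]
  }
  funnel["evaluated"] <- nrow(joined)

  if (nrow(joined) == 0L) {
    out <- tibble(contig = character(), pos = integer(), strand = character(),
                  a_treated = integer(), g_treated = integer(),
                  a_control = integer(), g_control = integer(),
                  apparent_m = numeric(), accessibility = numeric(),
                  true_m = numeric(), exposed_m = numeric(),
                  p_value = numeric(), q_value = numeric(), passed = logical())
    funnel["passed"] <- 0L
    return(structure(out, class = c("etam_calls", class(tibble())),
                     funnel = funnel, mode = params$mode))
  }

  out <- tibble(
    contig = joined$contig, pos = joined$pos, strand = joined$strand,
    a_treated = joined$a_count_treated, g_treated = joined$g_count_treated,
    a_control = joined$a_count_control, g_control = joined$g_count_control
  )
  out$apparent_m <- apparent_methylation(out$a_treated, out$g_treated, c_treated)

  if (params$mode == "ivt") {
    if (is.null(accessibility)) {
      accessibility <- shrink_accessibility(
        accessibility_estimates(control, c_control), seed = seed)
    }
    s_col <- if ("shrunken_s" %in% names(accessibility)) "shrunken_s" else "raw_s"
    acc <- as_tibble(accessibility)[, c("contig", "pos", "strand", s_col)]
    names(acc)[4] <- "accessibility"
    out <- dplyr::left_join(out, acc, by = c("contig", "pos", "strand"))
    adj <- adjust_methylation(out$apparent_m, out$accessibility)
    out$true_m <- adj$true_m
    out$exposed_m <- adj$exposed_m
  } else {
    if (is.null(params$e)) abort("fto mode requires an efficiency bound `e` in call_params()")
    fits <- fit_fto(treated, control, e = params$e, c_minus = c_treated,
                    c_plus = c_control, min_coverage = params$min_coverage,
                    grid_step = params$grid_step)
    fits <- fits[, c("contig", "pos", "strand", "m_hat", "s_hat")]
    out <- dplyr::inner_join(out, fits, by = c("contig", "pos", "strand"))
    out$accessibility <- out$s_hat
    out$true_m <- out$m_hat
    out$exposed_m <- out$m_hat * out$s_hat
    out$m_hat <- out$s_hat <- NULL
  }

  out$p_value <- fisher_persistence_test(out$a_treated, out$g_treated,
                                         out$a_control, out$g_control)
  out$q_value <- bh_adjust(out$p_value)
  out$passed <- out$q_value < params$fdr_threshold &
    !is.na(out$exposed_m) & out$exposed_m >= params$exposed_threshold

  if (!is.null(reference)) out <- add_motifs(out, reference)
  funnel["passed"] <- sum(out$passed)
  structure(out, class = c("etam_calls", class(tibble())),
            funnel = funnel, mode = params$mode)
}

#' @rdname call_sites
#' @param calls A call tibble from [call_sites()].
#' @export
call_funnel <- function(calls) attr(calls, "funnel")

#' @export
print.etam_calls <- function(x, ...) {
  f <- call_funnel(x)
  if (!is.null(f)) {
    cat(sprintf("<etam_calls> mode=%s  evaluated=%d  passed=%d\n",
                attr(x, "mode") %||% "?", f[["evaluated"]], f[["passed"]]))
  }
  NextMethod()
}

#' Conversion-corrected stoichiometry for a single targeted site
#'
#' For amplicon or Sanger-trace readouts the raw persistent-A fraction
#' still contains the conversion background; the corrected stoichiometry
#' applies the same inversion as [apparent_methylation()], but directly on
#' a fraction: `clip((a_fraction - (1 - c)) / c, 0, 1)`.
#'
#' @param a_fraction Observed A fraction (trace peak ratio or tally) in
#'   `[0, 1]`.
#' @param c Conversion rate in `(0, 1]`.
#' @return Corrected methylation fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' quantify_target_site(0.80, c = 0.99)
quantify_target_site <- function(a_fraction, c) {
  assert_scalar_prob(c, "c", allow_zero = FALSE)
  if (any(a_fraction < 0 | a_fraction > 1)) abort("`a_fraction` must lie in [0, 1]")
  clip01((a_fraction - (1 - c)) / c)
}
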