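# joint binomial log-likelihood for the FTO-control model:
# P(A | minus) = 1 - c_minus * s * (1 - m)
# P(A | plus)  = 1 - c_plus  * s * (1 - m * (1 - e))
fto_loglik <- function(m, s, a_minus, g_minus, a_plus, g_plus, c_minus, c_plus, e) {
  p_minus <- 1 - c_minus * s * (1 - m)
  p_plus <- 1 - c_plus * s * (1 - m * (1 - e))
  term <- function(k, p) if (k == 0) rep(0, length(p)) else k * log(p)
  term(a_minus, p_minus) + term(g_minus, 1 - p_minus) +
    term(a_plus, p_plus) + term(g_plus, 1 - p_plus)
}

#' Upper bound on FTO demethylation efficiency from spike-in probes
#'
#' FTO demethylates only part of the m6A in a sample. Fully methylated
#' spike-in probes carried through the minus- and plus-FTO arms report how
#' much methylation survives the treatment: the efficiency bound is
#' `e = clip(1 - m_plus / m_minus, 0, 1)`, where each `m` is the pooled
#' apparent-methylation estimate on the 100% m6A probes. The joint model
#' ([joint_fit_fto()]) uses this bound as its fixed `e`, which makes the
#' methylation estimates conservatively low.
#'
#' @param probes_minus,probes_plus Probe tibbles (see [simulate_probes()])
#'   with columns `designed_m6a_fraction`, `a_count`, `g_count`; each must
#'   include probes with designed fraction 1.
#' @param c_minus,c_plus Conversion rates of the two arms (`c_plus`
#'   defaults to `c_minus`).
#' @return The efficiency bound, a number in `[0, 1]`.
#' @export
estimate_fto_efficiency <- function(probes_minus, probes_plus, c_minus,
                                    c_plus = c_minus) {
  pooled_m <- function(probes, c, arm) {
    full <- probes[probes$designed_m6a_fraction == 1, , drop = FALSE]
    if (nrow(full) == 0L) {
      abort(sprintf("%s probe set contains no fully methylated (fraction 1) probes", arm))
    }
    apparent_methylation(sum(full$a_count), sum(full$g_count), c)
  }
  m_minus <- pooled_m(probes_minus, c_minus, "minus-FTO")
  m_plus <- pooled_m(probes_plus, c_plus, "plus-FTO")
  if (m_minus == 0) abort("minus-FTO probes report zero methylation; cannot form ratio")
  clip01(1 - m_plus / m_minus)
}

#' Joint maximum-likelihood fit of methylation and accessibility from FTO controls
#'
#' Without a modification-free control, accessibility and methylation must
#' be separated using the demethylase-treated (FTO+) arm: both arms share
#' the site accessibility `s`, while methylation is `m` in the untreated
#' arm and `m * (1 - e)` after FTO treatment with efficiency `e`. The two
#' binomial likelihoods are maximised jointly over `(m, s)` on `[0, 1]^2`
#' by a dense grid search (step `grid_step`) followed by local refinement.
#' If the surface is flat along a ridge (small `e` confounds `m` and `s`),
#' the solution with maximal `s` is reported — the conservative,
#' "accessible but less methylated" call.
#'
#' @param a_minus,g_minus A/G counts in the untreated (FTO-) arm.
#' @param a_plus,g_plus A/G counts in the FTO-treated arm.
#' @param c_minus,c_plus Conversion rates of the two arms.
#' @param e FTO efficiency in `(0, 1]`; `e = 0` makes the model
#'   unidentifiable and is an error. See [estimate_fto_efficiency()].
#' @param grid_step Grid spacing for the initial search.
#' @param refine Run a bounded quasi-Newton refinement from the grid
#'   optimum.
#' @return A one-row tibble with `m_hat`, `s_hat`, `e_used`, `loglik`.
#' @export
#' @examples
#' joint_fit_fto(50, 50, 1, 99, c_minus = 1, c_plus = 1, e = 1)
joint_fit_fto <- function(a_minus, g_minus, a_plus, g_plus, c_minus, c_plus, e,
                          grid_step = 0.005, refine = TRUE) {
  assert_count_vec(c(a_minus, g_minus, a_plus, g_plus), "counts")
  if (a_minus + g_minus < 1 || a_plus + g_plus < 1) {
    abort("joint_fit_fto requires coverage >= 1 in both arms")
  }
  assert_scalar_prob(c_minus, "c_minus", allow_zero = FALSE)
  assert_scalar_prob(c_plus, "c_plus", allow_zero = FALSE)
  assert_scalar_prob(e, "e")
  if (e == 0) abort("e = 0: methylation and accessibility are unidentifiable")

  grid <- seq(0, 1, by = grid_step)
  # rows = m, cols = s
  ll <- outer(grid, grid, fto_loglik,
              a_minus = a_minus, g_minus = g_minus,
              a_plus = a_plus, g_plus = g_plus,
              c_minus = c_minus, c_plus = c_plus, e = e)
  best <- max(ll)
  near <- which(ll >= best - 1e-9, arr.ind = TRUE)
  # ridge tie-break: maximal s, then minimal m ("accessible, less methylated")
  pick <- near[order(-near[, 2], near[, 1])[1], ]
  m_hat <- grid[pick[1]]
  s_hat <- grid[pick[2]]
  loglik <- ll[pick[1], pick[2]]

  if (refine) {
    eps <- 1e-9
    obj <- function(par) {
      -fto_loglik(par[1], par[2], a_minus, g_minus, a_plus, g_plus,
                  c_minus, c_plus, e)
    }
    opt <- tryCatch(
      optim(c(min(max(m_hat, eps), 1 - eps), min(max(s_hat, eps), 1 - eps)),
            obj, method = "L-BFGS-B", lower = 0, upper = 1),
      error = function(err) NULL)
    if (!is.null(opt) && is.finite(opt$value) && -opt$value > loglik) {
      m_hat <- opt$par[1]
      s_hat <- opt$par[2]
      loglik <- -opt$value
    }
  }
  tibble(m_hat = m_hat, s_hat = s_hat, e_used = e, loglik = loglik)
}

#' Fit the FTO joint model at every shared site of two count tables
#'
#' @param minus,plus `etam_counts` tibbles for the FTO- and FTO+ arms, with
#'   conversion rates set (or supplied via `c_minus` / `c_plus`).
#' @param e FTO efficiency bound.
#' @inheritParams joint_fit_fto
#' @param min_coverage Sites need `a + g >= min_coverage` in both arms.
#' @return A tibble with one row per fitted site: site coordinates, both
#'   arms' counts, `m_hat`, `s_hat`, `e_used`, `loglik`.
#' @export
fit_fto <- function(minus, plus, e,
                    c_minus = conversion_rate(minus),
                    c_plus = conversion_rate(plus),
                    min_coverage = 1L, grid_step = 0.005) {
  if (is.null(c_minus) || is.null(c_plus)) {
    abort("conversion rates missing; run estimate_conversion_rate() on both tables")
  }
  joined <- dplyr::inner_join(
    as_tibble(minus)[, c("contig", "pos", "strand", "a_count", "g_count")],
    as_tibble(plus)[, c("contig", "pos", "strand", "a_count", "g_count")],
    by = c("contig", "pos", "strand"), suffix = c("_minus", "_plus")
  ) |>
    dplyr::filter(.data$a_count_minus + .data$g_count_minus >= min_coverage,
                  .data$a_count_plus + .data$g_count_plus >= min_coverage)
  fits <- purrr::pmap(
    list(joined$a_count_minus, joined$g_count_minus,
         joined$a_count_plus, joined$g_count_plus),
    function(am, gm, ap, gp) {
      joint_fit_fto(am, gm, ap, gp, c_minus = c_minus, c_plus = c_plus,
                    e = e, grid_step = grid_step)
    }
  )
  dplyr::bind_cols(joined, dplyr::bind_rows(fits))
}
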