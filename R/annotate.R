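#' Calibration points from probe counts
#'
#' Converts a probe table into (designed m6A %, persistent A %) pairs for
#' [fit_calibration()].
#'
#' @param probes A tibble with columns `designed_m6a_fraction`, `a_count`,
#'   `g_count` (see [simulate_probes()]).
#' @return A tibble with `designed_pct` and `persistent_a_pct`.
#' @export
calibration_points <- function(probes) {
  tibble(designed_pct = 100 * probes$designed_m6a_fraction,
         persistent_a_pct = 100 * probes$a_count / (probes$a_count + probes$g_count))
}

#' Linear calibration of persistent-A signal against designed m6A content
#'
#' Ordinary least-squares fit of the persistent-A percentage on the
#' designed m6A percentage across spike-in probes. A slope near 1 and a
#' coefficient of determination near 1 demonstrate that the persistent-A
#' readout quantifies stoichiometry linearly.
#'
#' @param points A data frame with columns `designed_pct` and
#'   `persistent_a_pct` (see [calibration_points()]), at least two rows
#'   with distinct x values.
#' @return An object of class `etam_calibration` with elements `slope`,
#'   `intercept`, `r_squared`, `n_points`, the underlying `lm` fit and the
#'   data. Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' pts <- data.frame(designed_pct = c(0, 25, 50, 75, 100),
#'                   persistent_a_pct = c(1.69, 26.1, 46.5, 73.9, 98.7))
#' glance(fit_calibration(pts))
fit_calibration <- function(points) {
  points <- as_tibble(points)
  if (nrow(points) < 2L) abort("calibration needs at least 2 points")
  if (length(unique(points$designed_pct)) < 2L) {
    abort("calibration x values are all equal; cannot fit")
  }
  model <- lm(persistent_a_pct ~ designed_pct, data = points)
  # collinear probe series are expected; a perfect fit is not a defect
  sm <- suppressWarnings(summary(model))
  structure(list(slope = unname(coef(model)[2]),
                 intercept = unname(coef(model)[1]),
                 r_squared = sm$r.squared,
                 n_points = nrow(points),
                 model = model, data = points),
            class = "etam_calibration")
}

#' @export
print.etam_calibration <- function(x, ...) {
  cat(sprintf("<etam_calibration> slope=%.4f intercept=%.3f r^2=%.4f n=%d\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
tidy.etam_calibration <- function(x, ...) {
  co <- suppressWarnings(summary(x$model))$coefficients
  tibble(term = rownames(co), estimate = co[, 1], std.error = co[, 2],
         statistic = co[, 3], p.value = co[, 4])
}

#' @export
glance.etam_calibration <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r.squared = x$r_squared,
         n_points = x$n_points)
}

#' Gaps between neighbouring sites within transcripts
#'
#' Successive positional differences within each transcript, pooled over
#' transcripts; transcripts with fewer than two sites contribute nothing.
#'
#' @param sites A data frame with a transcript identifier column and a
#'   position column (transcript coordinates).
#' @param transcript_col,pos_col Column names.
#' @return A list with `gaps` (tibble of `transcript_id`, `gap`) and
#'   `median_gap` (`NA` when no transcript has two sites).
#' @export
#' @examples
#' neighbor_gaps(data.frame(contig = "T1", pos = c(10, 72)))$median_gap
neighbor_gaps <- function(sites, transcript_col = "contig", pos_col = "pos") {
  sites <- as_tibble(sites)
  gaps <- sites |>
    dplyr::group_by(transcript_id = .data[[transcript_col]]) |>
    dplyr::reframe(gap = diff(sort(.data[[pos_col]])))
  list(gaps = gaps,
       median_gap = if (nrow(gaps)) median(gaps$gap) else NA_real_)
}

#' Permutation null for the median neighbour gap
#'
#' Draws `n_sites` positions from the candidate A sites (uniformly without
#' replacement, or stratified so the drawn 5-mer motif frequencies exactly
#' match those observed in the call set) and records the median neighbour
#' gap per draw. Observed medians well below the null distribution
#' indicate clustering of methylation sites.
#'
#' @param candidates A data frame of candidate sites with transcript and
#'   position columns (typically all evaluated A sites), plus a `motif5`
#'   column for motif-matched sampling.
#' @param n_sites Number of sites per draw.
#' @param mode `"unconstrained"` or `"motif_matched"`.
#' @param observed_motifs 5-mers of the observed call set (required for
#'   motif-matched mode); the drawn motif counts reproduce this table
#'   exactly.
#' @param reps Number of permutation draws.
#' @param seed Integer seed; draws are deterministic given the seed.
#' @param scope `"pooled"` samples across the whole candidate set;
#'   `"per_transcript"` allocates the draw across transcripts in
#'   proportion to their candidate counts.
#' @inheritParams neighbor_gaps
#' @param return_draws Also return the sampled candidate rows per rep as a
#'   list-column `draw` (for diagnostics).
#' @return A tibble with columns `rep` and `median_gap` (plus `draw` when
#'   requested).
#' @export
permutation_gap_null <- function(candidates, n_sites,
                                 mode = c("unconstrained", "motif_matched"),
                                 observed_motifs = NULL, reps = 10L, seed = 1L,
                                 scope = c("pooled", "per_transcript"),
                                 transcript_col = "contig", pos_col = "pos",
                                 return_draws = FALSE) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  candidates <- as_tibble(candidates)
  n_cand <- nrow(candidates)
  if (n_sites > n_cand) abort("n_sites exceeds the number of candidate sites")

  draw_one <- function() {
    if (mode == "motif_matched") {
      if (is.null(observed_motifs)) abort("motif_matched mode requires observed_motifs")
      quota <- table(observed_motifs)
      idx <- integer(0)
      for (mt in names(quota)) {
        pool <- which(candidates$motif5 == mt)
        if (length(pool) < quota[[mt]]) {
          abort(sprintf("motif stratum %s has %d candidates but quota %d",
                        mt, length(pool), quota[[mt]]))
        }
        idx <- c(idx, sample(pool, quota[[mt]]))
      }
      idx
    } else if (scope == "per_transcript") {
      tx <- candidates[[transcript_col]]
      counts <- table(tx)
      # largest-remainder proportional allocation
      exact <- n_sites * as.numeric(counts) / n_cand
      base <- floor(exact)
      rem <- n_sites - sum(base)
      if (rem > 0) {
        top_up <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
        base[top_up] <- base[top_up] + 1L
      }
      unlist(purrr::map2(names(counts), base, function(t, k) {
        if (k == 0) return(integer(0))
        sample(which(tx == t), min(k, sum(tx == t)))
      }), use.names = FALSE)
    } else {
      sample.int(n_cand, n_sites)
    }
  }

  with_seed(seed, {
    draws <- lapply(seq_len(reps), function(i) {
      candidates[draw_one(), , drop = FALSE]
    })
    out <- tibble(rep = seq_len(reps),
                  median_gap = vapply(draws, function(d) {
                    neighbor_gaps(d, transcript_col = transcript_col,
                                  pos_col = pos_col)$median_gap
                  }, numeric(1)))
    if (return_draws) out$draw <- draws
    out
  })
}

#' Methylation load of a transcript
#'
#' The sum of the (true) methylation levels of all called sites on a
#' transcript; a transcript with sites at 0.3, 0.7 and 1.0 carries a load
#' of 2.0.
#'
#' @param true_m Methylation levels in `[0, 1]`.
#' @return The load, a non-negative number (0 for an empty input).
#' @export
methylation_load <- function(true_m) {
  if (any(true_m < 0 | true_m > 1, na.rm = TRUE)) {
    abort("`true_m` values must lie in [0, 1]")
  }
  sum(true_m, na.rm = TRUE)
}

#' Per-transcript methylation loads from a call set
#'
#' Considers every transcript carrying at least one evaluated site; the
#' load sums `true_m` over its *passed* calls (0 when none passed).
#'
#' @param calls A call tibble from [call_sites()].
#' @param transcript_col Column identifying the transcript.
#' @return A tibble with `transcript_id` and `load`.
#' @export
transcript_loads <- function(calls, transcript_col = "contig") {
  as_tibble(calls) |>
    dplyr::group_by(transcript_id = .data[[transcript_col]]) |>
    dplyr::summarise(load = methylation_load(.data$true_m[.data$passed]),
                     .groups = "drop")
}

#' Bin transcripts by methylation load
#'
#' Transcripts with zero load form the `none` bin; the rest are ranked by
#' load (descending, ties broken by transcript id) and split into
#' `high` / `medium` / `low` tertiles by rank, any remainder assigned
#' top-down so bin sizes differ by at most one.
#'
#' @param loads A tibble with `transcript_id` and `load`
#'   (see [transcript_loads()]).
#' @return The input with a `bin` factor column
#'   (`high`, `medium`, `low`, `none`).
#' @export
bin_by_load <- function(loads) {
  loads <- as_tibble(loads)
  lvls <- c("high", "medium", "low", "none")
  meth <- loads[loads$load > 0, , drop = FALSE]
  meth <- meth[order(-meth$load, meth$transcript_id), , drop = FALSE]
  n <- nrow(meth)
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- base + c(rem >= 1L, rem >= 2L, 0L)
  meth$bin <- rep(lvls[1:3], times = sizes)
  none <- loads[loads$load == 0, , drop = FALSE]
  if (nrow(none)) none$bin <- "none"
  out <- dplyr::bind_rows(meth, none)
  out$bin <- factor(out$bin, levels = lvls)
  dplyr::arrange(out, .data$bin, dplyr::desc(.data$load), .data$transcript_id)
}

#' Compare mRNA half-lives across methylation-load bins
#'
#' Summarises half-lives per bin and tests, for each methylated bin,
#' whether its half-lives are shorter than those of the unmethylated
#' (`none`) reference bin with a one-tailed Wilcoxon rank-sum test.
#'
#' @param bins Output of [bin_by_load()].
#' @param half_lives A data frame with `transcript_id` and
#'   `half_life_hours` (see [read_half_lives()]).
#' @return A tibble with one row per bin: `bin`, `n`, `mean_half_life`,
#'   `median_half_life`, `p_value` (vs the `none` bin; `NA` for the
#'   reference itself).
#' @export
compare_half_lives <- function(bins, half_lives) {
  joined <- dplyr::inner_join(as_tibble(bins), as_tibble(half_lives),
                              by = "transcript_id")
  ref <- joined$half_life_hours[joined$bin == "none"]
  if (!length(ref)) abort("reference (none) bin has no transcripts with half-lives")
  joined |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_half_life = mean(.data$half_life_hours),
      median_half_life = median(.data$half_life_hours),
      p_value = if (dplyr::first(.data$bin) == "none") NA_real_ else {
        wilcox.test(.data$half_life_hours, ref, alternative = "less",
                    exact = FALSE)$p.value
      },
      .groups = "drop"
    )
}

#' Read a half-life table (TSV: `transcript_id`, `half_life_hours`)
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_half_lives <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    transcript_id = readr::col_character(),
    half_life_hours = readr::col_double()
  ), progress = FALSE)
}

#' Spike-in amount per microgram of total RNA
#'
#' `y = d * v * c / t`: dilution factor times volume (uL) times
#' concentration (attomole/uL), divided by total RNA mass (ug).
#'
#' @param d Dilution factor.
#' @param v Volume in microliters.
#' @param c Concentration in attomole per microliter.
#' @param t Total RNA mass in micrograms; must be positive.
#' @return Spike-in amount in attomole per microgram.
#' @export
spike_in_amount <- function(d, v, c, t) {
  if (any(t <= 0)) abort("`t` (total RNA, ug) must be positive")
  d * v * c / t
}

#' Read a transcript annotation table
#'
#' TSV with columns `transcript_id`, `contig`, `strand`, `exon_starts`,
#' `exon_ends` (comma-joined 0-based half-open intervals, sorted and
#' non-overlapping).
#'
#' @param path Path to the TSV file.
#' @return A tibble with list-columns `exon_starts` and `exon_ends`.
#' @export
read_annotation <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  x$exon_starts <- lapply(strsplit(x$exon_starts, ",", fixed = TRUE), as.integer)
  x$exon_ends <- lapply(strsplit(x$exon_ends, ",", fixed = TRUE), as.integer)
  bad <- which(mapply(function(s, e) {
    length(s) != length(e) || any(e <= s) || (length(s) > 1 && any(diff(s) <= 0))
  }, x$exon_starts, x$exon_ends))
  if (length(bad)) {
    abort(sprintf("annotation %s: malformed exons for transcript %s",
                  path, x$transcript_id[bad[1]]))
  }
  as_tibble(x)
}

#' Project genomic sites onto spliced transcript coordinates
#'
#' Gap statistics are biologically within-transcript distances, so when an
#' annotation is available genomic call positions are converted to
#' exon-concatenated (spliced) coordinates, measured from the transcript
#' 5' end (strand-aware). Sites falling outside every exon of every
#' matching transcript are dropped.
#'
#' @param sites A data frame with `contig`, `pos`, `strand`.
#' @param annotation Annotation tibble from [read_annotation()].
#' @return The input rows that map, with `transcript_id` and `tx_pos`
#'   columns added (one row per site x matching transcript).
#' @export
map_to_transcript <- function(sites, annotation) {
  sites <- as_tibble(sites)
  hits <- purrr::pmap(annotation, function(transcript_id, contig, strand,
                                           exon_starts, exon_ends, ...) {
    on_tx <- sites$contig == contig & sites$strand == strand
    if (!any(on_tx)) return(NULL)
    sub <- sites[on_tx, , drop = FALSE]
    exlen <- exon_ends - exon_starts
    cum <- cumsum(c(0L, exlen))[seq_along(exon_starts)]
    exon_idx <- vapply(sub$pos, function(p) {
      i <- which(p >= exon_starts & p < exon_ends)
      if (length(i)) i[1] else NA_integer_
    }, integer(1))
    keep <- !is.na(exon_idx)
    if (!any(keep)) return(NULL)
    sub <- sub[keep, , drop = FALSE]
    exon_idx <- exon_idx[keep]
    fwd <- cum[exon_idx] + (sub$pos - exon_starts[exon_idx])
    total <- sum(exlen)
    sub$transcript_id <- transcript_id
    sub$tx_pos <- if (strand == "+") fwd else total - 1L - fwd
    sub
  })
  dplyr::bind_rows(hits)
}
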