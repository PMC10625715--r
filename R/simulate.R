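#' Distribution specifications for the simulator
#'
#' Small named-distribution objects used in [sim_config()]. Supported:
#' `"fixed"` (`value`), `"uniform"` (`min`, `max`), `"beta"` (`shape1`,
#' `shape2`), `"levels"` (discrete `values` with optional `probs`),
#' `"poisson"` (`lambda`), `"nbinom"` (`mu`, `size`), and
#' `"accessibility_default"` — the empirical shape of deaminase
#' accessibility in cellular transcriptomes: 92% of sites are nearly fully
#' accessible (>= 0.9, most of them exactly 1), the rest uniform on
#' (0.2, 0.9).
#'
#' @param name Distribution name.
#' @param ... Parameters (see above).
#' @return A list of class `sim_dist`.
#' @export
sim_dist <- function(name, ...) {
  structure(c(list(name = name), list(...)), class = "sim_dist")
}

draw_dist <- function(d, n) {
  if (!inherits(d, "sim_dist")) d <- do.call(sim_dist, d)
  switch(d$name,
    fixed = rep(d$value, n),
    uniform = runif(n, d$min, d$max),
    beta = stats::rbeta(n, d$shape1, d$shape2),
    levels = sample(d$values, n, replace = TRUE, prob = d$probs),
    poisson = rpois(n, d$lambda),
    nbinom = rnbinom(n, mu = d$mu, size = d$size),
    accessibility_default = {
      high <- runif(n) < 0.92
      s <- numeric(n)
      # accessible bulk: mostly fully exposed, remainder just under 1
      full <- high & runif(n) < 0.75
      s[full] <- 1
      s[high & !full] <- runif(sum(high & !full), 0.9, 1)
      s[!high] <- runif(sum(!high), 0.2, 0.9)
      s
    },
    abort(sprintf("unknown distribution '%s'", d$name))
  )
}

#' Simulation configuration
#'
#' Defines the generative model shared by all simulator outputs. A read of
#' an unedited site shows a persistent `A` with probability
#' `pi = 1 - c * s * (1 - m_eff)`: conversion requires sample-level
#' deaminase competence `c`, site accessibility `s`, and the absence of a
#' methyl mark. `m_eff` is the true methylation `m` for treated and
#' FTO-untreated samples, 0 for the IVT control, and `m * (1 - e)` after
#' FTO treatment with efficiency `e`. Endogenously edited sites carry a
#' persistent G excess in *both* samples (the editing level is the
#' fraction of molecules already converted genomically), so they mimic
#' high conversion, not methylation.
#'
#' @param n_transcripts,transcript_length Number and length (scalar or
#'   `c(min, max)` range) of random transcripts.
#' @param n_m6a_sites Number of methylated sites to place.
#' @param methylation_distribution Distribution of true methylation levels
#'   at m6A sites; default near-uniform on (0, 1).
#' @param accessibility_distribution Per-site accessibility distribution;
#'   default `"accessibility_default"` (92% of sites >= 0.9).
#' @param coverage_distribution Per-site read-depth distribution; default
#'   negative binomial with mean 50.
#' @param conversion_rate_treated,conversion_rate_control Sample
#'   conversion rates (treated / FTO arms vs IVT control).
#' @param fto_efficiency FTO demethylation efficiency used for the
#'   `fto_plus` role.
#' @param editing_fraction Fraction of unmethylated A sites given
#'   endogenous A-to-I editing; editing levels are uniform on (0.2, 1).
#' @param drach_fraction Fraction of m6A sites placed at DRACH-centre As.
#' @param placement `"uniform"` scatters m6A sites over candidate As;
#'   `"clustered"` concentrates them around randomly chosen anchors
#'   (window `cluster_width`), for studying site clustering.
#' @param cluster_width Half-window (nt) for clustered placement.
#' @param fragment_length Simulated read length.
#' @param poorly_processed_fraction Fraction of reads from fragments that
#'   largely escaped the deaminase.
#' @param poorly_processed_conversion Multiplier on `c` for those reads.
#' @param other_rate Per-read probability of a non-A/G observation
#'   (sequencing error / mispriming), kept out of the model.
#' @param seed Integer seed; fully determines every simulator output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 20L,
                       transcript_length = 1500L,
                       n_m6a_sites = 150L,
                       methylation_distribution = sim_dist("uniform", min = 0.05, max = 1),
                       accessibility_distribution = sim_dist("accessibility_default"),
                       coverage_distribution = sim_dist("nbinom", mu = 50, size = 5),
                       conversion_rate_treated = 0.99,
                       conversion_rate_control = 0.99,
                       fto_efficiency = 0.9,
                       editing_fraction = 0.005,
                       drach_fraction = 0.85,
                       placement = c("uniform", "clustered"),
                       cluster_width = 150L,
                       fragment_length = 100L,
                       poorly_processed_fraction = 0.05,
                       poorly_processed_conversion = 0.2,
                       other_rate = 0.002,
                       seed = 1L) {
  placement <- match.arg(placement)
  for (nm in c("conversion_rate_treated", "conversion_rate_control",
               "fto_efficiency", "editing_fraction", "drach_fraction",
               "poorly_processed_fraction", "poorly_processed_conversion",
               "other_rate")) {
    assert_scalar_prob(get(nm), nm)
  }
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    transcript_length = as.integer(transcript_length),
    n_m6a_sites = as.integer(n_m6a_sites),
    methylation_distribution = methylation_distribution,
    accessibility_distribution = accessibility_distribution,
    coverage_distribution = coverage_distribution,
    conversion_rate_treated = conversion_rate_treated,
    conversion_rate_control = conversion_rate_control,
    fto_efficiency = fto_efficiency,
    editing_fraction = editing_fraction,
    drach_fraction = drach_fraction,
    placement = placement,
    cluster_width = as.integer(cluster_width),
    fragment_length = as.integer(fragment_length),
    poorly_processed_fraction = poorly_processed_fraction,
    poorly_processed_conversion = poorly_processed_conversion,
    other_rate = other_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Read / write a simulator configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_sim_config()` returns a [sim_config()]; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in grep("_distribution$", names(raw), value = TRUE)) {
    raw[[nm]] <- do.call(sim_dist, as.list(raw[[nm]]))
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config A [sim_config()] object.
#' @export
write_sim_config <- function(config, path) {
  jsonlite::write_json(lapply(unclass(config), function(x) {
    if (inherits(x, "sim_dist")) unclass(x) else x
  }), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a transcriptome with known m6A truth
#'
#' Generates random transcript sequences, records every interior A site
#' (at least 2 nt from the ends, so each has a full 5-mer context), and
#' places `n_m6a_sites` methylated sites — preferentially at DRACH centres
#' (`drach_fraction`) under uniform placement, or around random anchors
#' under clustered placement. Per-site accessibility and editing status
#' are drawn for every A site. Fully deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `reference` (named character vector, DNA alphabet)
#'   and `truth`, a tibble with one row per tracked A site: `contig`,
#'   `pos`, `strand`, `motif5`, `motif_class`, `is_m6a`, `m`, `s`,
#'   `is_edited`, `editing_level`.
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    lens <- if (length(config$transcript_length) == 2L) {
      sample(config$transcript_length[1]:config$transcript_length[2],
             config$n_transcripts, replace = TRUE)
    } else rep(config$transcript_length, config$n_transcripts)
    ids <- sprintf("tx%03d", seq_len(config$n_transcripts))
    reference <- setNames(vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, ""), ids)

    truth <- purrr::map2(ids, reference, function(id, seq) {
      ch <- strsplit(seq, "", fixed = TRUE)[[1]]
      pos <- which(ch == "A") - 1L            # 0-based
      pos <- pos[pos >= 2L & pos <= nchar(seq) - 3L]
      if (!length(pos)) return(NULL)
      tibble(contig = id, pos = pos, strand = "+")
    }) |> dplyr::bind_rows()
    truth$motif5 <- fetch_motif(reference, truth$contig, truth$pos, truth$strand)
    truth$motif_class <- classify_motif(truth$motif5)

    n_sites <- nrow(truth)
    if (config$n_m6a_sites > n_sites) {
      abort(sprintf("n_m6a_sites = %d exceeds the %d available A sites",
                    config$n_m6a_sites, n_sites))
    }
    is_m6a <- rep(FALSE, n_sites)
    if (config$placement == "uniform") {
      drach_idx <- which(truth$motif_class == "DRACH")
      other_idx <- which(truth$motif_class != "DRACH")
      n_drach <- round(config$n_m6a_sites * config$drach_fraction)
      n_drach <- min(n_drach, length(drach_idx))
      n_other <- config$n_m6a_sites - n_drach
      if (n_other > length(other_idx)) {
        abort("not enough non-DRACH A sites for the requested placement")
      }
      chosen <- c(sample(drach_idx, n_drach),
                  if (n_other > 0) sample(other_idx, n_other))
      is_m6a[chosen] <- TRUE
    } else {
      n_clusters <- max(1L, round(config$n_m6a_sites / 5))
      anchors <- sample.int(n_sites, n_clusters)
      assignment <- sample.int(n_clusters, config$n_m6a_sites, replace = TRUE)
      chosen <- integer(0)
      for (k in seq_len(n_clusters)) {
        want <- sum(assignment == k)
        if (!want) next
        anc <- anchors[k]
        near <- which(truth$contig == truth$contig[anc] &
                        abs(truth$pos - truth$pos[anc]) <= config$cluster_width)
        near <- setdiff(near, chosen)
        chosen <- c(chosen, sample(near, min(want, length(near))))
      }
      # top up from the remaining pool if clusters were too small
      short <- config$n_m6a_sites - length(chosen)
      if (short > 0) chosen <- c(chosen, sample(setdiff(seq_len(n_sites), chosen), short))
      is_m6a[chosen] <- TRUE
    }
    truth$is_m6a <- is_m6a
    truth$m <- ifelse(is_m6a,
                      clip01(draw_dist(config$methylation_distribution, n_sites)), 0)
    truth$s <- clip01(draw_dist(config$accessibility_distribution, n_sites))
    editable <- which(!truth$is_m6a)
    n_edit <- round(config$editing_fraction * n_sites)
    edited <- if (n_edit > 0) sample(editable, min(n_edit, length(editable))) else integer(0)
    truth$is_edited <- seq_len(n_sites) %in% edited
    truth$editing_level <- ifelse(truth$is_edited, runif(n_sites, 0.2, 1), 0)
    list(reference = reference, truth = truth)
  })
}

role_params <- function(config, role) {
  role <- match.arg(role, c("treated", "ivt", "fto_minus", "fto_plus"))
  c_rate <- if (role %in% c("treated", "fto_minus")) {
    config$conversion_rate_treated
  } else config$conversion_rate_control
  list(role = role, c = c_rate,
       m_scale = switch(role, treated = 1, fto_minus = 1, ivt = 0,
                        fto_plus = 1 - config$fto_efficiency))
}

#' Simulate a per-site count table for one sample role
#'
#' Per site, coverage is drawn from the configured depth distribution and
#' the persistent-A count from `Binomial(n, P(A))` with
#' `P(A) = (1 - eta) * (1 - c * s * (1 - m_eff))`, where `eta` is the
#' site's editing level. `m_eff` is `m` for `treated`/`fto_minus`, 0 for
#' `ivt`, and `m * (1 - fto_efficiency)` for `fto_plus`. Each role uses an
#' independent, seed-derived random stream.
#'
#' @param truth Truth tibble from [simulate_transcriptome()].
#' @param config The same [sim_config()].
#' @param role One of `"treated"`, `"ivt"`, `"fto_minus"`, `"fto_plus"`.
#' @return An `etam_counts` tibble with the role's true conversion rate
#'   attached.
#' @export
simulate_counts <- function(truth, config, role = "treated") {
  pars <- role_params(config, role)
  offset <- match(pars$role, c("treated", "ivt", "fto_minus", "fto_plus"))
  with_seed(config$seed * 131L + offset, {
    n <- draw_dist(config$coverage_distribution, nrow(truth))
    keep <- n > 0
    tr <- truth[keep, , drop = FALSE]
    n <- as.integer(n[keep])
    p_a <- (1 - tr$editing_level) *
      (1 - pars$c * tr$s * (1 - pars$m_scale * tr$m))
    other <- rbinom(length(n), n, config$other_rate)
    a <- rbinom(length(n), n - other, p_a)
    site_counts(tibble(contig = tr$contig, pos = tr$pos, strand = tr$strand,
                       a_count = a, g_count = n - other - a, other_count = other),
                role = pars$role, label = paste0("sim_", pars$role),
                conversion_rate = NULL)
  })
}

#' Simulate read observations for the treated sample
#'
#' Reads of length `fragment_length` tile each transcript at a depth drawn
#' from the coverage distribution; each covered A site is converted
#' independently under the site model. A configurable fraction of reads
#' derives from poorly processed fragments whose effective conversion rate
#' is suppressed (`c * poorly_processed_conversion`); these are the reads
#' [filter_reads()] is designed to remove. Reads covering no tracked A
#' site are still emitted, with empty lists.
#'
#' @inheritParams simulate_counts
#' @param role Sample role for the read-level model (default `"treated"`).
#' @return An `etam_reads` tibble.
#' @export
simulate_reads <- function(truth, config, role = "treated") {
  pars <- role_params(config, role)
  with_seed(config$seed * 131L + 57L, {
    frag <- config$fragment_length
    by_tx <- split(truth, truth$contig)
    all_reads <- purrr::imap(by_tx, function(tr, id) {
      tx_len <- max(tr$pos) + 3L
      depth <- max(1, draw_dist(config$coverage_distribution, 1))
      n_reads <- max(1L, ceiling(depth * tx_len / frag))
      start <- sample.int(max(1L, tx_len - frag + 1L), n_reads, replace = TRUE) - 1L
      poor <- runif(n_reads) < config$poorly_processed_fraction
      c_eff <- ifelse(poor, pars$c * config$poorly_processed_conversion, pars$c)
      pos_list <- lapply(start, function(s0) tr$pos[tr$pos >= s0 & tr$pos < s0 + frag])
      obs_list <- lapply(seq_len(n_reads), function(i) {
        p <- pos_list[[i]]
        if (!length(p)) return(character(0))
        row <- match(p, tr$pos)
        p_a <- (1 - tr$editing_level[row]) *
          (1 - c_eff[i] * tr$s[row] * (1 - pars$m_scale * tr$m[row]))
        base <- ifelse(runif(length(p)) < p_a, "A", "G")
        err <- runif(length(p)) < config$other_rate
        base[err] <- sample(c("C", "U", "N"), sum(err), replace = TRUE)
        base
      })
      tibble(read_id = sprintf("%s_r%05d", id, seq_len(n_reads)),
             umi = vapply(seq_len(n_reads), function(i) {
               paste(sample(c("A", "C", "G", "U"), 6, replace = TRUE), collapse = "")
             }, ""),
             contig = id, strand = "+",
             ref_a_positions = pos_list, observed = obs_list)
    })
    read_observations(dplyr::bind_rows(all_reads))
  })
}

#' Simulate UMI-collapsed spike-in probe counts
#'
#' Each probe carries a designed m6A fraction `f` at its central position;
#' a read shows a persistent A with probability `f + (1 - f) * (1 - c)`
#' (the probe is fully accessible by design).
#'
#' @param designed_fractions Designed m6A fractions, e.g.
#'   `c(0, 0.25, 0.5, 0.75, 1)`.
#' @param reads_per_probe Reads simulated per probe.
#' @param conversion_rate Probe-assay conversion rate.
#' @param seed Integer seed.
#' @param replicates Probes simulated per designed fraction.
#' @return A tibble with columns `probe_id`, `designed_m6a_fraction`,
#'   `a_count`, `g_count`.
#' @export
simulate_probes <- function(designed_fractions = c(0, 0.25, 0.5, 0.75, 1),
                            reads_per_probe = 10000L, conversion_rate = 0.99,
                            seed = 1L, replicates = 1L) {
  if (any(designed_fractions < 0 | designed_fractions > 1)) {
    abort("designed fractions must lie in [0, 1]")
  }
  assert_scalar_prob(conversion_rate, "conversion_rate")
  with_seed(seed, {
    f <- rep(designed_fractions, each = replicates)
    p_a <- f + (1 - f) * (1 - conversion_rate)
    a <- rbinom(length(f), reads_per_probe, p_a)
    tibble(
      probe_id = sprintf("probe_f%03.0f_%d", 100 * f,
                         rep(seq_len(replicates), times = length(designed_fractions))),
      designed_m6a_fraction = f,
      a_count = a,
      g_count = reads_per_probe - a
    )
  })
}

#' Simulate a complete paired dataset
#'
#' Convenience wrapper producing the reference, truth and count tables for
#' a treated/control pair in one call.
#'
#' @param config A [sim_config()].
#' @param roles Character vector of roles to simulate counts for.
#' @return A list with `reference`, `truth` and one `etam_counts` per role.
#' @export
simulate_dataset <- function(config, roles = c("treated", "ivt")) {
  sim <- simulate_transcriptome(config)
  tables <- lapply(roles, function(r) simulate_counts(sim$truth, config, role = r))
  names(tables) <- roles
  c(sim, tables)
}
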