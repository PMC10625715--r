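#' Run the simulate -> rate -> call -> annotate pipeline
#'
#' Orchestrates the full workflow from a single configuration list and
#' writes all artifacts plus a machine-readable run manifest (inputs,
#' parameters, seed, stage-wise site counts) to `outdir`. Stages:
#'
#' 1. *simulate* (optional): if `config$simulate` is a [sim_config()] (or a
#'    list of its arguments), generates reference, truth and count tables
#'    and writes them to `outdir`.
#' 2. *rate*: estimates conversion rates for both count tables.
#' 3. *call*: [call_sites()] in `"ivt"` or `"fto"` mode; writes
#'    `calls.tsv` and `calls.bed`.
#' 4. *annotate* (optional): per-transcript loads, load bins, neighbour
#'    gaps, and half-life comparison when `config$half_lives` is given;
#'    writes `report.tsv`.
#'
#' Every stochastic step derives its stream from `config$seed`, so a fixed
#' config yields byte-identical outputs.
#'
#' @param config A named list: `outdir` (required), `seed` (default 1),
#'   and either `simulate` (simulation arguments) or `treated` / `control`
#'   (paths to count TSVs); optional `mode` (`"ivt"`/`"fto"`), `e`,
#'   `min_coverage`, `fdr_threshold`, `exposed_threshold`, `exclude`
#'   (path to a site TSV), `reference` (FASTA path; filled automatically
#'   when simulating), `half_lives` (TSV path), `rate_min_coverage`,
#'   `rate_trim`.
#' @return Invisibly, a list with `calls`, `manifest` and the manifest
#'   path.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$outdir)) abort("config$outdir is required")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  mode <- config$mode %||% "ivt"
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  manifest <- list(seed = seed, mode = mode, stages = list())

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (isTRUE(sim_args)) sim_args <- list()
    if (!inherits(sim_args, "sim_config")) {
      sim_args$seed <- sim_args$seed %||% seed
      sim_args <- do.call(sim_config, sim_args)
    }
    roles <- if (mode == "ivt") c("treated", "ivt") else c("fto_minus", "fto_plus")
    ds <- stage("simulate", simulate_dataset(sim_args, roles = roles))
    write_reference(ds$reference, file.path(outdir, "reference.fa"))
    readr::write_tsv(ds$truth[, c("contig", "pos", "strand", "motif5", "is_m6a",
                                  "m", "s", "is_edited", "editing_level")],
                     file.path(outdir, "truth.tsv"), progress = FALSE)
    treated <- ds[[roles[1]]]
    control <- ds[[roles[2]]]
    # simulated FTO runs default to the efficiency the truth was built with
    if (mode == "fto" && is.null(config$e)) config$e <- sim_args$fto_efficiency
    write_site_counts(treated, file.path(outdir, "treated.tsv"))
    write_site_counts(control, file.path(outdir, "control.tsv"))
    config$reference <- file.path(outdir, "reference.fa")
    manifest$inputs <- list(simulated = TRUE,
                            sim_config = lapply(unclass(sim_args), function(x) {
                              if (inherits(x, "sim_dist")) unclass(x) else x
                            }))
  } else {
    if (is.null(config$treated) || is.null(config$control)) {
      abort("config needs either `simulate` or both `treated` and `control` paths")
    }
    for (p in c(config$treated, config$control)) {
      if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
    }
    treated_role <- if (mode == "ivt") "treated" else "fto_minus"
    control_role <- if (mode == "ivt") "ivt" else "fto_plus"
    treated <- stage("read", read_site_counts(config$treated, role = treated_role))
    control <- stage("read", read_site_counts(config$control, role = control_role))
    manifest$inputs <- list(simulated = FALSE, treated = config$treated,
                            control = config$control)
  }

  rate_cov <- config$rate_min_coverage %||% 20L
  rate_trim <- config$rate_trim %||% 0
  treated <- stage("rate", set_conversion_rate(
    treated, estimate_conversion_rate(treated, rate_cov, rate_trim)))
  control <- stage("rate", set_conversion_rate(
    control, estimate_conversion_rate(control, rate_cov, rate_trim)))
  manifest$conversion_rates <- list(treated = conversion_rate(treated),
                                    control = conversion_rate(control))

  exclusion <- NULL
  if (!is.null(config$exclude)) {
    exclusion <- stage("read", readr::read_tsv(
      config$exclude, col_types = readr::cols(
        contig = readr::col_character(), pos = readr::col_integer(),
        strand = readr::col_character()), progress = FALSE))
  }
  params <- call_params(
    min_coverage = config$min_coverage %||% 10L,
    fdr_threshold = config$fdr_threshold %||% 0.05,
    exposed_threshold = config$exposed_threshold %||% 0.10,
    mode = mode, exclusion_sites = exclusion, e = config$e
  )
  calls <- stage("call", call_sites(treated, control, params = params,
                                    reference = config$reference, seed = seed))
  write_calls(calls, file.path(outdir, "calls.tsv"), format = "tsv")
  write_calls(calls, file.path(outdir, "calls.bed"), format = "bed")
  manifest$stages$call <- as.list(call_funnel(calls))
  manifest$parameters <- params[c("min_coverage", "fdr_threshold",
                                  "exposed_threshold", "mode")]

  loads <- stage("annotate", transcript_loads(calls))
  bins <- stage("annotate", bin_by_load(loads))
  report <- bins
  if (!is.null(config$half_lives)) {
    hl <- stage("annotate", read_half_lives(config$half_lives))
    hl_cmp <- stage("annotate", compare_half_lives(bins, hl))
    readr::write_tsv(hl_cmp, file.path(outdir, "half_life_comparison.tsv"),
                     progress = FALSE)
    manifest$stages$half_life <- list(bins = nrow(hl_cmp))
  }
  readr::write_tsv(report, file.path(outdir, "report.tsv"), progress = FALSE)
  gaps <- neighbor_gaps(calls[calls$passed, , drop = FALSE])
  manifest$stages$annotate <- list(transcripts = nrow(bins),
                                   median_gap = gaps$median_gap)

  manifest$outputs <- list(calls_tsv = file.path(outdir, "calls.tsv"),
                           calls_bed = file.path(outdir, "calls.bed"),
                           report_tsv = file.path(outdir, "report.tsv"))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(list(calls = calls, manifest = manifest, manifest_path = manifest_path))
}
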