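small_cfg <- function(...) {
  sim_config(n_transcripts = 4L, transcript_length = 600L, n_m6a_sites = 25L,
             seed = 101L, ...)
}

test_that("the simulator is deterministic under its seed", {
  cfg <- small_cfg()
  a <- simulate_transcriptome(cfg)
  b <- simulate_transcriptome(cfg)
  expect_identical(a$reference, b$reference)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_counts(a$truth, cfg, "treated"),
                   simulate_counts(b$truth, cfg, "treated"))
  expect_identical(simulate_probes(seed = 5), simulate_probes(seed = 5))
})

test_that("m6A placement respects motif preference and editing config", {
  all_drach <- simulate_transcriptome(small_cfg(drach_fraction = 1))
  m6a <- all_drach$truth[all_drach$truth$is_m6a, ]
  expect_true(all(m6a$motif_class == "DRACH"))

  none_edited <- simulate_transcriptome(small_cfg(editing_fraction = 0))
  expect_false(any(none_edited$truth$is_edited))

  expect_error(simulate_transcriptome(
    sim_config(n_transcripts = 1, transcript_length = 60, n_m6a_sites = 500)),
    "exceeds")
})

test_that("simulated counts follow the site model in its corners", {
  cfg <- small_cfg(coverage_distribution = sim_dist("fixed", value = 200),
                   other_rate = 0)
  full <- make_truth(m = rep(1, 30), s = 0.7)
  tab <- simulate_counts(full, cfg, "treated")
  expect_true(all(tab$g_count == 0))  # m = 1: every read keeps its A

  cfg1 <- small_cfg(coverage_distribution = sim_dist("fixed", value = 200),
                    conversion_rate_treated = 1, other_rate = 0)
  none <- make_truth(m = rep(0, 30), s = 1)
  tab <- simulate_counts(none, cfg1, "treated")
  expect_true(all(tab$a_count == 0))  # m = 0, c = s = 1: full conversion
})

test_that("the persistent-A fraction converges to 1 - c s (1 - m_eff) for every role", {
  cfg <- small_cfg(coverage_distribution = sim_dist("fixed", value = 1e6),
                   conversion_rate_treated = 0.987,
                   conversion_rate_control = 0.99,
                   fto_efficiency = 0.9, other_rate = 0)
  truth <- make_truth(m = rep(0.5, 1), s = 1)
  for (role in c("treated", "ivt", "fto_minus", "fto_plus")) {
    m_eff <- switch(role, treated = 0.5, fto_minus = 0.5, ivt = 0,
                    fto_plus = 0.5 * (1 - cfg$fto_efficiency))
    c_role <- if (role %in% c("treated", "fto_minus")) 0.987 else 0.99
    pi_a <- 1 - c_role * 1 * (1 - m_eff)
    tab <- simulate_counts(truth, cfg, role)
    frac <- tab$a_count / (tab$a_count + tab$g_count)
    tol <- 3 * sqrt(pi_a * (1 - pi_a) / 1e6)
    expect_lt(abs(frac - pi_a), max(tol, 2e-3))
  }
})

test_that("IVT counts are independent of the methylation truth", {
  cfg <- small_cfg()
  truth <- make_truth(m = runif(50), s = runif(50, 0.5, 1))
  permuted <- truth
  permuted$m <- rev(truth$m)
  expect_identical(simulate_counts(truth, cfg, "ivt"),
                   simulate_counts(permuted, cfg, "ivt"))
})

test_that("probe counts follow f + (1 - f)(1 - c)", {
  all_m <- simulate_probes(1, reads_per_probe = 5000, conversion_rate = 0.99, seed = 2)
  expect_equal(all_m$g_count, 0L)

  bg <- simulate_probes(0, reads_per_probe = 1e5, conversion_rate = 0.9831, seed = 3)
  expect_lt(abs(bg$a_count / 1e5 - 0.0169), 0.001)

  half <- simulate_probes(0.5, reads_per_probe = 1e4, conversion_rate = 1, seed = 4)
  expect_lt(abs(half$a_count / 1e4 - 0.5), 0.015)
})

test_that("simulated reads behave at the edges and reproduce the count model", {
  cfg <- small_cfg(poorly_processed_fraction = 0)
  truth <- make_truth(m = rep(0, 40))
  reads <- simulate_reads(truth, cfg)
  expect_identical(nrow(filter_reads(reads)), nrow(reads))  # nothing to remove

  # fragments upstream of the only A sites are still emitted, with empty lists
  far <- make_truth(m = 0)
  far$pos <- 300L
  cfg_far <- small_cfg(fragment_length = 50L,
                       coverage_distribution = sim_dist("fixed", value = 30))
  reads_far <- simulate_reads(far, cfg_far)
  expect_true(any(lengths(reads_far$ref_a_positions) == 0L))

  # filtered-read tallies and direct count simulation agree in distribution:
  # sparse methylation interleaved with unmethylated sites, as in real
  # transcripts, so the read filter touches poorly processed reads only
  set.seed(55)
  truth_ks <- make_truth(m = sample(c(rep(0, 250), runif(50))), s = 1)
  cfg_ks <- sim_config(seed = 77L,
                       coverage_distribution = sim_dist("fixed", value = 60),
                       poorly_processed_fraction = 0.05, other_rate = 0)
  from_reads <- count_sites(filter_reads(simulate_reads(truth_ks, cfg_ks)))
  # oracle: at each tallied site, an independent binomial draw at the same
  # coverage under the closed-form law pi = 1 - c s (1 - m)
  pi_a <- local({
    row <- match(from_reads$pos, truth_ks$pos)
    1 - cfg_ks$conversion_rate_treated * truth_ks$s[row] * (1 - truth_ks$m[row])
  })
  cov <- from_reads$a_count + from_reads$g_count
  oracle_a <- rbinom(length(cov), cov, pi_a)
  keep <- cov >= 20
  ks <- suppressWarnings(stats::ks.test(
    (from_reads$a_count / cov)[keep], (oracle_a / cov)[keep]))
  expect_gt(ks$p.value, 0.01)
  # and the site means agree with the closed form overall
  expect_lt(abs(mean(from_reads$a_count / cov) - mean(pi_a)), 0.01)
})

test_that("simulator configs round-trip through JSON", {
  cfg <- small_cfg(coverage_distribution = sim_dist("poisson", lambda = 30))
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_identical(simulate_transcriptome(back)$truth,
                   simulate_transcriptome(cfg)$truth)
})
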