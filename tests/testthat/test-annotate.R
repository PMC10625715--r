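test_that("probe calibration reproduces the published linear fit", {
  pts <- data.frame(designed_pct = c(0, 25, 50, 75, 100),
                    persistent_a_pct = c(1.69, 26.1, 46.5, 73.9, 98.7))
  fit <- fit_calibration(pts)
  expect_equal(round(fit$r_squared, 2), 1.00)
  # slope from the normal equations, Sxy / Sxx
  x <- pts$designed_pct; y <- pts$persistent_a_pct
  expect_equal(fit$slope, sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
  expect_equal(fit$slope, 0.967, tolerance = 1e-3)

  collinear <- data.frame(designed_pct = c(0, 50, 100),
                          persistent_a_pct = c(2, 52, 102))
  expect_equal(fit_calibration(collinear)$r_squared, 1, tolerance = 1e-12)

  expect_error(fit_calibration(data.frame(designed_pct = c(10, 10),
                                          persistent_a_pct = c(1, 2))), "all equal")
  expect_error(fit_calibration(pts[1, ]), "at least 2")

  # r^2 invariant under affine rescaling of x
  rescaled <- transform(pts, designed_pct = 3 * designed_pct + 7)
  expect_equal(fit_calibration(rescaled)$r_squared, fit$r_squared)

  # end-to-end: simulated probes at high depth give a near-perfect line
  probes <- simulate_probes(c(0, 0.25, 0.5, 0.75, 1), reads_per_probe = 5e4,
                            conversion_rate = 0.9831, seed = 12)
  sim_fit <- fit_calibration(calibration_points(probes))
  expect_gt(sim_fit$r_squared, 0.999)
  expect_equal(glance(sim_fit)$slope, sim_fit$slope)
})

test_that("neighbour gaps pool within-transcript differences", {
  one <- neighbor_gaps(data.frame(contig = "T1", pos = c(10, 72)))
  expect_equal(one$gaps$gap, 62)
  expect_equal(one$median_gap, 62)

  multi <- neighbor_gaps(data.frame(contig = "T1", pos = c(0, 10, 30)))
  expect_equal(sort(multi$gaps$gap), c(10, 20))
  expect_equal(multi$median_gap, 15)

  singles <- neighbor_gaps(data.frame(contig = c("T1", "T2"), pos = c(5, 9)))
  expect_equal(nrow(singles$gaps), 0L)
  expect_true(is.na(singles$median_gap))
})

test_that("the permutation null is deterministic and motif-exact", {
  set.seed(3)
  cand <- tibble::tibble(
    contig = rep(c("T1", "T2"), each = 200),
    pos = c(sort(sample.int(4000, 200)), sort(sample.int(4000, 200))),
    motif5 = sample(c("GGACU", "AAACA", "UGACU"), 400, replace = TRUE)
  )
  a <- permutation_gap_null(cand, n_sites = 60, reps = 10, seed = 42)
  b <- permutation_gap_null(cand, n_sites = 60, reps = 10, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a), 10L)

  obs_motifs <- rep(c("GGACU", "AAACA"), c(20, 10))
  drawn <- permutation_gap_null(cand, n_sites = 30, mode = "motif_matched",
                                observed_motifs = obs_motifs, reps = 5, seed = 9,
                                return_draws = TRUE)
  for (d in drawn$draw) {
    expect_identical(as.vector(table(d$motif5)[c("GGACU", "AAACA")]),
                     as.vector(table(obs_motifs)[c("GGACU", "AAACA")]))
  }
  # quota exceeding a stratum names the motif
  expect_error(permutation_gap_null(cand, n_sites = 400, mode = "motif_matched",
                                    observed_motifs = rep("GGACU", 400), seed = 1),
               "GGACU")
  expect_error(permutation_gap_null(cand, n_sites = 1000), "exceeds")
})

test_that("clustered sites fall below the permutation null; uniform sites do not", {
  set.seed(19)
  cand <- tibble::tibble(contig = rep(sprintf("T%02d", 1:10), each = 300),
                         pos = rep(seq(0, by = 7, length.out = 300), 10))
  # clustered observed set: runs of adjacent candidate sites
  clustered <- cand[unlist(lapply(seq(0, 2700, by = 300),
                                  function(o) o + sample.int(280, 1) + 0:19)), ]
  obs <- neighbor_gaps(clustered)$median_gap
  null <- permutation_gap_null(cand, n_sites = nrow(clustered), reps = 10, seed = 7)
  expect_true(all(obs < null$median_gap))

  uniform <- cand[sort(sample.int(nrow(cand), 200)), ]
  obs_u <- neighbor_gaps(uniform)$median_gap
  null_u <- permutation_gap_null(cand, n_sites = 200, reps = 10, seed = 8)
  expect_gte(sum(obs_u >= min(null_u$median_gap) & obs_u <= max(null_u$median_gap)), 0)
  # bracketed: not strictly outside the null range
  expect_true(obs_u >= min(null_u$median_gap) && obs_u <= max(null_u$median_gap))
})

test_that("methylation load sums signals and is additive", {
  expect_equal(methylation_load(c(0.3, 0.7, 1.0)), 2.0)
  expect_equal(methylation_load(numeric(0)), 0)
  expect_equal(methylation_load(0.5), 0.5)
  expect_error(methylation_load(1.2), "0, 1")
  set.seed(2)
  x <- runif(10); y <- runif(5)
  expect_equal(methylation_load(c(x, y)),
               methylation_load(x) + methylation_load(y))
})

test_that("load binning partitions transcripts with the stated tie and remainder rules", {
  nine <- tibble::tibble(transcript_id = sprintf("t%02d", 1:9),
                         load = seq(0.9, 0.1, by = -0.1))
  b9 <- bin_by_load(nine)
  expect_equal(as.vector(table(b9$bin)), c(3, 3, 3, 0))

  zero <- tibble::tibble(transcript_id = c("a", "b"), load = c(0, 0))
  expect_true(all(bin_by_load(zero)$bin == "none"))

  four <- tibble::tibble(transcript_id = c("a", "b", "c", "d"),
                         load = c(4, 3, 2, 1))
  b4 <- bin_by_load(four)
  expect_equal(as.vector(table(b4$bin)), c(2, 1, 1, 0))
  expect_setequal(b4$transcript_id[b4$bin == "high"], c("a", "b"))

  # ties broken lexicographically; every transcript in exactly one bin
  tied <- tibble::tibble(transcript_id = c("z", "a", "m", "q", "b"),
                         load = c(1, 1, 1, 0, 1))
  bt <- bin_by_load(tied)
  expect_equal(sum(as.vector(table(bt$bin))), 5L)
  expect_setequal(bt$transcript_id, tied$transcript_id)
  expect_equal(bt$transcript_id[bt$bin == "high"], c("a", "b"))
})

test_that("half-life comparison reports summaries and one-tailed rank-sum tests", {
  toy_bins <- tibble::tibble(transcript_id = c("a", "b", "c", "d"),
                             load = c(2, 1, 0, 0),
                             bin = factor(c("high", "high", "none", "none"),
                                          levels = c("high", "medium", "low", "none")))
  toy_hl <- tibble::tibble(transcript_id = c("a", "b", "c", "d"),
                           half_life_hours = c(2, 4, 6, 8))
  cmp <- compare_half_lives(toy_bins, toy_hl)
  expect_equal(cmp$mean_half_life[cmp$bin == "high"], 3)
  expect_equal(cmp$mean_half_life[cmp$bin == "none"], 7)
  expect_true(is.na(cmp$p_value[cmp$bin == "none"]))

  set.seed(33)
  n <- 500
  big <- tibble::tibble(
    transcript_id = sprintf("t%04d", 1:(2 * n)),
    load = rep(c(3, 0), each = n),
    bin = factor(rep(c("high", "none"), each = n),
                 levels = c("high", "medium", "low", "none")))
  hl <- tibble::tibble(
    transcript_id = big$transcript_id,
    half_life_hours = c(rnorm(n, 4.8, 2), rnorm(n, 6.8, 2)))
  cmp_big <- compare_half_lives(big, hl)
  expect_lt(cmp_big$p_value[cmp_big$bin == "high"], 1e-6)

  same <- hl
  same$half_life_hours <- rep(rnorm(n, 6, 1), 2)
  cmp_same <- compare_half_lives(big, same)
  expect_gte(cmp_same$p_value[cmp_same$bin == "high"], 0.4)

  no_ref <- big[big$bin == "high", ]
  expect_error(compare_half_lives(no_ref, hl), "reference")
})

test_that("spike-in amounts follow y = d v c / t", {
  expect_equal(spike_in_amount(1, 1, 1, 1), 1)
  expect_equal(spike_in_amount(0.01, 2, 50, 1), 1)
  expect_error(spike_in_amount(1, 1, 1, 0), "positive")
})

test_that("genomic sites project onto spliced transcript coordinates", {
  ann <- tibble::tibble(
    transcript_id = c("txA", "txB"), contig = "chr1", strand = c("+", "-"),
    exon_starts = list(c(100L, 300L), c(100L, 300L)),
    exon_ends = list(c(200L, 350L), c(200L, 350L)))
  sites <- data.frame(contig = "chr1", pos = c(150L, 310L, 250L),
                      strand = c("+", "+", "+"))
  mapped <- map_to_transcript(sites, ann[1, ])
  expect_equal(mapped$tx_pos, c(50L, 110L))     # intronic site dropped
  minus_sites <- data.frame(contig = "chr1", pos = c(150L, 310L), strand = "-")
  mapped_m <- map_to_transcript(minus_sites, ann[2, ])
  # spliced length 150; 5' end of a minus transcript is the highest coordinate
  expect_equal(mapped_m$tx_pos, c(150L - 1L - 50L, 150L - 1L - 110L))
})
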