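test_that("the read filter removes exactly the >50%-unconverted fragments", {
  reads <- read_observations(tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    contig = "tx1", strand = "+",
    ref_a_positions = list(seq(0, 90, by = 10), seq(0, 90, by = 10), integer(0)),
    observed = list(c(rep("A", 6), rep("G", 4)),   # 6/10 unconverted
                    c(rep("A", 5), rep("G", 5)),   # exactly 1/2: kept
                    character(0))                  # no evidence: kept
  ))
  kept <- filter_reads(reads)
  expect_setequal(kept$read_id, c("r2", "r3"))
  expect_error(filter_reads(reads, max_unconverted_fraction = 1.5), "0, 1")
})

test_that("count_sites tallies match a brute-force oracle", {
  reads <- read_observations(tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    contig = "tx1", strand = "+",
    ref_a_positions = list(5L, 5L, 5L),
    observed = list("G", "G", "G")
  ))
  tab <- count_sites(reads)
  expect_equal(tab$a_count, 0L)
  expect_equal(tab$g_count, 3L)

  set.seed(99)
  pos_list <- lapply(1:100, function(i) sort(sample.int(50, sample(0:6, 1))))
  rnd <- read_observations(tibble::tibble(
    read_id = sprintf("r%03d", 1:100),
    contig = sample(c("tx1", "tx2"), 100, replace = TRUE),
    strand = sample(c("+", "-"), 100, replace = TRUE),
    ref_a_positions = pos_list,
    observed = lapply(pos_list, function(p) {
      sample(c("A", "G", "C", "N"), length(p), replace = TRUE,
             prob = c(.3, .6, .05, .05))
    })
  ))
  got <- as.data.frame(count_sites(rnd))
  oracle <- tally_reads_oracle(rnd)
  rownames(got) <- rownames(oracle) <- NULL
  expect_equal(got[, c("contig", "pos", "strand")], oracle[, c("contig", "pos", "strand")])
  expect_equal(got$a_count, oracle$a_count)
  expect_equal(got$g_count, oracle$g_count)
  expect_equal(got$other_count, oracle$other_count)
})

test_that("conversion-rate estimation pools qualifying sites", {
  two <- site_counts(tibble::tibble(contig = "t", pos = 1:2, strand = "+",
                                    a_count = c(1L, 3L), g_count = c(99L, 97L)),
                     role = "ivt")
  expect_equal(estimate_conversion_rate(two), 196 / 200)

  all_g <- site_counts(tibble::tibble(contig = "t", pos = 1:5, strand = "+",
                                      a_count = 0L, g_count = 50L), role = "ivt")
  expect_equal(estimate_conversion_rate(all_g), 1)

  all_a <- site_counts(tibble::tibble(contig = "t", pos = 1:5, strand = "+",
                                      a_count = 50L, g_count = 0L), role = "ivt")
  expect_equal(estimate_conversion_rate(all_a), 0)

  thin <- site_counts(tibble::tibble(contig = "t", pos = 1L, strand = "+",
                                     a_count = 2L, g_count = 3L), role = "ivt")
  expect_error(estimate_conversion_rate(thin), "coverage")

  # trimming discards outlier (methylated-looking) sites before pooling
  mixed <- site_counts(tibble::tibble(
    contig = "t", pos = 1:20, strand = "+",
    a_count = c(rep(1L, 18), 80L, 90L), g_count = c(rep(99L, 18), 20L, 10L)),
    role = "treated")
  expect_equal(estimate_conversion_rate(mixed, trim = 0.1), 0.99)
})

test_that("apparent methylation is the clipped binomial MLE", {
  expect_equal(apparent_methylation(0, 100, 0.99), 0)     # unclipped negative
  expect_equal(apparent_methylation(100, 0, 1), 1)
  expect_equal(apparent_methylation(261, 739, 0.9831),
               (261 / 1000 - (1 - 0.9831)) / 0.9831)
  expect_error(apparent_methylation(1, 1, 0), "c")
  expect_error(apparent_methylation(0, 0, 0.99), ">= 1")

  # closed form equals the grid-search likelihood maximiser
  set.seed(31)
  for (i in 1:25) {
    n <- sample(20:400, 1)
    a <- rbinom(1, n, runif(1))
    c <- runif(1, 0.9, 1)
    expect_lt(abs(apparent_methylation(a, n - a, c) -
                    grid_mle_oracle(a, n - a, c, step = 1e-4)), 1e-3)
  }
})

test_that("apparent methylation is monotone in a at fixed coverage", {
  for (c in c(0.9, 0.99, 1)) {
    m_hat <- apparent_methylation(0:50, 50:0, c)
    expect_true(all(diff(m_hat) >= 0))
  }
})

test_that("accessibility estimation and adjustment invert the site model", {
  expect_equal(raw_accessibility(0, 100, 0.99), 1)   # unclipped 1.0101
  expect_equal(raw_accessibility(15, 85, 0.9), 0.85 / 0.9)
  expect_equal(raw_accessibility(10, 0, 0.99), 0)

  adj <- adjust_methylation(0.45, 0.9)
  expect_equal(adj$true_m, 0.5)
  expect_equal(adj$exposed_m, 0.45)

  clipped <- adjust_methylation(0.8, 0.5)
  expect_equal(clipped$true_m, 1)
  expect_equal(clipped$exposed_m, 0.5)

  blocked <- adjust_methylation(0.3, 0)
  expect_true(is.na(blocked$true_m))
  expect_equal(blocked$exposed_m, 0)

  # exposed_m = min(apparent, s) wherever s > 0
  set.seed(8)
  ap <- runif(200); s <- runif(200, 0.01, 1)
  adj <- adjust_methylation(ap, s)
  expect_equal(adj$exposed_m, pmin(ap, s))
})

test_that("mean apparent methylation recovers the truth across levels", {
  set.seed(12)
  c <- 0.99
  for (m in c(0, 0.25, 0.5, 0.75, 1)) {
    a <- rbinom(400, 100, m + (1 - m) * (1 - c))
    m_hat <- apparent_methylation(a, 100 - a, c)
    expect_lt(abs(mean(m_hat) - m), 0.02)
  }
})

test_that("accessibility shrinkage leaves constant estimates untouched", {
  set.seed(4)
  n <- 300
  cov <- sample(20:200, n, replace = TRUE)
  g <- round(cov * 0.95 * 0.9)
  est <- tibble::tibble(contig = "t", pos = seq_len(n), strand = "+",
                        a_count = cov - g, g_count = g,
                        raw_s = 0.95)
  expect_warning(shrink_accessibility(est, c_control = 0.9, n_train = 2000, seed = 1),
                 "training on all")
  out <- suppressWarnings(
    shrink_accessibility(est, c_control = 0.9, n_train = 2000, seed = 1))
  expect_equal(out$shrunken_s, rep(0.95, n), tolerance = 1e-8)
  expect_s3_class(shrinkage_fit(out), "etam_shrinkage")
  expect_equal(nrow(tidy(shrinkage_fit(out))), 3L)
})

test_that("shrinkage reduces error for noisy low-coverage accessibility", {
  set.seed(21)
  c_ctrl <- 0.99
  n <- 3000
  cov <- rpois(n, 15) + 1L
  g <- rbinom(n, cov, c_ctrl)           # true s = 1 everywhere
  est <- tibble::tibble(contig = "t", pos = seq_len(n), strand = "+",
                        a_count = cov - g, g_count = g,
                        raw_s = raw_accessibility(cov - g, g, c_ctrl))
  out <- shrink_accessibility(est, c_control = c_ctrl, n_train = 2000, seed = 2)
  expect_lt(mean(abs(out$shrunken_s - 1)), mean(abs(out$raw_s - 1)))
})
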