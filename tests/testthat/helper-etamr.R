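# fixture builders shared across test files

make_count_table <- function(n = 10, seed = 1, role = "treated") {
  set.seed(seed)
  site_counts(tibble::tibble(
    contig = sample(c("tx1", "tx2"), n, replace = TRUE),
    pos = sample.int(10000, n),
    strand = sample(c("+", "-"), n, replace = TRUE),
    a_count = rbinom(n, 100, 0.1),
    g_count = rbinom(n, 100, 0.9),
    other_count = rbinom(n, 5, 0.1)
  ), role = role)
}

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# truth table with hand-set parameters, one transcript
make_truth <- function(m, s = 1, editing_level = 0, contig = "tx1") {
  n <- max(length(m), length(s), length(editing_level))
  m <- rep_len(m, n); s <- rep_len(s, n); editing_level <- rep_len(editing_level, n)
  tibble::tibble(
    contig = contig, pos = seq(2L, by = 10L, length.out = n), strand = "+",
    motif5 = "GGACU", motif_class = "DRACH",
    is_m6a = m > 0, m = m, s = s,
    is_edited = editing_level > 0, editing_level = editing_level
  )
}

# independent tally oracle for count_sites: plain loops and environments
tally_reads_oracle <- function(reads) {
  env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(reads))) {
    ps <- reads$ref_a_positions[[i]]
    bs <- reads$observed[[i]]
    for (j in seq_along(ps)) {
      key <- paste(reads$contig[i], ps[j], reads$strand[i], sep = ":")
      cur <- if (exists(key, envir = env)) get(key, envir = env) else c(a = 0, g = 0, o = 0)
      slot <- if (bs[j] == "A") "a" else if (bs[j] == "G") "g" else "o"
      cur[slot] <- cur[slot] + 1
      assign(key, cur, envir = env)
    }
  }
  keys <- ls(env)
  out <- do.call(rbind, lapply(keys, function(k) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    v <- get(k, envir = env)
    data.frame(contig = parts[1], pos = as.integer(parts[2]), strand = parts[3],
               a_count = v[["a"]], g_count = v[["g"]], other_count = v[["o"]])
  }))
  out[order(out$contig, out$pos, out$strand), ]
}

# grid-search oracle for the one-parameter binomial MLE
grid_mle_oracle <- function(a, g, c, step = 1e-5) {
  m <- seq(0, 1, by = step)
  p_a <- m + (1 - m) * (1 - c)
  ll <- ifelse(rep(a, length(m)) == 0, 0, a * log(p_a)) +
    ifelse(rep(g, length(m)) == 0, 0, g * log(1 - p_a))
  m[which.max(ll)]
}

# exhaustive hypergeometric tail enumeration for the one-sided Fisher test
fisher_enum_oracle <- function(a_t, g_t, a_c, g_c) {
  n_treat <- a_t + g_t
  k_a <- a_t + a_c
  n_tot <- a_t + g_t + a_c + g_c
  xs <- max(0, k_a - (n_tot - n_treat)):min(n_treat, k_a)
  probs <- choose(k_a, xs) * choose(n_tot - k_a, n_treat - xs) / choose(n_tot, n_treat)
  sum(probs[xs >= a_t])
}
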