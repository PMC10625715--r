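# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build per-site accessibility estimates from a control count table
#'
#' @param control An `etam_counts` tibble for the modification-free (IVT)
#'   control, with its conversion rate set.
#' @param c_control Control conversion rate; defaults to the one stored on
#'   `control`.
#' @return A tibble with columns `contig`, `pos`, `strand`, `a_count`,
#'   `g_count`, `raw_s`, suitable for [shrink_accessibility()].
#' @export
accessibility_estimates <- function(control, c_control = conversion_rate(control)) {
  if (is.null(c_control)) {
    abort("control table has no conversion rate; run estimate_conversion_rate() first")
  }
  out <- tibble(
    contig = control$contig, pos = control$pos, strand = control$strand,
    a_count = control$a_count, g_count = control$g_count,
    raw_s = raw_accessibility(control$a_count, control$g_count, c_control)
  )
  attr(out, "c_control") <- c_control
  out
}

#' Coverage-bias correction ("shrinkage") of raw accessibility estimates
#'
#' Raw accessibility at low coverage is not just noisy: because the
#' estimate is a clipped ratio, its errors at nearly fully accessible
#' sites are one-sided and it is systematically biased low wherever a
#' single persistent-A read can swing the ratio. The count-driven part of
#' that trend is estimable: an ordinary least-squares model of the raw
#' estimate on the control A and G counts (the A+G total is collinear
#' with these and dropped) is trained on a random sample of `n_train`
#' sites with `folds`-fold cross-validation reporting its out-of-fold
#' error. Each site is then corrected upward by its estimated shortfall
#' against the high-coverage anchor (the mean raw estimate over training
#' sites of above-median coverage, where ratio bias is negligible):
#' \deqn{shrunken = clip(raw + \min(\max(0, anchor - pred),\;
#'   1/(c (n + 1))), 0, 1)}
#' The correction is one-sided — estimates are never pulled down, so
#' exact high-coverage estimates are untouched — and capped at the
#' `1/(c (n+1))` scale of ratio-estimator bias at coverage `n`, which
#' protects genuinely low-accessibility sites from being inflated by more
#' than their sampling bias could explain.
#'
#' @param estimates A tibble from [accessibility_estimates()] (columns
#'   `a_count`, `g_count`, `raw_s`; id columns are passed through).
#' @param c_control Control conversion rate (stored by
#'   [accessibility_estimates()]), used in the bias cap.
#' @param n_train Number of sites sampled for training (all sites, with a
#'   warning, when fewer are available).
#' @param folds Number of cross-validation folds.
#' @param seed Seed for the training sample and fold assignment.
#' @return The input tibble with a `shrunken_s` column added; the fitted
#'   model and CV summary are available via [shrinkage_fit()].
#' @export
shrink_accessibility <- function(estimates, c_control = attr(estimates, "c_control"),
                                 n_train = 2000L, folds = 10L, seed = 1L) {
  estimates <- as_tibble(estimates)
  n <- nrow(estimates)
  if (n < 2L) abort("shrink_accessibility needs at least 2 sites")

  if (n < n_train) {
    warn(sprintf("only %d sites available (< n_train = %d); training on all",
                 n, n_train))
    n_train <- n
  }
  folds <- min(folds, n_train)

  fit <- with_seed(seed, {
    train_idx <- sample.int(n, n_train)
    train <- estimates[train_idx, , drop = FALSE]
    fold_id <- sample(rep_len(seq_len(folds), n_train))

    pred_oof <- rep(NA_real_, n_train)
    for (k in seq_len(folds)) {
      hold <- fold_id == k
      m_k <- lm(raw_s ~ a_count + g_count, data = train[!hold, , drop = FALSE])
      pred_oof[hold] <- predict(m_k, newdata = train[hold, , drop = FALSE])
    }
    oof_mse <- mean((pred_oof - train$raw_s)^2)

    model <- lm(raw_s ~ a_count + g_count, data = train)
    train_cov <- train$a_count + train$g_count
    high <- train_cov >= median(train_cov)
    list(model = model, mean_raw = mean(train$raw_s),
         anchor = mean(train$raw_s[high]),
         oof_mse = oof_mse, n_train = n_train, folds = folds)
  })

  pred <- as.numeric(predict(fit$model, newdata = estimates))
  cov <- estimates$a_count + estimates$g_count
  c_cap <- if (is.null(c_control)) 1 else c_control
  correction <- pmin(pmax(fit$anchor - pred, 0), 1 / (c_cap * (cov + 1)))
  estimates$shrunken_s <- clip01(estimates$raw_s + correction)
  attr(estimates, "c_control") <- c_control
  attr(estimates, "shrinkage_fit") <- structure(fit, class = "etam_shrinkage")
  estimates
}

#' @rdname shrink_accessibility
#' @param x A tibble returned by [shrink_accessibility()].
#' @export
shrinkage_fit <- function(x) {
  fit <- attr(x, "shrinkage_fit")
  if (is.null(fit)) abort("no shrinkage fit attached; run shrink_accessibility() first")
  fit
}

#' @export
print.etam_shrinkage <- function(x, ...) {
  cat(sprintf(
    "<etam_shrinkage> n_train=%d  folds=%d  anchor=%.4f  oof_mse=%.2e\n",
    x$n_train, x$folds, x$anchor, x$oof_mse))
  invisible(x)
}

#' @export
tidy.etam_shrinkage <- function(x, ...) {
  # a degenerate (constant-response) training set is legitimate here
  co <- suppressWarnings(summary(x$model))$coefficients
  tibble(term = rownames(co), estimate = co[, 1], std.error = co[, 2],
         statistic = co[, 3], p.value = co[, 4])
}

#' @export
glance.etam_shrinkage <- function(x, ...) {
  tibble(anchor = x$anchor, mean_raw = x$mean_raw, oof_mse = x$oof_mse,
         n_train = x$n_train, folds = x$folds,
         r.squared = suppressWarnings(summary(x$model))$r.squared)
}
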