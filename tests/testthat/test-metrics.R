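# Independent oracles: a brute-force binomial CDF by direct summation of
# the mass function, and an exact discrete convolution of the angular-error
# distribution for the permutation null.

oracle_binom_cdf <- function(k, n, p) {
  if (k < 0) return(0)
  sum(choose(n, 0:k) * p^(0:k) * (1 - p)^(n - (0:k)))
}

oracle_envelope <- function(n, p, alpha = 0.05) {
  ks <- 0:n
  cdf_km1 <- vapply(ks - 1, oracle_binom_cdf, 0, n = n, p = p)
  cdf_k <- vapply(ks, oracle_binom_cdf, 0, n = n, p = p)
  c(low = max(ks[cdf_km1 <= alpha]) / n,
    high = min(ks[cdf_k >= 1 - alpha]) / n)
}

# exact pmf of the sum of n iid angular errors (units of 45 deg)
oracle_error_sum_pmf <- function(n) {
  base <- c(1, 2, 2, 2, 1) / 8
  pmf <- 1
  for (i in seq_len(n)) {
    new <- numeric(length(pmf) + 4)
    for (j in 0:4) new[seq_along(pmf) + j] <- new[seq_along(pmf) + j] +
        pmf * base[j + 1]
    pmf <- new
  }
  pmf  # support 0:(4n)
}

test_that("binomial envelope matches the exact-CDF oracle", {
  for (p in c(0.5, 0.125)) {
    for (n in c(1, 2, 5, 10, 20, 57, 100, 250, 500)) {
      env <- binomial_envelope(n, p)
      orc <- oracle_envelope(n, p)
      expect_equal(c(env$low, env$high), unname(orc),
                   info = sprintf("n=%d p=%g", n, p))
    }
  }
})

test_that("binomial envelope hits the printed n=20 value and shrinks with n", {
  expect_equal(binomial_envelope(20, 0.5)$high, 14 / 20)  # = 0.70
  expect_equal(binomial_envelope(1, 0.5)$low, 0)
  expect_equal(binomial_envelope(1, 0.5)$high, 1)
  # upper bound (as a fraction) is non-increasing in n, up to lattice wiggle
  env <- binomial_envelope(10:500, 0.5)
  expect_lt(max(diff(env$high)), 0.034)     # local lattice effects only
  expect_lt(env$high[491], env$high[1])     # net decrease over the sweep
  fit <- stats::lm(high ~ n, data = env)    # monotone trend
  expect_lt(stats::coef(fit)[2], 0)
})

test_that("permutation envelope matches the exact convolution null", {
  penv <- permutation_envelope(30, replicates = 2e4, seed = 7)
  for (n in c(1, 5, 15, 30)) {
    pmf <- oracle_error_sum_pmf(n)
    cdf <- cumsum(pmf)
    s <- 0:(4 * n)
    lo <- 45 * min(s[cdf >= 0.05]) / n
    hi <- 45 * min(s[cdf >= 0.95]) / n
    expect_lte(abs(penv$low_deg[n] - lo), 45 / n)
    expect_lte(abs(penv$high_deg[n] - hi), 45 / n)
    expect_lt(abs(penv$null_mean_deg[n] - 90), 3)  # E|error| = 90 deg
  }
  # n = 1: null support is the error lattice itself
  expect_true(all(c(penv$low_deg[1], penv$high_deg[1]) %in%
                    c(0, 45, 90, 135, 180)))
})

test_that("permutation envelope is seed-reproducible and warns when unstable", {
  e1 <- permutation_envelope(10, replicates = 5000, seed = 3)
  e2 <- permutation_envelope(10, replicates = 5000, seed = 3)
  expect_identical(e1, e2)
  expect_warning(permutation_envelope(5, replicates = 500), "unstable")
})

test_that("cumulative traces track exact running accuracy", {
  cues <- rep(c("L", "R"), 30)
  tr_all <- cumulative_trace(
    tibble::tibble(cued_direction = cues, prediction = cues), 2)
  expect_true(all(tr_all$accuracy == 1))
  expect_equal(attr(tr_all, "last_nonsignificant"), 4)

  # alternating correct/incorrect: converges to 0.5, never significant
  pred_alt <- ifelse(seq_along(cues) %% 2 == 1, cues, "U")
  pred_alt[pred_alt == "U"] <- ifelse(cues[seq_along(cues) %% 2 == 0] == "L",
                                      "R", "L")
  tr_alt <- cumulative_trace(
    tibble::tibble(cued_direction = cues, prediction = pred_alt), 2)
  expect_equal(tr_alt$accuracy[60], 0.5)
  expect_false(any(tr_alt$acc_significant))
  expect_true(is.na(trials_to_significance(tr_alt)))
  expect_error(cumulative_trace(
    tibble::tibble(cued_direction = character(), prediction = character()),
    2), "no evaluated predictions")
})

test_that("8-target traces carry zero angular error for perfect predictions", {
  dirs <- rep(peripheral_directions(), 3)
  tr <- cumulative_trace(
    tibble::tibble(cued_direction = dirs, prediction = dirs), 8,
    replicates = 5000)
  expect_true(all(tr$angular_error_deg == 0))
  # a single zero-error prediction is not yet significant (P = 1/8 > .05);
  # from n = 2 the all-zero path lies below the null's 5th quantile
  expect_true(all(tr$ang_significant[-1]))
  expect_equal(attr(tr, "last_nonsignificant_angular"), 1L)
  expect_equal(trials_to_significance(tr, "angular"), 2L)
})

test_that("the trace recomputed from the final prediction list matches", {
  set.seed(14)
  cues <- sample(peripheral_directions(), 40, replace = TRUE)
  preds <- sample(c(peripheral_directions(), "CENTER"), 40, replace = TRUE)
  df <- tibble::tibble(cued_direction = cues, prediction = preds)
  a <- cumulative_trace(df, 8, replicates = 2000, seed = 5)
  b <- cumulative_trace(df, 8, replicates = 2000, seed = 5)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  # streamed prefix agrees with the full trace
  a_prefix <- cumulative_trace(df[1:25, ], 8, replicates = 2000, seed = 5)
  expect_equal(a_prefix$accuracy, a$accuracy[1:25])
  expect_equal(a_prefix$angular_error_deg, a$angular_error_deg[1:25])
})

test_that("confusion matrices are row-normalized with flagged empty rows", {
  cues <- rep(c("L", "R"), each = 10)
  cm <- confusion_matrix(
    tibble::tibble(cued_direction = cues, prediction = cues), 2)
  expect_equal(unclass(cm), 100 * diag(2),
               ignore_attr = TRUE)
  expect_equal(rowSums(cm), c(L = 100, R = 100))

  expect_warning(
    cm2 <- confusion_matrix(
      tibble::tibble(cued_direction = rep("L", 5), prediction = rep("R", 5)),
      2),
    "no predictions")
  expect_equal(unname(cm2["L", "R"]), 100)
  expect_warning(
    cm3 <- confusion_matrix(
      tibble::tibble(cued_direction = rep("L", 4), prediction = rep("L", 4)),
      2),
    "no predictions")
  expect_true(all(is.na(cm3["R", ])))

  # 8-target matrices have a CENTER column
  dirs <- rep(peripheral_directions(), 2)
  cm8 <- confusion_matrix(
    tibble::tibble(cued_direction = dirs, prediction = dirs), 8)
  expect_equal(colnames(cm8), c(peripheral_directions(), "CENTER"))
  expect_true(all(cm8[, "CENTER"] == 0))

  # random balanced 2-class predictions: rows near (50, 50)
  set.seed(15)
  rnd <- sample(c("L", "R"), 400, replace = TRUE)
  cmr <- confusion_matrix(
    tibble::tibble(cued_direction = rep(c("L", "R"), 200), prediction = rnd),
    2)
  expect_true(all(abs(cmr - 50) < 20))
  td <- tidy(cmr)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$percent), 200)
})
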