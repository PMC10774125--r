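# Performance quantification: cumulative percent correct and cumulative
# mean angular error, with chance envelopes from the exact binomial law
# (accuracy) and a permutation null (angular error).

#' Exact binomial chance envelope for cumulative accuracy
#'
#' For each number of predictions `n`, the 90% chance envelope under
#' Binomial(n, p_chance): the lower bound is the largest k with
#' CDF(k-1) <= alpha, the upper bound the smallest k with
#' CDF(k) >= 1 - alpha, both as fractions of n. Accuracy strictly above the
#' upper bound is significant at alpha (one-sided binomial test).
#'
#' @param n number(s) of predictions (vectorized).
#' @param p_chance per-trial chance probability (1/2 or 1/8).
#' @param alpha one-sided significance level (default 0.05).
#' @return Tibble with columns `n`, `low`, `high` (fractions).
#' @export
binomial_envelope <- function(n, p_chance, alpha = 0.05) {
  stopifnot(all(n >= 1), p_chance > 0, p_chance < 1)
  low <- high <- numeric(length(n))
  for (i in seq_along(n)) {
    k <- 0:n[i]
    cdf_km1 <- stats::pbinom(k - 1, n[i], p_chance)
    low[i] <- max(k[cdf_km1 <= alpha]) / n[i]
    cdf_k <- stats::pbinom(k, n[i], p_chance)
    high[i] <- min(k[cdf_k >= 1 - alpha]) / n[i]
  }
  tibble::tibble(n = n, low = low, high = high)
}

#' Permutation chance envelope for cumulative mean angular error
#'
#' Monte Carlo null for the eight-target task: each replicate draws
#' uniform random directions, and the cumulative mean absolute angular
#' error is tracked as a function of the number of predictions n. The
#' envelope is the 5th and 95th quantile of the null at each n. Because a
#' uniform random prediction against any fixed cue has the error
#' distribution {0, 45, 90, 135, 180} degrees with probabilities
#' (1, 2, 2, 2, 1)/8, cumulative means live on the 45/n-degree lattice;
#' replicates are tabulated exactly on that lattice, so quantiles are exact
#' functions of the Monte Carlo counts with bounded memory.
#'
#' @param n_max largest number of predictions.
#' @param n_targets must be 8 (angular error is defined for the 8-target
#'   task).
#' @param replicates Monte Carlo replicates (default 1e5).
#' @param alpha envelope tail probability per side (default 0.05).
#' @param seed RNG seed.
#' @return Tibble with columns `n`, `low_deg`, `high_deg`, `null_mean_deg`.
#' @export
permutation_envelope <- function(n_max, n_targets = 8, replicates = 1e5,
                                 alpha = 0.05, seed = 1) {
  stopifnot(n_targets == 8, n_max >= 1)
  if (replicates < 1000) {
    warning("permutation envelope with < 1000 replicates is unstable")
  }
  probs <- c(1, 2, 2, 2, 1) / 8  # |error| = 45 * {0,1,2,3,4} degrees
  counts <- lapply(seq_len(n_max), function(n) numeric(4 * n + 1))
  with_seed(seed, {
    chunk <- 5000L
    done <- 0L
    while (done < replicates) {
      r <- min(chunk, replicates - done)
      E <- matrix(sample.int(5L, r * n_max, replace = TRUE, prob = probs) - 1L,
                  r, n_max)
      S <- E
      for (t in seq_len(n_max)[-1]) S[, t] <- S[, t - 1] + E[, t]
      for (n in seq_len(n_max)) {
        counts[[n]] <- counts[[n]] + tabulate(S[, n] + 1L, 4 * n + 1)
      }
      done <- done + r
    }
  })
  low <- high <- nm <- numeric(n_max)
  for (n in seq_len(n_max)) {
    s <- 0:(4 * n)
    cdf <- cumsum(counts[[n]]) / replicates
    low[n] <- 45 * min(s[cdf >= alpha]) / n
    high[n] <- 45 * min(s[cdf >= 1 - alpha]) / n
    nm[n] <- 45 * sum(s * counts[[n]]) / (n * replicates)
  }
  tibble::tibble(n = seq_len(n_max), low_deg = low, high_deg = high,
                 null_mean_deg = nm)
}

#' Cumulative performance trace with chance envelopes
#'
#' Running cumulative percent correct (and, for eight-target tasks, running
#' mean absolute angular error) over the evaluated predictions, with the
#' binomial envelope attached at every n (and the permutation envelope for
#' angular error). Significance is one-sided: accuracy strictly above the
#' upper envelope bound; angular error strictly below the lower bound.
#'
#' @param data data frame with columns `cued_direction` and `prediction`
#'   (rows in evaluation order; rows without a prediction are dropped);
#'   an optional `trial` column is carried through.
#' @param n_targets 2 or 8.
#' @param alpha one-sided significance level.
#' @param replicates permutation replicates for the angular-error envelope.
#' @param seed RNG seed for the permutation envelope.
#' @return A tibble (class `fus_trace`) with one row per evaluated
#'   prediction: `trial`, `n_pred`, `accuracy`, `acc_low`, `acc_high`,
#'   `acc_significant`, and for 8 targets `angular_error_deg` (cumulative
#'   mean), `ang_low_deg`, `ang_high_deg`, `ang_significant`. Attributes
#'   `last_nonsignificant` (accuracy metric) and, for 8 targets,
#'   `last_nonsignificant_angular` hold the largest evaluated trial whose
#'   statistic is not beyond the envelope (0 if significant throughout).
#' @export
cumulative_trace <- function(data, n_targets, alpha = 0.05,
                             replicates = 1e5, seed = 1) {
  stopifnot(all(c("cued_direction", "prediction") %in% names(data)))
  data <- data[!is.na(data$prediction), , drop = FALSE]
  if (nrow(data) == 0) stop("no evaluated predictions")
  n <- nrow(data)
  trial <- if ("trial" %in% names(data)) data$trial else seq_len(n)
  correct <- data$prediction == data$cued_direction
  acc <- cumsum(correct) / seq_len(n)
  env <- binomial_envelope(seq_len(n), 1 / n_targets, alpha)
  out <- tibble::tibble(trial = trial, n_pred = seq_len(n),
                        n_correct = cumsum(correct), accuracy = acc,
                        acc_low = env$low, acc_high = env$high,
                        acc_significant = acc > env$high)
  last_ns <- function(sig) if (all(sig)) 0L else max(which(!sig))
  attr(out, "last_nonsignificant") <- trial_of(trial, last_ns(out$acc_significant))
  if (n_targets == 8) {
    err <- angular_error(data$cued_direction, data$prediction)
    cum_err <- cumsum(err) / seq_len(n)
    penv <- permutation_envelope(n, 8, replicates, alpha, seed)
    out$angular_error_deg <- cum_err
    out$ang_low_deg <- penv$low_deg
    out$ang_high_deg <- penv$high_deg
    out$ang_significant <- cum_err < penv$low_deg
    attr(out, "last_nonsignificant_angular") <-
      trial_of(trial, last_ns(out$ang_significant))
  }
  class(out) <- c("fus_trace", class(out))
  out
}

trial_of <- function(trial, i) if (i == 0L) 0L else as.integer(trial[i])

#' Number of trials needed to reach (and keep) significant decoding
#'
#' The trial after the last non-significant evaluated trial, per the
#' cumulative accuracy statistic; NA if the trace never becomes (or does
#' not end) significant.
#'
#' @param trace a [cumulative_trace()] result.
#' @param metric `"accuracy"` or `"angular"`.
#' @return Integer trial count, or NA.
#' @export
trials_to_significance <- function(trace, metric = c("accuracy", "angular")) {
  metric <- match.arg(metric)
  sig <- if (metric == "accuracy") trace$acc_significant else
    trace$ang_significant
  if (!sig[length(sig)]) return(NA_integer_)
  i <- if (all(sig)) 0L else max(which(!sig))
  as.integer(trace$n_pred[i + 1L])
}

#' Row-normalized confusion matrix
#'
#' Rows are cued classes, columns predicted classes (eight-target matrices
#' include a CENTER column); each row sums to 100. A cued class with no
#' predictions yields a row of NA with a warning (never silently zeroed).
#'
#' @param data data frame with `cued_direction` and `prediction` columns.
#' @param n_targets 2 or 8.
#' @return A percentage matrix of class `fus_confusion`.
#' @export
confusion_matrix <- function(data, n_targets) {
  stopifnot(all(c("cued_direction", "prediction") %in% names(data)))
  data <- data[!is.na(data$prediction), , drop = FALSE]
  cue_classes <- task_directions(n_targets)
  pred_classes <- if (n_targets == 8) c(cue_classes, "CENTER") else cue_classes
  tab <- table(factor(data$cued_direction, cue_classes),
               factor(data$prediction, pred_classes))
  m <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
              dimnames = list(cued = cue_classes, predicted = pred_classes))
  rs <- rowSums(m)
  if (any(rs == 0)) {
    warning("cue class(es) with no predictions: ",
            paste(cue_classes[rs == 0], collapse = ", "),
            " (rows set to NA)")
  }
  pct <- sweep(m, 1, rs, `/`) * 100
  pct[rs == 0, ] <- NA_real_
  structure(pct, class = c("fus_confusion", "matrix"))
}

#' @export
print.fus_confusion <- function(x, ...) {
  cat("<fus_confusion> row-normalized percentages (rows = cued):\n")
  print(round(unclass(x), 1))
  invisible(x)
}

#' @rdname confusion_matrix
#' @param x a `fus_confusion`.
#' @param ... unused.
#' @return `tidy()`: long tibble with columns `cued`, `predicted`,
#'   `percent`.
#' @method tidy fus_confusion
#' @export
tidy.fus_confusion <- function(x, ...) {
  g <- expand.grid(cued = rownames(x), predicted = colnames(x),
                   stringsAsFactors = FALSE)
  tibble::tibble(cued = g$cued, predicted = g$predicted,
                 percent = as.vector(unclass(x)))
}
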