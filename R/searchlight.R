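# Post hoc mapping of decodable information: a circular ROI (200 um
# radius = 2 voxels by default) slides over every voxel whose ROI fits
# entirely inside the grid; the task-appropriate decoder is cross-validated
# on the ROI's voxels and the mean fold performance is assigned to the
# centre voxel.

roi_offsets <- function(radius_px) {
  r <- radius_px
  g <- expand.grid(dy = -floor(r):floor(r), dx = -floor(r):floor(r))
  g[g$dy^2 + g$dx^2 <= r^2, ]
}

# seeded stratified fold assignment, shared across all ROIs
stratified_folds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Per-trial preprocessed feature frames for searchlight decoding
#'
#' Collects, for every behaviorally valid and decodable trial, the
#' preprocessed (z-scored, pillbox-filtered) last memory-period frames as
#' images, keeping the voxel geometry needed by the sliding-ROI analysis.
#'
#' @param session a [fus_session()].
#' @param config a [preproc_config()].
#' @return List with `frames` (`H x W x k x n_trials` array) and `labels`
#'   (cued directions).
#' @export
session_feature_frames <- function(session, config = preproc_config()) {
  prep <- preprocess_session(session, config)
  k <- config$feature_frames
  keep <- which(session$trials$valid)
  H <- prep$dims[1]; W <- prep$dims[2]
  frames <- array(NA_real_, dim = c(H, W, k, length(keep)))
  labels <- character(length(keep))
  ok <- logical(length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    idx <- feature_frame_indices(prep$timestamps,
                                 session$trials$t_memory_end[i], k)
    if (is.null(idx)) next
    for (m in seq_len(k)) frames[, , m, j] <- preprocessed_frame(prep, idx[m])
    labels[j] <- session$trials$cued_direction[i]
    ok[j] <- TRUE
  }
  list(frames = frames[, , , ok, drop = FALSE], labels = labels[ok])
}

# lean CV performance of the task decoder on one ROI feature matrix
roi_cv_performance <- function(X, labels, fold, n_targets, var_target,
                               shrinkage) {
  folds <- sort(unique(fold))
  perf <- numeric(length(folds))
  n_correct <- 0L
  for (fi in seq_along(folds)) {
    te <- fold == folds[fi]
    m <- fit_decoder(X[!te, , drop = FALSE], labels[!te], n_targets,
                     var_target, shrinkage)
    pred <- decoder_predict_labels(m, X[te, , drop = FALSE])
    if (n_targets == 2) {
      perf[fi] <- mean(pred == labels[te])
      n_correct <- n_correct + sum(pred == labels[te])
    } else {
      perf[fi] <- mean(angular_error(labels[te], pred))
      n_correct <- n_correct + sum(pred == labels[te])
    }
  }
  list(score = mean(perf), n_correct = n_correct)
}

#' Searchlight decoding map
#'
#' Slides a circular ROI across the image; at each centre voxel whose ROI
#' is fully contained in the grid, runs the task-appropriate decoder
#' (cPCA + LDA for two classes, the PCA + LDA multicoder for eight
#' directions) on the ROI's voxels (all feature time points) under
#' seeded stratified k-fold cross-validation, and assigns the mean fold
#' performance (accuracy, or mean angular error for eight targets) to the
#' centre voxel.
#'
#' @param feature_frames `H x W x k x n_trials` array from
#'   [session_feature_frames()].
#' @param labels per-trial cued directions.
#' @param n_targets 2 or 8.
#' @param radius_px ROI radius in pixels (default 2 = 200 um at 0.1 mm).
#' @param folds cross-validation folds (default 10).
#' @param seed seed for the fold assignment.
#' @param var_target,shrinkage decoder hyperparameters.
#' @return An object of class `fus_searchlight`: `score` matrix (NA where
#'   the ROI does not fit), `metric`, `n_correct` matrix, `scored` logical
#'   matrix, and the analysis parameters.
#' @export
searchlight_map <- function(feature_frames, labels, n_targets,
                            radius_px = 2, folds = 10, seed = 1,
                            var_target = 0.95, shrinkage = 0.1) {
  stopifnot(is.array(feature_frames), length(dim(feature_frames)) == 4,
            dim(feature_frames)[4] == length(labels))
  d <- dim(feature_frames)
  H <- d[1]; W <- d[2]; k <- d[3]; n <- d[4]
  counts <- table(labels)
  if (any(counts < folds)) {
    stop("stratified ", folds, "-fold CV needs >= ", folds,
         " trials per class")
  }
  off <- roi_offsets(radius_px)
  r_int <- max(abs(c(off$dy, off$dx)))
  if (H - 2 * r_int < 1 || W - 2 * r_int < 1) {
    stop("ROI radius ", radius_px, " does not fit inside the ", H, "x", W,
         " grid")
  }
  fold <- stratified_folds(labels, folds, seed)
  # trials x (voxel, frame) layout so one ROI is one column subset
  ap <- aperm(feature_frames, c(3, 1, 2, 4))
  Tall <- t(matrix(ap, k * H * W, n))
  score <- matrix(NA_real_, H, W)
  ncor <- matrix(NA_real_, H, W)
  for (cx in (1 + r_int):(W - r_int)) {
    vox0 <- (cx - 1) * H
    for (cy in (1 + r_int):(H - r_int)) {
      vs <- vox0 + cy + off$dy + off$dx * H
      cols <- rep((vs - 1) * k, each = k) + seq_len(k)
      res <- roi_cv_performance(Tall[, cols, drop = FALSE], labels, fold,
                                n_targets, var_target, shrinkage)
      score[cy, cx] <- res$score
      ncor[cy, cx] <- res$n_correct
    }
  }
  structure(list(score = score, n_correct = ncor, scored = !is.na(score),
                 metric = if (n_targets == 2) "accuracy" else
                   "angular_error",
                 n_trials = n, n_targets = n_targets,
                 radius_px = radius_px, folds = folds, seed = seed,
                 p = NULL, q = NULL),
            class = "fus_searchlight")
}

#' @export
print.fus_searchlight <- function(x, ...) {
  cat("<fus_searchlight> ", sum(x$scored), " scored voxels, metric = ",
      x$metric, ", radius = ", x$radius_px, " px, ", x$folds, "-fold CV\n",
      sep = "")
  invisible(x)
}

#' Voxel-wise significance of a searchlight map
#'
#' One-sided p-values per scored voxel — the exact binomial tail for
#' accuracy maps, the permutation-null lower tail for angular-error maps —
#' with Benjamini-Hochberg q-values over the scored voxels.
#'
#' @param map a [searchlight_map()] result.
#' @param replicates permutation replicates (angular-error maps).
#' @param seed permutation seed.
#' @return The map with `p` and `q` matrices filled in.
#' @export
voxel_significance <- function(map, replicates = 1e5, seed = 1) {
  stopifnot(inherits(map, "fus_searchlight"))
  n <- map$n_trials
  p <- matrix(NA_real_, nrow(map$score), ncol(map$score))
  idx <- which(map$scored)
  if (map$metric == "accuracy") {
    # P(X >= n_correct) under Binomial(n, 1/n_targets)
    p[idx] <- stats::pbinom(map$n_correct[idx] - 1, n, 1 / map$n_targets,
                            lower.tail = FALSE)
  } else {
    # lower tail of the permutation null of the mean angular error,
    # evaluated on the exact 45/n-degree lattice
    counts <- permutation_null_counts(n, replicates, seed)
    cdf <- cumsum(counts) / sum(counts)
    s_obs <- round(map$score[idx] * n / 45)
    p[idx] <- cdf[pmin(pmax(s_obs, 0), 4 * n) + 1]
  }
  q <- matrix(NA_real_, nrow(p), ncol(p))
  q[idx] <- stats::p.adjust(p[idx], method = "BH")
  map$p <- p
  map$q <- q
  map
}

# Monte Carlo counts of the n-prediction angular-error sum (in units of
# 45 degrees) under the uniform null; shared by the envelope and the
# searchlight tail.
permutation_null_counts <- function(n, replicates = 1e5, seed = 1) {
  probs <- c(1, 2, 2, 2, 1) / 8
  counts <- numeric(4 * n + 1)
  with_seed(seed, {
    chunk <- 20000L
    done <- 0L
    while (done < replicates) {
      r <- min(chunk, replicates - done)
      E <- matrix(sample.int(5L, r * n, replace = TRUE, prob = probs) - 1L,
                  r, n)
      counts <- counts + tabulate(rowSums(E) + 1L, 4 * n + 1)
      done <- done + r
    }
  })
  counts
}

#' Top-decile overlay mask of a searchlight map
#'
#' The 10% best-scoring scored voxels (highest accuracy, or lowest mean
#' angular error), `ceiling(0.10 * n_scored)` voxels in total; ties are
#' broken by p-value (when available) and then by scan order.
#'
#' @param map a [searchlight_map()] result (optionally with significance).
#' @param fraction mask fraction (default 0.10).
#' @return Logical `H x W` matrix.
#' @export
top_decile_mask <- function(map, fraction = 0.10) {
  stopifnot(inherits(map, "fus_searchlight"))
  idx <- which(map$scored)
  n_keep <- ceiling(fraction * length(idx))
  key <- map$score[idx]
  if (map$metric == "angular_error") key <- -key
  tie_p <- if (!is.null(map$p)) map$p[idx] else rep(0, length(idx))
  ord <- order(-key, tie_p, idx)
  mask <- matrix(FALSE, nrow(map$score), ncol(map$score))
  mask[idx[ord[seq_len(n_keep)]]] <- TRUE
  mask
}
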