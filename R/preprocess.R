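#' Preprocessing configuration
#'
#' Parameters of the streaming preprocessing applied before classification:
#' a rolling 60-frame (30 s) buffer, a rolling voxel-wise z-score over that
#' buffer, then a pillbox spatial filter of radius 2 pixels. Features are
#' the last `feature_frames` (default 3, i.e. 1.5 s) preprocessed frames of
#' the memory period.
#'
#' @param buffer_frames rolling buffer capacity in frames.
#' @param zscore_ddof degrees-of-freedom correction for the buffer standard
#'   deviation (1 = sample sd).
#' @param pillbox_radius_px pillbox filter radius in pixels.
#' @param pillbox_dialect `"area"` (area-weighted disk) or `"binary"`.
#' @param feature_frames number of memory-period frames per feature vector.
#' @param zscore_scope `"arrival"` (default): each decode frame is z-scored
#'   against the buffer state at its own arrival; `"final"`: all decode
#'   frames are z-scored against the buffer state at the last one's arrival.
#' @return A list of class `preproc_config`.
#' @export
preproc_config <- function(buffer_frames = 60, zscore_ddof = 1,
                           pillbox_radius_px = 2,
                           pillbox_dialect = c("area", "binary"),
                           feature_frames = 3,
                           zscore_scope = c("arrival", "final")) {
  stopifnot(buffer_frames >= 2, zscore_ddof %in% c(0, 1),
            pillbox_radius_px >= 1, feature_frames >= 1)
  pillbox_dialect <- match.arg(pillbox_dialect)
  zscore_scope <- match.arg(zscore_scope)
  structure(as.list(environment()), class = "preproc_config")
}

#' Streaming rolling frame buffer
#'
#' FIFO buffer of the most recent `capacity` raw frames, carrying running
#' cumulative sums so that rolling statistics are computed with the same
#' floating-point operation order as the vectorized batch path — the
#' streaming and replay code paths are bit-identical by construction.
#'
#' @param capacity buffer capacity in frames.
#' @param dims frame dimensions `c(H, W)`.
#' @return A list of class `rolling_buffer`.
#' @export
rolling_buffer <- function(capacity = 60, dims) {
  stopifnot(capacity >= 2, length(dims) == 2)
  structure(list(capacity = capacity, dims = as.integer(dims),
                 frames = list(),
                 csum = numeric(prod(dims)), csum2 = numeric(prod(dims)),
                 csum_before = numeric(prod(dims)),
                 csum2_before = numeric(prod(dims)),
                 n_seen = 0L),
            class = "rolling_buffer")
}

#' @rdname rolling_buffer
#' @param buf a `rolling_buffer`.
#' @param frame `H x W` matrix matching the buffer dimensions.
#' @return `push_frame()`: the updated buffer (newest appended, oldest
#'   evicted once full).
#' @export
push_frame <- function(buf, frame) {
  stopifnot(inherits(buf, "rolling_buffer"), is.matrix(frame))
  if (!identical(dim(frame), buf$dims)) {
    stop("frame dims ", paste(dim(frame), collapse = "x"),
         " do not match buffer dims ", paste(buf$dims, collapse = "x"))
  }
  v <- as.vector(frame)
  buf$frames[[length(buf$frames) + 1]] <- v
  buf$csum <- buf$csum + v
  buf$csum2 <- buf$csum2 + v * v
  buf$n_seen <- buf$n_seen + 1L
  if (length(buf$frames) > buf$capacity) {
    ev <- buf$frames[[1]]
    buf$csum_before <- buf$csum_before + ev
    buf$csum2_before <- buf$csum2_before + ev * ev
    buf$frames <- buf$frames[-1]
  }
  buf
}

#' @rdname rolling_buffer
#' @export
buffer_size <- function(buf) length(buf$frames)

# Rolling mean/sd of the current window from the running sums; the
# sums-of-squares variance is floored at 0 and a relative tolerance maps
# constant (zero-variance) voxels to sd = 0.
window_stats <- function(s1, s2, n, ddof) {
  mean <- s1 / n
  v <- (s2 - n * mean * mean) / (n - ddof)
  msq <- s2 / n
  v[v < 0 | v < 1e-12 * msq] <- 0
  list(mean = mean, sd = sqrt(v))
}

#' Rolling voxel-wise z-score of a buffer
#'
#' Z-scores every frame in the buffer against the buffer's voxel-wise mean
#' and standard deviation (ddof = 1 by default). Voxels with zero variance
#' map to 0. Requires at least 2 buffered frames.
#'
#' @param buf a [rolling_buffer()] holding >= 2 frames.
#' @param zscore_ddof degrees-of-freedom correction.
#' @return `H x W x n` array of z-scored frames (newest last).
#' @export
rolling_zscore <- function(buf, zscore_ddof = 1) {
  stopifnot(inherits(buf, "rolling_buffer"))
  n <- length(buf$frames)
  if (n < 2) stop("rolling z-score needs at least 2 buffered frames")
  st <- window_stats(buf$csum - buf$csum_before,
                     buf$csum2 - buf$csum2_before, n, zscore_ddof)
  out <- array(0, dim = c(buf$dims, n))
  zero <- st$sd == 0
  for (j in seq_len(n)) {
    z <- buf$frames[[j]] - st$mean
    z[zero] <- 0
    z[!zero] <- z[!zero] / st$sd[!zero]
    out[, , j] <- matrix(z, buf$dims[1], buf$dims[2])
  }
  out
}

#' Batch preprocessor over a recorded session
#'
#' Computes, for every frame, the rolling voxel-wise z-score against the
#' `buffer_frames`-frame window ending at that frame (the buffer state at
#' the frame's arrival). Pillbox filtering is applied on demand per frame.
#' The result is bit-identical to pushing the frames through a
#' [rolling_buffer()] one at a time.
#'
#' @param session a [fus_session()].
#' @param config a [preproc_config()].
#' @return A `fus_preproc` object; use [preprocessed_frame()] to obtain
#'   individual z-scored, filtered frames.
#' @export
preprocess_session <- function(session, config = preproc_config()) {
  stopifnot(inherits(session, "fus_session"),
            inherits(config, "preproc_config"))
  d <- dim(session$frames)
  V <- d[1] * d[2]; T_ <- d[3]
  X <- matrix(session$frames, V, T_)
  # per-voxel cumulative sums; z-scored frames are derived lazily per
  # frame (a closed-loop run only ever touches the decode frames). the
  # sums are accumulated with plain double additions in arrival order —
  # the same operations as the streaming buffer's running sums — so the
  # two paths are bit-identical (base cumsum would accumulate in extended
  # precision and break that).
  S1 <- X; S2 <- X * X
  for (t in seq_len(T_)[-1]) {
    S1[, t] <- S1[, t - 1] + X[, t]
    S2[, t] <- S2[, t - 1] + X[, t] * X[, t]
  }
  structure(list(X = X, S1 = S1, S2 = S2, dims = d[1:2], n_frames = T_,
                 kernel = pillbox_kernel(config$pillbox_radius_px,
                                         config$pillbox_dialect),
                 config = config, timestamps = session$timestamps),
            class = "fus_preproc")
}

# rolling voxel-wise z-score of frame t against the buffer window ending
# at its arrival (same arithmetic as rolling_zscore on a streaming buffer)
zscored_frame_vec <- function(prep, t) {
  if (t < 2) stop("rolling z-score needs at least 2 buffered frames")
  cap <- prep$config$buffer_frames
  s1 <- prep$S1[, t]; s2 <- prep$S2[, t]
  if (t > cap) {
    s1 <- s1 - prep$S1[, t - cap]
    s2 <- s2 - prep$S2[, t - cap]
  }
  st <- window_stats(s1, s2, min(t, cap), prep$config$zscore_ddof)
  z <- prep$X[, t] - st$mean
  zero <- st$sd == 0
  z[zero] <- 0
  z[!zero] <- z[!zero] / st$sd[!zero]
  z
}

#' @rdname preprocess_session
#' @param prep a `fus_preproc`.
#' @param t frame index (must be >= 2: one frame alone has no rolling sd).
#' @return `zscored_frame()`: the rolling z-scored frame (unfiltered).
#' @export
zscored_frame <- function(prep, t) {
  stopifnot(inherits(prep, "fus_preproc"), t >= 2, t <= prep$n_frames)
  matrix(zscored_frame_vec(prep, t), prep$dims[1], prep$dims[2])
}

#' @rdname preprocess_session
#' @return `preprocessed_frame()`: the z-scored, pillbox-filtered frame.
#' @export
preprocessed_frame <- function(prep, t) {
  conv2_zero(zscored_frame(prep, t), prep$kernel)
}

# Indices of the k most recent frames at or before time `t_end`; NULL if
# the trial cannot yield a warm, complete feature window.
feature_frame_indices <- function(timestamps, t_end, k) {
  idx <- which(timestamps <= t_end)
  if (length(idx) < k) return(NULL)
  idx <- utils::tail(idx, k)
  if (idx[1] < 2) return(NULL)  # cold buffer: no sd defined yet
  idx
}

#' Extract the decode feature vector for one trial
#'
#' The feature vector is the concatenation of the last `feature_frames`
#' preprocessed frames of the memory period (timestamps at or before
#' `t_memory_end`), oldest frame first, each frame flattened column-major.
#' Length is `feature_frames * H * W`. Returns NULL (trial not decodable)
#' if fewer than `feature_frames` frames precede the end of memory or the
#' buffer is cold.
#'
#' @param prep a [preprocess_session()] result.
#' @param t_memory_end end of the trial's memory period (seconds).
#' @return Numeric feature vector, or NULL.
#' @export
extract_features <- function(prep, t_memory_end) {
  stopifnot(inherits(prep, "fus_preproc"))
  k <- prep$config$feature_frames
  idx <- feature_frame_indices(prep$timestamps, t_memory_end, k)
  if (is.null(idx)) return(NULL)
  if (prep$config$zscore_scope == "final") {
    # all decode frames z-scored against the buffer window ending at the
    # final decode frame's arrival
    t_ref <- idx[k]
    win <- max(1, t_ref - prep$config$buffer_frames + 1):t_ref
    st <- window_stats(rowSums(prep$X[, win, drop = FALSE]),
                       rowSums(prep$X[, win, drop = FALSE]^2),
                       length(win), prep$config$zscore_ddof)
    zero <- st$sd == 0
    return(unlist(lapply(idx, function(t) {
      z <- prep$X[, t] - st$mean
      z[zero] <- 0
      z[!zero] <- z[!zero] / st$sd[!zero]
      as.vector(conv2_zero(matrix(z, prep$dims[1], prep$dims[2]),
                           prep$kernel))
    }), use.names = FALSE))
  }
  unlist(lapply(idx, function(t) as.vector(preprocessed_frame(prep, t))),
         use.names = FALSE)
}

#' Collect decode features for every trial of a session
#'
#' Runs the batch preprocessor and extracts the per-trial feature vectors.
#' Trials whose feature window is incomplete are marked not decodable.
#'
#' @param session a [fus_session()].
#' @param config a [preproc_config()].
#' @return A list with `features` (n_trials x D matrix, NA rows where not
#'   decodable), `decodable` (logical), `frame_indices` (list), and the
#'   `fus_preproc` object as `prep`.
#' @export
session_features <- function(session, config = preproc_config()) {
  prep <- preprocess_session(session, config)
  k <- config$feature_frames
  n <- nrow(session$trials)
  D <- k * prod(prep$dims)
  feats <- matrix(NA_real_, n, D)
  decodable <- logical(n)
  fidx <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- feature_frame_indices(prep$timestamps,
                                 session$trials$t_memory_end[i], k)
    fidx[[i]] <- idx
    if (is.null(idx)) next
    feats[i, ] <- extract_features(prep, session$trials$t_memory_end[i])
    decodable[i] <- TRUE
  }
  list(features = feats, decodable = decodable, frame_indices = fidx,
       prep = prep)
}
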