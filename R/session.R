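#' fUS session recordings
#'
#' A `fus_session` bundles an ordered stack of 2 Hz power-Doppler frames with
#' per-frame timestamps, a per-trial event table, a single mean power-Doppler
#' anatomy image used for cross-session alignment, and task metadata. It is
#' the unit of storage and replay for the whole pipeline.
#'
#' @param frames numeric array `H x W x T` of non-negative power-Doppler
#'   intensities (arbitrary units).
#' @param timestamps numeric vector of length `T`, strictly increasing frame
#'   times in seconds.
#' @param trials tibble of trial records (see [trial_columns()]).
#' @param anatomy `H x W` matrix; defaults to the mean frame.
#' @param meta named list: `n_targets` (2 or 8), `eccentricity_deg`,
#'   `voxel_size_mm`, `frame_period_s`, `seed`, free-form provenance.
#' @return An object of class `fus_session`.
#' @export
fus_session <- function(frames, timestamps, trials,
                        anatomy = NULL, meta = list()) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (dim(frames)[3] != length(timestamps)) {
    stop("frame count (", dim(frames)[3], ") does not match number of ",
         "timestamps (", length(timestamps), ")")
  }
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  trials <- validate_trials(trials)
  if (nrow(trials) > 0) {
    tmin <- min(timestamps); tmax <- max(timestamps)
    tcols <- c("t_fixation", "t_cue_on", "t_cue_off", "t_memory_end",
               "t_movement", "t_reward")
    tt <- unlist(trials[tcols])
    tt <- tt[is.finite(tt)]
    if (length(tt) > 0 && (min(tt) < tmin - 1e-9 || max(tt) > tmax + 1e-9)) {
      stop("trial phase times fall outside the frame timestamp range")
    }
  }
  if (is.null(anatomy)) anatomy <- apply(frames, c(1, 2), mean)
  meta <- utils::modifyList(
    list(n_targets = NA_integer_, eccentricity_deg = 20,
         voxel_size_mm = 0.1, frame_period_s = 0.5, seed = NA_integer_),
    meta)
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 trials = trials, anatomy = anatomy, meta = meta),
            class = "fus_session")
}

#' Canonical trial-table columns
#'
#' @return Character vector of the required columns of a trial table.
#' @export
trial_columns <- function() {
  c("trial", "task", "cued_direction", "t_fixation", "t_cue_on", "t_cue_off",
    "t_memory_end", "t_movement", "t_reward", "valid", "success", "prediction")
}

validate_trials <- function(trials) {
  trials <- tibble::as_tibble(trials)
  missing <- setdiff(trial_columns(), names(trials))
  if (length(missing) > 0) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  }
  trials <- trials[trial_columns()]
  if (nrow(trials) == 0) return(trials)
  if (!all(trials$trial == seq_len(nrow(trials)))) {
    stop("trials must be numbered 1..n in order")
  }
  if (!all(trials$task %in% c("saccade", "reach", "bmi"))) {
    bad <- which(!trials$task %in% c("saccade", "reach", "bmi"))[1]
    stop("row ", bad, ": unknown task '", trials$task[bad], "'")
  }
  bad_cue <- which(!trials$cued_direction %in% peripheral_directions())
  if (length(bad_cue) > 0) {
    stop("row ", bad_cue[1], ": cued_direction '",
         trials$cued_direction[bad_cue[1]],
         "' is not a peripheral direction (CENTER is never a cue)")
  }
  ph <- as.matrix(trials[c("t_fixation", "t_cue_on", "t_cue_off",
                           "t_memory_end", "t_movement", "t_reward")])
  ord_ok <- apply(ph, 1, function(r) {
    r <- r[is.finite(r)]
    length(r) < 2 || all(diff(r) >= 0)
  })
  if (!all(ord_ok)) {
    stop("row ", which(!ord_ok)[1], ": phase times are not ordered")
  }
  if (any(trials$success & !trials$valid)) {
    stop("row ", which(trials$success & !trials$valid)[1],
         ": success implies valid")
  }
  ok_pred <- is.na(trials$prediction) |
    trials$prediction %in% c(peripheral_directions(), "CENTER")
  if (!all(ok_pred)) {
    stop("row ", which(!ok_pred)[1], ": bad prediction label")
  }
  trials
}

#' @export
print.fus_session <- function(x, ...) {
  d <- dim(x$frames)
  cat("<fus_session> ", d[1], "x", d[2], " voxels, ", d[3], " frames (",
      round(diff(range(x$timestamps)), 1), " s), ", nrow(x$trials),
      " trials, n_targets = ", x$meta$n_targets, "\n", sep = "")
  invisible(x)
}

#' @export
dim.fus_session <- function(x) dim(x$frames)

#' Read and write fUS sessions on disk
#'
#' A session directory holds `frames.nii.gz` (NIfTI-1, dims H x W x 1 x T,
#' pixdim carrying the 0.1 mm in-plane spacing and 0.5 s frame period),
#' `events.csv` (one row per trial, columns [trial_columns()]), and
#' `meta.json` (timestamps, task geometry, seed, provenance). The round trip
#' is lossless for pixels (single-precision NIfTI storage), timestamps and
#' all trial fields.
#'
#' @param session a `fus_session`.
#' @param path directory to write to / read from.
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns a `fus_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "fus_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(session$frames)
  arr <- array(session$frames, dim = c(d[1], d[2], 1L, d[3]))
  nii <- RNifti::asNifti(arr)
  vx <- session$meta$voxel_size_mm
  RNifti::pixdim(nii) <- c(vx, vx, 1, session$meta$frame_period_s)
  RNifti::writeNifti(nii, file.path(path, "frames.nii.gz"))
  readr::write_csv(session$trials, file.path(path, "events.csv"), na = "")
  meta <- session$meta
  meta$timestamps <- session$timestamps
  meta$anatomy <- as.vector(session$anatomy)
  meta$anatomy_dim <- d[1:2]
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  f_nii <- file.path(path, "frames.nii.gz")
  f_csv <- file.path(path, "events.csv")
  f_json <- file.path(path, "meta.json")
  for (f in c(f_nii, f_csv, f_json)) {
    if (!file.exists(f)) stop("missing session file: ", f)
  }
  nii <- RNifti::readNifti(f_nii)
  d <- dim(nii)
  frames <- array(as.numeric(nii), dim = c(d[1], d[2], d[length(d)]))
  meta <- jsonlite::read_json(f_json, simplifyVector = TRUE)
  timestamps <- as.numeric(meta$timestamps)
  if (length(timestamps) != dim(frames)[3]) {
    stop("frame stack has ", dim(frames)[3], " frames but meta.json lists ",
         length(timestamps), " timestamps")
  }
  anatomy <- matrix(as.numeric(meta$anatomy),
                    nrow = meta$anatomy_dim[1], ncol = meta$anatomy_dim[2])
  meta$timestamps <- NULL; meta$anatomy <- NULL; meta$anatomy_dim <- NULL
  trials <- read_events_csv(f_csv)
  fus_session(frames, timestamps, trials, anatomy = anatomy, meta = meta)
}

read_events_csv <- function(file) {
  trials <- tryCatch(
    readr::read_csv(file, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      trial = readr::col_integer(),
                      task = readr::col_character(),
                      cued_direction = readr::col_character(),
                      valid = readr::col_logical(),
                      success = readr::col_logical(),
                      prediction = readr::col_character(),
                      .default = readr::col_double())),
    error = function(e) stop("malformed events CSV: ", conditionMessage(e)))
  prob <- readr::problems(trials)
  if (nrow(prob) > 0) {
    stop("malformed events CSV at row ", prob$row[1], ": ", prob$expected[1],
         " expected, got '", prob$actual[1], "'")
  }
  validate_trials(trials)
}
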