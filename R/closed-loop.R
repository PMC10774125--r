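# The experiment protocol: shadow decoding during the instructed-movement
# training phase, the switch to closed-loop BMI control after 100 successful
# training trials, phase-dependent success rules, training-set growth
# policies, pretraining from a rigidly aligned previous session, and post
# hoc replay. The cued direction of the in-progress trial is never visible
# to the decoding path until after the trial ends: predictions are computed
# from the feature vector alone, before the trial's label is consulted.

#' Closed-loop protocol configuration
#'
#' @param n_targets 2 or 8.
#' @param switch_threshold successful training trials required before the
#'   switch to closed-loop BMI control (default 100).
#' @param policy training-set growth policy: `"realtime"` appends only
#'   successful trials (the online protocol); `"replay"` appends every
#'   valid trial regardless of prediction correctness (the post hoc
#'   simulation protocol, which keeps the training set balanced when
#'   early predictions are poor).
#' @param retrain refit the decoder whenever the training set grows
#'   (disable to freeze a pretrained model).
#' @param min_eval_trial first trial included in performance evaluation
#'   (shadow predictions before it are not scored; default 20).
#' @param var_target,shrinkage decoder hyperparameters, see
#'   [fit_cpca_lda()].
#' @param preproc a [preproc_config()].
#' @return A list of class `closed_loop_config`.
#' @export
closed_loop_config <- function(n_targets, switch_threshold = 100,
                               policy = c("realtime", "replay"),
                               retrain = TRUE, min_eval_trial = 20,
                               var_target = 0.95, shrinkage = 0.1,
                               preproc = preproc_config()) {
  stopifnot(n_targets %in% c(2, 8), switch_threshold >= 1)
  policy <- match.arg(policy)
  structure(as.list(environment()), class = "closed_loop_config")
}

#' Phase-dependent trial success rule
#'
#' During the training phase a trial succeeds iff the subject performed the
#' instructed movement correctly (the shadow decoder's prediction is
#' irrelevant and invisible). In BMI mode a trial succeeds iff the decoder
#' predicted the cued direction AND fixation was maintained until reward.
#' CENTER predictions never match a cue.
#'
#' @param valid did the trial reach the prediction point.
#' @param behavior_ok did the subject complete the behavioral requirement
#'   (correct movement in training; maintained fixation in BMI mode).
#' @param prediction decoder prediction (NA if none).
#' @param cue cued direction.
#' @param phase `"training"` or `"bmi"`.
#' @return Logical.
#' @export
trial_success <- function(valid, behavior_ok, prediction, cue, phase) {
  if (!valid) return(FALSE)
  if (phase == "training") return(isTRUE(behavior_ok))
  isTRUE(behavior_ok) && !is.na(prediction) && prediction == cue
}

can_fit_decoder <- function(labels, n_targets) {
  if (length(labels) < 4) return(FALSE)
  if (n_targets == 2) {
    counts <- table(factor(labels, task_directions(2)))
    return(all(counts >= 2))
  }
  if (!all(peripheral_directions() %in% labels)) return(FALSE)
  comp <- decompose_direction(labels)
  all(table(factor(comp$vertical, .VERTICAL_LEVELS)) >= 2) &&
    all(table(factor(comp$horizontal, .HORIZONTAL_LEVELS)) >= 2)
}

#' Build a pretraining set from a previous session
#'
#' Applies the rigid alignment transform to every frame of the previous
#' session (and its anatomy), re-runs the streaming preprocessing on the
#' transformed frames, and extracts features for all valid trials — the
#' initialization used when a decoder is seeded with a previous day's data.
#'
#' @param prev_session the previous session ([fus_session()]).
#' @param transform the [rigid_transform2d()] aligning the previous
#'   session's imaging plane to the current one (e.g. from
#'   [register_rigid()]).
#' @param config a [closed_loop_config()] (preprocessing and task settings
#'   must match the current session's).
#' @return A list of class `fus_pretrain` with `features`, `labels`,
#'   `provenance`.
#' @export
pretrain_from_previous <- function(prev_session, transform, config) {
  stopifnot(inherits(prev_session, "fus_session"),
            inherits(transform, "rigid_transform2d"),
            inherits(config, "closed_loop_config"))
  aligned <- prev_session
  aligned$frames <- apply_transform(prev_session$frames, transform)
  aligned$anatomy <- apply_transform(prev_session$anatomy, transform)
  sf <- session_features(aligned, config$preproc)
  keep <- prev_session$trials$valid & sf$decodable
  if (!any(keep)) stop("previous session has no valid decodable trials")
  structure(list(features = sf$features[keep, , drop = FALSE],
                 labels = prev_session$trials$cued_direction[keep],
                 provenance = rep("previous", sum(keep))),
            class = "fus_pretrain")
}

#' Run the closed-loop fUS-BMI protocol over a session
#'
#' Streams a session's trials through the full protocol: preprocess,
#' extract the last three memory-period frames, predict with the current
#' decoder (shadow prediction during the training phase, live control in
#' BMI mode), apply the phase-dependent success rule, grow the training set
#' per the policy, refit the decoder, and switch to BMI mode once the
#' successful-training-trial threshold is reached. Deterministic given
#' (session, config, pretrain): replaying a recorded session reproduces
#' the identical prediction sequence.
#'
#' @param session a [fus_session()] (live synthetic generation or a
#'   recorded session being replayed).
#' @param config a [closed_loop_config()].
#' @param pretrain optional [pretrain_from_previous()] result used to seed
#'   the training set (provenance "previous") and fit the model before the
#'   first trial.
#' @param seed seed for the permutation envelope in the performance trace.
#' @param envelope_replicates permutation replicates for the angular-error
#'   envelope of eight-target traces.
#' @return A list of class `fus_bmi_result`: `predictions` (per-trial
#'   tibble), `trace` (a [cumulative_trace()] over evaluated trials),
#'   `model` (final decoder), `trials` (session trial table with
#'   predictions filled in), `config`.
#' @export
run_closed_loop <- function(session, config, pretrain = NULL, seed = 1,
                            envelope_replicates = 1e4) {
  stopifnot(inherits(session, "fus_session"),
            inherits(config, "closed_loop_config"))
  sf <- session_features(session, config$preproc)
  trials <- session$trials
  n <- nrow(trials)
  D <- ncol(sf$features)
  n_pre <- if (is.null(pretrain)) 0L else nrow(pretrain$features)
  Xtr <- matrix(NA_real_, n_pre + n, D)
  labels <- character(n_pre + n)
  provenance <- character(n_pre + n)
  n_tr <- 0L
  add_row <- function(v, lab, prov) {
    n_tr <<- n_tr + 1L
    Xtr[n_tr, ] <<- v
    labels[n_tr] <<- lab
    provenance[n_tr] <<- prov
  }
  if (!is.null(pretrain)) {
    stopifnot(inherits(pretrain, "fus_pretrain"),
              ncol(pretrain$features) == D)
    for (i in seq_len(n_pre)) {
      add_row(pretrain$features[i, ], pretrain$labels[i], "previous")
    }
  }
  model <- NULL
  refit <- function() {
    if (can_fit_decoder(labels[seq_len(n_tr)], config$n_targets)) {
      model <<- fit_decoder(Xtr[seq_len(n_tr), , drop = FALSE],
                            labels[seq_len(n_tr)], config$n_targets,
                            config$var_target, config$shrinkage)
    }
  }
  refit()

  phase <- character(n)
  prediction <- rep(NA_character_, n)
  success <- logical(n)
  added <- logical(n)
  cur_phase <- "training"
  n_success_training <- 0L
  for (i in seq_len(n)) {
    phase[i] <- cur_phase
    decodable <- sf$decodable[i] && trials$valid[i]
    # prediction from features only; the trial's cue is consulted after
    if (!is.null(model) && decodable) {
      prediction[i] <- decoder_predict_labels(
        model, matrix(sf$features[i, ], 1))
    }
    cue <- trials$cued_direction[i]
    success[i] <- trial_success(trials$valid[i], trials$success[i],
                                prediction[i], cue, cur_phase)
    admit <- switch(config$policy,
                    realtime = success[i] && decodable,
                    replay = decodable)
    if (admit) {
      add_row(sf$features[i, ], cue, "current")
      added[i] <- TRUE
      if (config$retrain || is.null(model)) refit()
    }
    if (cur_phase == "training") {
      if (success[i]) n_success_training <- n_success_training + 1L
      if (n_success_training >= config$switch_threshold) cur_phase <- "bmi"
    }
  }

  predictions <- tibble::tibble(
    trial = trials$trial, phase = phase,
    cued_direction = trials$cued_direction, prediction = prediction,
    valid = trials$valid, success = success, added = added)
  out_trials <- trials
  out_trials$prediction <- prediction
  out_trials$success <- success
  eval_rows <- predictions[!is.na(predictions$prediction) &
                             predictions$trial >= config$min_eval_trial, ]
  trace <- if (nrow(eval_rows) > 0) {
    cumulative_trace(eval_rows, config$n_targets, seed = seed,
                     replicates = envelope_replicates)
  }
  structure(list(predictions = predictions, trace = trace, model = model,
                 trials = out_trials, config = config,
                 n_pretrain = n_pre,
                 n_success_training = n_success_training,
                 training_labels = labels[seq_len(n_tr)],
                 training_provenance = provenance[seq_len(n_tr)]),
            class = "fus_bmi_result")
}

#' @export
print.fus_bmi_result <- function(x, ...) {
  n_eval <- if (is.null(x$trace)) 0 else nrow(x$trace)
  acc <- if (n_eval > 0) x$trace$accuracy[n_eval] else NA
  cat("<fus_bmi_result> ", nrow(x$predictions), " trials (",
      sum(x$predictions$phase == "bmi"), " in BMI mode), ",
      n_eval, " evaluated predictions, final cumulative accuracy = ",
      ifelse(is.na(acc), "NA", sprintf("%.1f%%", 100 * acc)), "\n", sep = "")
  invisible(x)
}

#' Replay a recorded session through the closed-loop code path
#'
#' Streams a recorded session, frame by frame, through the same protocol
#' as [run_closed_loop()], with the post hoc training-set policy (every
#' valid trial is added regardless of prediction correctness). Supports
#' the "no pretraining" and "pretrained, frozen model" variants.
#'
#' @inheritParams run_closed_loop
#' @param retrain set FALSE to freeze the (pretrained) model.
#' @return A `fus_bmi_result`.
#' @export
replay_session <- function(session, config, pretrain = NULL,
                           retrain = TRUE, seed = 1,
                           envelope_replicates = 1e4) {
  config$policy <- "replay"
  config$retrain <- retrain
  run_closed_loop(session, config, pretrain = pretrain, seed = seed,
                  envelope_replicates = envelope_replicates)
}
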