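#' Task timing configuration for memory-guided movement sessions
#'
#' Defaults follow the memory-guided saccade task: fixation 5 s (+/- 1 s
#' uniform jitter), peripheral cue 400 ms, memory period 5 s (+/- 1 s),
#' hold 1.5 s (+/- 0.5 s), intertrial interval 8 s (+/- 2 s), 2 Hz frames,
#' targets at 20 degrees eccentricity.
#'
#' @param n_targets 2 or 8 cue directions. Two-target tasks use L and R.
#' @param fixation_s,fixation_jitter_s fixation duration and jitter bound.
#' @param cue_s cue duration (no jitter).
#' @param memory_s,memory_jitter_s memory-period duration and jitter bound.
#' @param hold_s,hold_jitter_s hold duration and jitter bound.
#' @param iti_s,iti_jitter_s intertrial interval and jitter bound.
#' @param frame_rate_hz imaging frame rate.
#' @param eccentricity_deg target eccentricity (metadata only).
#' @param p_behavior_success probability that the simulated subject
#'   completes a trial's behavioral requirements (fixation/movement).
#' @return A list of class `task_config`.
#' @export
task_config <- function(n_targets = 8,
                        fixation_s = 5, fixation_jitter_s = 1,
                        cue_s = 0.4,
                        memory_s = 5, memory_jitter_s = 1,
                        hold_s = 1.5, hold_jitter_s = 0.5,
                        iti_s = 8, iti_jitter_s = 2,
                        frame_rate_hz = 2,
                        eccentricity_deg = 20,
                        p_behavior_success = 1.0) {
  stopifnot(n_targets %in% c(2, 8),
            fixation_s > 0, cue_s > 0, memory_s > 0, hold_s > 0, iti_s > 0,
            fixation_jitter_s >= 0, fixation_jitter_s < fixation_s,
            memory_jitter_s >= 0, memory_jitter_s < memory_s,
            hold_jitter_s >= 0, hold_jitter_s < hold_s,
            iti_jitter_s >= 0, iti_jitter_s < iti_s,
            frame_rate_hz > 0,
            p_behavior_success >= 0, p_behavior_success <= 1)
  structure(as.list(environment()), class = "task_config")
}

task_directions <- function(n_targets) {
  if (n_targets == 2) c("L", "R") else peripheral_directions()
}

# Balanced pseudo-random cue order: shuffled balanced blocks (each block is
# a random permutation of the target set), truncated to n_trials, so every
# direction is cued floor(n/k) or ceiling(n/k) times.
balanced_cues <- function(n_trials, n_targets) {
  dirs <- task_directions(n_targets)
  n_blocks <- ceiling(n_trials / n_targets)
  seq <- unlist(lapply(seq_len(n_blocks), function(b) sample(dirs)))
  seq[seq_len(n_trials)]
}

#' Generate a synthetic fUS session
#'
#' Simulates a full recording: a jittered trial schedule, a balanced
#' pseudo-random cue sequence, and a 2 Hz power-Doppler frame stack in which
#' each tuned patch of the phantom responds to the cue-plus-memory interval
#' with its von Mises tuning gain convolved with the hemodynamic response,
#' on top of multiplicative voxel noise, slow global gain drift and a
#' pulsatility oscillation:
#' `frame(t) = anatomy * (1 + sum_p mask_p tuning_p(cue) amp_p (boxcar * hrf)(t))
#'             * (1 + noise) * gain(t)`.
#'
#' Sessions are bit-deterministic given `(phantom, task, n_trials, seed)`.
#'
#' @param phantom a [make_phantom()] phantom.
#' @param task a [task_config()].
#' @param n_trials number of trials (>= 1).
#' @param seed RNG seed.
#' @param task_name recorded task label ("saccade", "reach" or "bmi").
#' @return A [fus_session()] whose `meta$ground_truth` carries the patch
#'   masks and tuning parameters.
#' @export
generate_session <- function(phantom, task = task_config(), n_trials,
                             seed = 1, task_name = "saccade") {
  stopifnot(inherits(phantom, "fus_phantom"), inherits(task, "task_config"),
            n_trials >= 1)
  with_seed(seed, {
    jit <- function(n, b) if (b > 0) stats::runif(n, -b, b) else rep(0, n)
    fix_d <- task$fixation_s + jit(n_trials, task$fixation_jitter_s)
    mem_d <- task$memory_s + jit(n_trials, task$memory_jitter_s)
    hold_d <- task$hold_s + jit(n_trials, task$hold_jitter_s)
    iti_d <- task$iti_s + jit(n_trials, task$iti_jitter_s)
    cues <- balanced_cues(n_trials, task$n_targets)
    complete <- stats::runif(n_trials) < task$p_behavior_success
    # incomplete trials: half break before the end of memory (invalid),
    # half complete the memory period but fail the movement/hold (valid)
    early_break <- !complete & stats::runif(n_trials) < 0.5

    t0 <- 2  # lead-in before the first trial
    t_fix <- t_cue_on <- t_cue_off <- t_mem_end <- t_move <- t_rew <-
      numeric(n_trials)
    cursor <- t0
    for (i in seq_len(n_trials)) {
      t_fix[i] <- cursor
      t_cue_on[i] <- t_fix[i] + fix_d[i]
      t_cue_off[i] <- t_cue_on[i] + task$cue_s
      t_mem_end[i] <- t_cue_off[i] + mem_d[i]
      t_move[i] <- t_mem_end[i]
      t_rew[i] <- t_move[i] + hold_d[i]
      cursor <- t_rew[i] + iti_d[i]
    }
    dt <- 1 / task$frame_rate_hz
    t_end <- cursor + 10  # capture the final hemodynamic tail
    timestamps <- seq(0, t_end, by = dt)
    n_frames <- length(timestamps)
    if (n_frames < 4) stop("frame budget too short for the trial schedule")

    # per-patch response time course at frame resolution
    H <- phantom$dims[1]; W <- phantom$dims[2]
    V <- H * W
    cue_angle <- direction_angle(cues)
    resp <- lapply(phantom$patches, function(p) {
      stim <- numeric(n_frames)
      gains <- von_mises_tuning(cue_angle, p$preferred_deg, p$kappa)
      for (i in seq_len(n_trials)) {
        on <- timestamps >= t_cue_on[i] & timestamps < t_mem_end[i]
        stim[on] <- stim[on] + gains[i]
      }
      h <- hrf_kernel(p$hrf$peak_s, p$hrf$fwhm_s, p$hrf$delay_s, dt = dt)
      conv <- stats::convolve(stim, rev(h), type = "open")[seq_len(n_frames)]
      p$amplitude * conv
    })

    gain_drift <- cumprod(exp(stats::rnorm(n_frames, 0, phantom$drift_sd)))
    gain <- gain_drift * (1 + phantom$pulsatility_amp *
                            sin(2 * pi * 0.3 * timestamps))

    frames <- array(0, dim = c(H, W, n_frames))
    anat_v <- as.vector(phantom$anatomy)
    for (t in seq_len(n_frames)) {
      mod <- rep(1, V)
      for (k in seq_along(phantom$patches)) {
        m <- phantom$patches[[k]]$mask
        mod[m] <- mod[m] + resp[[k]][t]
      }
      px <- anat_v * mod
      if (phantom$noise_sd > 0) {
        px <- px * (1 + stats::rnorm(V, 0, phantom$noise_sd))
      }
      frames[, , t] <- px * gain[t]
    }

    valid <- !early_break
    success <- complete
    trials <- tibble::tibble(
      trial = seq_len(n_trials), task = task_name, cued_direction = cues,
      t_fixation = t_fix, t_cue_on = t_cue_on, t_cue_off = t_cue_off,
      t_memory_end = t_mem_end, t_movement = t_move, t_reward = t_rew,
      valid = valid, success = success, prediction = NA_character_)
    gt <- list(
      patches = lapply(phantom$patches, function(p)
        list(mask = p$mask, preferred_deg = p$preferred_deg,
             kappa = p$kappa, amplitude = p$amplitude)))
    fus_session(frames, timestamps, trials, anatomy = phantom$anatomy,
                meta = list(n_targets = task$n_targets,
                            eccentricity_deg = task$eccentricity_deg,
                            voxel_size_mm = phantom$voxel_size_mm,
                            frame_period_s = dt, seed = seed,
                            provenance = "synthetic", ground_truth = gt))
  })
}
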