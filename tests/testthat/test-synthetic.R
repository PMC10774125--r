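test_that("phantoms are deterministic, positive, and honor patch areas", {
  p1 <- make_phantom(dims = c(48, 60), seed = 7)
  p2 <- make_phantom(dims = c(48, 60), seed = 7)
  expect_identical(p1$anatomy, p2$anatomy)
  expect_true(all(p1$anatomy > 0))
  expect_length(p1$patches, 2)
  p3 <- make_phantom(dims = c(48, 60), seed = 7, patches = list(
    list(center = c(24, 30), area = 200, preferred_deg = 0)))
  expect_length(p3$patches[[1]]$mask, 200)
  expect_error(make_phantom(dims = c(48, 60), patches = list(
    list(center = c(2, 2), area = 200, preferred_deg = 0))),
    "does not fit")
})

test_that("von Mises tuning has unit peak and the closed-form trough", {
  expect_equal(von_mises_tuning(90, 90, 2), 1)
  expect_equal(von_mises_tuning(270, 90, 2), exp(-2 * 2))
  expect_equal(von_mises_tuning(0, 180, 5), exp(-10))
  # monotone in cos(angular distance)
  d <- seq(0, 180, by = 45)
  expect_true(all(diff(von_mises_tuning(d, 0, 2)) < 0))
})

test_that("cue sequences are balanced and sessions are bit-deterministic", {
  ph <- test_phantom(dims = c(16, 20))
  s1 <- generate_session(ph, task_config(n_targets = 8), 16, seed = 3)
  s2 <- generate_session(ph, task_config(n_targets = 8), 16, seed = 3)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$trials, s2$trials)
  expect_true(all(table(s1$trials$cued_direction) == 2))
  s3 <- generate_session(ph, task_config(n_targets = 2), 13, seed = 3)
  counts <- table(factor(s3$trials$cued_direction, c("L", "R")))
  expect_setequal(as.integer(counts), c(6, 7))
})

test_that("trial phase times follow the task schedule with stated jitter", {
  s <- test_session(n_trials = 20, n_targets = 8, seed = 9)
  tr <- s$trials
  fix_d <- tr$t_cue_on - tr$t_fixation
  expect_true(all(fix_d >= 4 & fix_d <= 6))
  expect_equal(tr$t_cue_off - tr$t_cue_on, rep(0.4, 20))
  mem_d <- tr$t_memory_end - tr$t_cue_off
  expect_true(all(mem_d >= 4 & mem_d <= 6))
  hold_d <- tr$t_reward - tr$t_movement
  expect_true(all(hold_d >= 1 & hold_d <= 2))
  iti <- tr$t_fixation[-1] - tr$t_reward[-20]
  expect_true(all(iti >= 6 & iti <= 10))
})

test_that("noiseless patch response matches the HRF-convolved boxcar oracle", {
  # single sharply tuned patch, no noise/drift/pulsatility: the preferred
  # cue's memory-period response approaches amplitude x (boxcar * hrf),
  # the anti-preferred response is ~ exp(-2*kappa) ~ 0
  amp <- 0.10
  ph <- make_phantom(dims = c(24, 30), noise_sd = 0, drift_sd = 0,
                     pulsatility_amp = 0, n_vessels = 4, seed = 2,
                     patches = list(list(center = c(12, 15), area = 50,
                                         preferred_deg = 180, kappa = 25,
                                         amplitude = amp)))
  s <- generate_session(ph, task_config(n_targets = 2), 10, seed = 4)
  mask <- ph$patches[[1]]$mask
  anat <- as.vector(ph$anatomy)[mask]
  rel <- function(i) {  # fractional CBV change of the patch, last 3 memory frames
    idx <- utils::tail(which(s$timestamps <= s$trials$t_memory_end[i]), 3)
    sapply(idx, function(t) mean(as.vector(s$frames[, , t])[mask] / anat)) - 1
  }
  pref <- sapply(which(s$trials$cued_direction == "L"), rel)
  anti <- sapply(which(s$trials$cued_direction == "R"), rel)
  # independent oracle: discrete convolution of a 5.4 s boxcar with a
  # unit-area gamma kernel peaking at 1.5 s reaches >= 0.8 of its asymptote
  # by the end of the memory period
  expect_gt(min(pref), 0.8 * amp)
  expect_lt(max(pref), 1.02 * amp)
  expect_lt(max(abs(anti)), 0.02 * amp)
})

test_that("memory-period response is monotone in cos(cue - preferred)", {
  ph <- make_phantom(dims = c(24, 30), noise_sd = 0, drift_sd = 0,
                     pulsatility_amp = 0, n_vessels = 4, seed = 2,
                     patches = list(list(center = c(12, 15), area = 50,
                                         preferred_deg = 90, kappa = 2,
                                         amplitude = 0.10)))
  s <- generate_session(ph, task_config(n_targets = 8), 16, seed = 5)
  mask <- ph$patches[[1]]$mask
  anat <- as.vector(ph$anatomy)[mask]
  resp <- sapply(seq_len(16), function(i) {
    idx <- utils::tail(which(s$timestamps <= s$trials$t_memory_end[i]), 3)
    mean(sapply(idx, function(t)
      mean(as.vector(s$frames[, , t])[mask] / anat))) - 1
  })
  by_dir <- tapply(resp, s$trials$cued_direction, mean)
  cosd <- round(cos((direction_angle(names(by_dir)) - 90) * pi / 180), 6)
  by_cos <- tapply(by_dir, cosd, mean)  # pool directions with equal cos
  expect_true(all(diff(by_cos[order(as.numeric(names(by_cos)))]) > 0))
})

test_that("rigid perturbation is recovered by a phase-correlation oracle", {
  ph <- quiet_phantom(dims = c(48, 60))
  ph2 <- perturb_for_next_session(ph, rotate_deg = 0, shift_px = c(3, -4))
  tr <- attr(ph2, "true_transform")
  expect_equal(c(tr$tx_px, tr$ty_px), c(3, -4))
  # FFT cross-correlation peak of the two anatomies sits at the true shift
  a <- ph$anatomy - mean(ph$anatomy)
  b <- ph2$anatomy - mean(ph2$anatomy)
  xc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  pk <- which(xc == max(xc), arr.ind = TRUE)[1, ]
  H <- nrow(a); W <- ncol(a)
  dy <- ((pk[1] - 1 + H / 2) %% H) - H / 2
  dx <- ((pk[2] - 1 + W / 2) %% W) - W / 2
  expect_equal(unname(c(dx, dy)), c(-3, 4))  # moving-to-fixed displacement
})

test_that("identity perturbation and rotation round trips preserve the phantom", {
  ph <- quiet_phantom(dims = c(48, 60))
  same <- perturb_for_next_session(ph, 0, c(0, 0), gain = 1)
  expect_equal(same$anatomy, ph$anatomy)
  expect_equal(same$patches[[1]]$mask, ph$patches[[1]]$mask)
  rot <- perturb_for_next_session(ph, 2, c(0, 0))
  back <- perturb_for_next_session(rot, -2, c(0, 0))
  interior <- 6:(48 - 5)
  err <- abs(back$anatomy[interior, 6:55] - ph$anatomy[interior, 6:55])
  expect_lt(mean(err), 0.02 * diff(range(ph$anatomy)))
  expect_error(perturb_for_next_session(ph, 11, c(0, 0)), "<= 10")
  expect_error(perturb_for_next_session(ph, 0, c(21, 0)), "<= 20")
  big <- perturb_for_next_session  # patch pushed off-grid errors
  expect_error(big(ph, 0, c(-20, 0)), "off the grid")
})

test_that("SVD clutter filter removes static rank-1 clutter", {
  set.seed(8)
  img <- matrix(runif(30 * 20, 1, 3), 30, 20)
  ens <- array(rep(img, 10), dim = c(30, 20, 10))
  pw <- svd_clutter_filter(ens, 0.3)
  expect_lt(max(pw), 1e-20)
  expect_error(svd_clutter_filter(ens[, , 1:3], 0.3), "at least 4")
  expect_error(svd_clutter_filter(ens, 1), "discard_fraction")
})

test_that("a 30% discard on a 200-frame ensemble drops exactly 60 components", {
  # rank bookkeeping: with 60 of 200 components removed, an ensemble of
  # exactly 61 orthogonal slow-time components retains only the weakest one
  set.seed(9)
  V <- 80; N <- 200
  U <- qr.Q(qr(matrix(rnorm(V * 61), V, 61)))
  B <- qr.Q(qr(matrix(rnorm(N * 61), N, 61)))
  d <- seq(100, 40, length.out = 61)
  ens <- U %*% (d * t(B))
  pw <- svd_clutter_filter(ens, 0.3)
  # residual energy equals the weakest component's energy: 60 are discarded
  expect_equal(sum(pw) * N, d[61]^2, tolerance = 1e-6)
})

test_that("clutter-filtered power localizes a fluctuating voxel", {
  # three strong tissue-motion components (discarded, floor(0.3*12) = 3)
  # plus a weak white fluctuation confined to one voxel (retained)
  set.seed(10)
  V <- 25 * 16; N <- 12
  tissue_maps <- matrix(runif(V * 3, 1, 3), V, 3)
  tissue_t <- rbind(rep(1, N), sin(2 * pi * (1:N) / N),
                    cos(2 * pi * (1:N) / N))
  ens <- tissue_maps %*% (c(200, 60, 50) * tissue_t)
  vox <- (9 - 1) * 25 + 7  # voxel (7, 9)
  ens[vox, ] <- ens[vox, ] + rnorm(N, 0, 0.5)
  pw <- svd_clutter_filter(array(ens, dim = c(25, 16, N)), 0.3)
  expect_equal(unname(which(pw == max(pw), arr.ind = TRUE)[1, ]), c(7, 9))
  expect_gt(max(pw), 100 * stats::median(pw))
})
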