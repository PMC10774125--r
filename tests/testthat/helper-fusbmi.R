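# Shared fixtures: small phantoms and sessions built in code so tests run
# on reduced grids while keeping the generator's default noise, tuning and
# task-timing conditions.

test_phantom <- function(dims = c(32, 40), seed = 11,
                         area = max(12, round(0.05 * prod(dims))),
                         amplitude = 0.10, kappa = 2, noise_sd = 0.02,
                         drift_sd = 0.002, pulsatility_amp = 0.01,
                         preferred = c(180, 90)) {
  patches <- list(
    list(center = round(c(0.35 * dims[1], 0.30 * dims[2])), area = area,
         preferred_deg = preferred[1], kappa = kappa, amplitude = amplitude),
    list(center = round(c(0.60 * dims[1], 0.65 * dims[2])), area = area,
         preferred_deg = preferred[2], kappa = kappa, amplitude = amplitude)
  )
  make_phantom(dims = dims, patches = patches, noise_sd = noise_sd,
               drift_sd = drift_sd, pulsatility_amp = pulsatility_amp,
               n_vessels = 6, seed = seed)
}

quiet_phantom <- function(...) {
  test_phantom(noise_sd = 0, drift_sd = 0, pulsatility_amp = 0, ...)
}

test_session <- function(n_trials = 12, n_targets = 2, seed = 21,
                         phantom = test_phantom(), ...) {
  generate_session(phantom, task_config(n_targets = n_targets, ...),
                   n_trials = n_trials, seed = seed)
}

# two well-separated Gaussian classes in D dimensions (decoder fixtures)
gaussian_two_class <- function(n_per_class = 100, D = 300, sep = 6,
                               seed = 5) {
  set.seed(seed)
  mu <- rnorm(D); mu <- mu / sqrt(sum(mu^2)) * sep / 2
  x <- rbind(matrix(rnorm(n_per_class * D), n_per_class, D) +
               rep(mu, each = n_per_class),
             matrix(rnorm(n_per_class * D), n_per_class, D) -
               rep(mu, each = n_per_class))
  list(x = x, labels = rep(c("R", "L"), each = n_per_class))
}

# simple stratified CV accuracy used as an independent evaluation harness
cv_accuracy <- function(x, labels, fit_fun, folds = 10, seed = 3) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  correct <- 0
  for (f in seq_len(folds)) {
    te <- fold == f
    m <- fit_fun(x[!te, , drop = FALSE], labels[!te])
    pred <- predict(m, x[te, , drop = FALSE])$prediction
    correct <- correct + sum(pred == labels[te])
  }
  correct / length(labels)
}
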