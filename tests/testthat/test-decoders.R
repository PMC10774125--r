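test_that("cPCA+LDA separates well-separated clouds and not null data", {
  d <- gaussian_two_class(n_per_class = 100, D = 300, sep = 6)
  acc <- cv_accuracy(d$x, d$labels, fit_cpca_lda)
  expect_gte(acc, 0.95)
  # same distribution for both classes: accuracy ~ 0.5 within binomial noise
  set.seed(6)
  x0 <- matrix(rnorm(200 * 120), 200, 120)
  acc0 <- cv_accuracy(x0, rep(c("R", "L"), each = 100), fit_cpca_lda)
  expect_lt(abs(acc0 - 0.5), 3 * sqrt(0.25 / 200) + 0.05)
})

test_that("the 95% rule keeps one component for a (100,1,1,...) spectrum", {
  # per class, variance concentrated on one axis: eigenvalue bookkeeping
  # must retain exactly 1 component per class at the 95% target
  set.seed(7)
  n <- 40; D <- 30
  make_cloud <- function(mu) {
    z <- cbind(rnorm(n, 0, 10), matrix(rnorm(n * (D - 1), 0, 0.1),
                                       n, D - 1))
    sweep(z, 2, mu, `+`)
  }
  x <- rbind(make_cloud(rep(0, D)), make_cloud(rep(3, D)))
  m <- fit_cpca_lda(x, rep(c("R", "L"), each = n))
  expect_equal(unname(m$n_components), c(1, 1))
  expect_true(all(m$var_retained >= 0.95))
})

test_that("decoders validate class counts and dimensions", {
  set.seed(8)
  x <- matrix(rnorm(40), 10, 4)
  expect_error(fit_cpca_lda(x, c("R", rep("L", 9))), ">= 2 training samples")
  expect_error(fit_cpca_lda(x, rep("R", 10)), "2 classes")
  m <- fit_cpca_lda(x, rep(c("R", "L"), 5))
  expect_error(predict(m, matrix(0, 1, 5)), "dimension")
})

test_that("3-class PCA+LDA separates collinear clusters, dimension bounded", {
  set.seed(9)
  n <- 30; D <- 60
  dirvec <- rnorm(D); dirvec <- dirvec / sqrt(sum(dirvec^2))
  x <- do.call(rbind, lapply(c(-6, 0, 6), function(s)
    matrix(rnorm(n * D), n, D) + s * rep(dirvec, each = n)))
  labels <- rep(c("DOWN", "MID", "UP"), each = n)
  fit3 <- function(x, l) fit_pca_lda_3class(x, l, "vertical")
  acc <- cv_accuracy(x, labels, fit3, folds = 5)
  expect_gte(acc, 0.95)
  m <- fit_pca_lda_3class(x, labels, "vertical")
  expect_lte(m$n_components, min(nrow(x) - 1, D))
  expect_gte(m$var_retained, 0.95)
  # shuffled labels: near 1/3
  set.seed(10)
  acc0 <- cv_accuracy(x, sample(labels), fit3, folds = 5)
  expect_lt(abs(acc0 - 1 / 3), 0.15)
  expect_error(fit_pca_lda_3class(x[1:60, ], labels[1:60], "vertical"),
               ">= 2 samples")
})

test_that("a balanced 8-direction set gives 3/2/3 counts per axis class", {
  labels <- rep(peripheral_directions(), 2)
  comp <- decompose_direction(labels)
  expect_equal(as.vector(table(factor(comp$vertical,
                                      c("UP", "MID", "DOWN")))),
               c(6, 4, 6))
  expect_equal(as.vector(table(factor(comp$horizontal,
                                      c("LEFT", "MID", "RIGHT")))),
               c(6, 4, 6))
})

test_that("multicoder equals its component argmaxes combined", {
  set.seed(11)
  sf <- session_features(test_session(n_trials = 24, n_targets = 8,
                                      seed = 31))
  s <- test_session(n_trials = 24, n_targets = 8, seed = 31)
  m <- fit_multicoder(sf$features, s$trials$cued_direction)
  x_new <- sf$features + matrix(rnorm(length(sf$features), 0, 0.1),
                                nrow(sf$features))
  pred <- predict(m, x_new)
  pv <- predict(m$vertical, x_new)$prediction
  ph <- predict(m$horizontal, x_new)$prediction
  expect_equal(pred$prediction, combine_components(pv, ph))
  expect_equal(pred$vertical, pv)
  expect_equal(pred$horizontal, ph)
})

test_that("multicoder decodes a noiseless sharply tuned synthetic session", {
  ph <- quiet_phantom(kappa = 8)
  s <- generate_session(ph, task_config(n_targets = 8), 32, seed = 41)
  sf <- session_features(s)
  labels <- s$trials$cued_direction
  tr <- 1:24; te <- 25:32
  m <- fit_multicoder(sf$features[tr, ], labels[tr])
  pred <- predict(m, sf$features[te, ])$prediction
  expect_gt(mean(pred == labels[te]), 1 / 8)
  expect_lt(mean(angular_error(labels[te], pred)), 90)
})

test_that("component predictions (MID, MID) yield CENTER", {
  expect_equal(combine_components("MID", "MID"), "CENTER")
  # and a decoder can emit it: force degenerate horizontal/vertical MIDs
  set.seed(12)
  n <- 4
  x <- rbind(matrix(rnorm(n * 20, 5), n, 20), matrix(rnorm(n * 20, -5), n, 20),
             matrix(rnorm(n * 20, 0, 0.1), 2 * n, 20))
  labels <- c(rep("U", n), rep("D", n), rep(c("L", "R"), n))
  m <- fit_multicoder(x, labels)
  pred <- predict(m, matrix(0, 1, 20))$prediction
  expect_true(pred %in% c(peripheral_directions(), "CENTER"))
})

test_that("fitted decoders serialize to JSON and reload to identical predictions", {
  d <- gaussian_two_class(n_per_class = 20, D = 50, sep = 4)
  m <- fit_cpca_lda(d$x, d$labels)
  f <- withr::local_tempfile(fileext = ".json")
  write_decoder(m, f)
  m2 <- read_decoder(f)
  probe <- matrix(rnorm(30 * 50), 30, 50)
  expect_identical(predict(m, probe)$prediction, predict(m2, probe)$prediction)
  expect_equal(predict(m, probe), predict(m2, probe), tolerance = 1e-10)

  s <- test_session(n_trials = 24, n_targets = 8, seed = 31)
  sf <- session_features(s)
  mm <- fit_multicoder(sf$features, s$trials$cued_direction)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_decoder(mm, f2)
  mm2 <- read_decoder(f2)
  expect_identical(predict(mm, sf$features), predict(mm2, sf$features))
})

test_that("tidy and glance summarize fitted decoders", {
  d <- gaussian_two_class(n_per_class = 15, D = 40, sep = 4)
  m <- fit_cpca_lda(d$x, d$labels)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$class, c("R", "L"))
  gl <- glance(m)
  expect_equal(gl$n_train, 30)
  expect_gte(gl$var_retained, 0.95)

  s <- test_session(n_trials = 24, n_targets = 8, seed = 31)
  sf <- session_features(s)
  mm <- fit_multicoder(sf$features, s$trials$cued_direction)
  expect_setequal(tidy(mm)$component, c("vertical", "horizontal"))
  expect_equal(glance(mm)$kind, "multicoder")
})

test_that("cPCA+LDA agrees with MASS::lda on a low-dimensional problem", {
  # independent cross-check: when D << n and no reduction is needed, the
  # shrinkage-LDA decision should track classical LDA closely
  set.seed(13)
  n <- 200; D <- 5
  x <- rbind(matrix(rnorm(n * D), n, D) + 1.5,
             matrix(rnorm(n * D), n, D) - 1.5)
  labels <- rep(c("R", "L"), each = n)
  m <- fit_cpca_lda(x, labels, shrinkage = 0.01)
  ref <- MASS::lda(x, grouping = labels)
  probe <- matrix(rnorm(200 * D), 200, D)
  agree <- mean(predict(m, probe)$prediction ==
                  as.character(predict(ref, probe)$class))
  expect_gte(agree, 0.97)
})
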