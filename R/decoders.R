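# Linear movement-intention decoders. Two-class decoding uses class-wise
# PCA (a per-class subspace at 95% within-class variance, union
# orthonormalized) followed by LDA on the projections; eight-direction
# decoding uses a "multicoder": two independent pooled-PCA + 3-class LDA
# models for the vertical (UP/MID/DOWN) and horizontal (LEFT/MID/RIGHT)
# movement components, combined into one of the eight peripheral directions
# (or CENTER when both components vote MID). LDA uses a small fixed
# shrinkage of the pooled covariance toward its diagonal because the number
# of training trials is far below the feature dimension early in training.

# subtract a per-column offset without sweep()'s aperm overhead
center_rows <- function(x, center) {
  x - rep(center, each = nrow(x))
}

canonical_class_order <- function(classes) {
  orders <- list(.DIRECTIONS, .VERTICAL_LEVELS, .HORIZONTAL_LEVELS)
  for (ord in orders) {
    if (all(classes %in% ord)) return(intersect(ord, classes))
  }
  sort(classes)
}

# Leading principal axes capturing >= var_target of total variance of the
# (already centred) sample matrix; zero directions are never retained.
# For n << D the spectrum comes from the n x n Gram matrix (same subspace,
# much cheaper than a direct SVD of the n x D matrix).
pca_basis_centered <- function(Xc, var_target) {
  n <- nrow(Xc); D <- ncol(Xc)
  if (D > 2 * n) {
    ev <- eigen(tcrossprod(Xc), symmetric = TRUE)
    eig <- pmax(ev$values, 0)
    d <- sqrt(eig)
    tot <- sum(eig)
    if (tot <= 0) stop("training samples have no variance")
    m <- which(cumsum(eig) >= var_target * tot - 1e-12)[1]
    m <- min(m, sum(d > max(d[1] * 1e-12, 0)))
    keep <- seq_len(m)
    basis <- crossprod(Xc, ev$vectors[, keep, drop = FALSE]) /
      rep(d[keep], each = D)
  } else {
    sv <- svd(Xc, nu = 0)
    eig <- sv$d^2
    tot <- sum(eig)
    if (tot <= 0) stop("training samples have no variance")
    m <- which(cumsum(eig) >= var_target * tot - 1e-12)[1]
    m <- min(m, sum(sv$d > max(sv$d[1] * 1e-12, 0)))
    basis <- sv$v[, seq_len(m), drop = FALSE]
  }
  list(basis = basis,
       var_retained = sum(eig[seq_len(m)]) / tot, eig = eig, m = m)
}

lda_fit <- function(Z, y, levels, shrinkage) {
  K <- length(levels)
  m <- ncol(Z)
  n <- nrow(Z)
  M <- matrix(0, K, m)
  priors <- numeric(K)
  Sw <- matrix(0, m, m)
  for (k in seq_len(K)) {
    rows <- y == levels[k]
    priors[k] <- mean(rows)
    Zk <- Z[rows, , drop = FALSE]
    M[k, ] <- colMeans(Zk)
    Zc <- center_rows(Zk, M[k, ])
    Sw <- Sw + crossprod(Zc)
  }
  Sw <- Sw / (n - K)
  S <- (1 - shrinkage) * Sw + shrinkage * diag(diag(Sw), m)
  dg <- diag(S)
  eps <- 1e-8 * max(mean(dg), 1e-12)
  diag(S) <- dg + eps
  W <- solve(S, t(M))                      # m x K
  const <- -0.5 * colSums(t(M) * W) + log(priors)
  list(W = W, const = const, levels = levels, priors = priors,
       means = M, shrinkage = shrinkage)
}

lda_scores <- function(lda, Z) {
  Z %*% lda$W + rep(lda$const, each = nrow(Z))
}

lda_predict <- function(lda, Z) {
  sc <- lda_scores(lda, Z)
  lda$levels[max.col(sc, ties.method = "first")]
}

#' Fit the two-class cPCA + LDA decoder
#'
#' Class-wise PCA: each class's samples are reduced to the principal axes
#' retaining 95% of that class's variance; features are projected onto the
#' orthonormalized union of the two class bases; LDA (with shrinkage of the
#' pooled covariance toward its diagonal) is fit on the projections.
#'
#' @param x numeric matrix, trials x features.
#' @param labels character vector of two direction labels.
#' @param var_target retained-variance target per class (default 0.95).
#' @param shrinkage LDA covariance shrinkage coefficient (default 0.1).
#' @return A fitted decoder of class `fus_decoder` (kind `"cpca_lda"`).
#' @export
fit_cpca_lda <- function(x, labels, var_target = 0.95, shrinkage = 0.1) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  classes <- canonical_class_order(unique(labels))
  if (length(classes) != 2) stop("cPCA + LDA decoder requires exactly 2 classes")
  counts <- table(factor(labels, classes))
  if (any(counts < 2)) {
    stop("each class needs >= 2 training samples (got ",
         paste(counts, collapse = ", "), ")")
  }
  center <- colMeans(x)
  per_class <- lapply(classes, function(cl) {
    Xk <- x[labels == cl, , drop = FALSE]
    pca_basis_centered(center_rows(Xk, colMeans(Xk)), var_target)
  })
  B <- do.call(cbind, lapply(per_class, `[[`, "basis"))
  qb <- qr(B, LAPACK = TRUE)
  rank <- sum(abs(diag(qr.R(qb))) > 1e-10)
  Q <- qr.Q(qb)[, seq_len(rank), drop = FALSE]
  Z <- center_rows(x, center) %*% Q
  lda <- lda_fit(Z, labels, classes, shrinkage)
  structure(list(kind = "cpca_lda", center = center, basis = Q, lda = lda,
                 classes = classes, var_target = var_target,
                 var_retained = vapply(per_class, `[[`, 0, "var_retained"),
                 n_components = vapply(per_class, `[[`, 0L, "m"),
                 n_train = nrow(x)),
            class = "fus_decoder")
}

#' Fit a pooled PCA + LDA three-class component model
#'
#' Single PCA over all samples retaining 95% of total variance, then
#' three-class LDA. Used for one axis (vertical or horizontal) of the
#' eight-direction multicoder.
#'
#' @param x trials x features matrix.
#' @param labels component labels: all of {UP, MID, DOWN} (vertical) or
#'   {LEFT, MID, RIGHT} (horizontal) must be present with >= 2 samples.
#' @param axis `"vertical"` or `"horizontal"`.
#' @inheritParams fit_cpca_lda
#' @return A fitted `fus_decoder` (kind `"pca_lda"`).
#' @export
fit_pca_lda_3class <- function(x, labels, axis = c("vertical", "horizontal"),
                               var_target = 0.95, shrinkage = 0.1) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  levels <- if (axis == "vertical") .VERTICAL_LEVELS else .HORIZONTAL_LEVELS
  counts <- table(factor(labels, levels))
  if (any(counts < 2)) {
    stop(axis, " component model needs >= 2 samples of each of {",
         paste(levels, collapse = ", "), "}")
  }
  center <- colMeans(x)
  pca <- pca_basis_centered(center_rows(x, center), var_target)
  Z <- center_rows(x, center) %*% pca$basis
  lda <- lda_fit(Z, labels, levels, shrinkage)
  structure(list(kind = "pca_lda", axis = axis, center = center,
                 basis = pca$basis, lda = lda, classes = levels,
                 var_target = var_target, var_retained = pca$var_retained,
                 n_components = pca$m, n_train = nrow(x)),
            class = "fus_decoder")
}

#' Fit the eight-direction multicoder
#'
#' Decomposes each trial's cued direction into its vertical and horizontal
#' components and fits the two three-class component models on the same
#' feature vectors. Predictions recombine the independent component
#' argmaxes via [combine_components()] (CENTER is possible).
#'
#' @param x trials x features matrix.
#' @param labels peripheral direction labels.
#' @inheritParams fit_cpca_lda
#' @return A fitted `fus_decoder` (kind `"multicoder"`).
#' @export
fit_multicoder <- function(x, labels, var_target = 0.95, shrinkage = 0.1) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  comp <- decompose_direction(labels)
  structure(list(
    kind = "multicoder",
    vertical = fit_pca_lda_3class(x, comp$vertical, "vertical",
                                  var_target, shrinkage),
    horizontal = fit_pca_lda_3class(x, comp$horizontal, "horizontal",
                                    var_target, shrinkage),
    n_train = nrow(x)),
    class = "fus_decoder")
}

#' Fit the task-appropriate decoder
#'
#' Dispatches on the number of distinct cue directions: two classes use
#' cPCA + LDA, eight use the multicoder.
#'
#' @inheritParams fit_cpca_lda
#' @param n_targets 2 or 8.
#' @return A fitted `fus_decoder`.
#' @export
fit_decoder <- function(x, labels, n_targets, var_target = 0.95,
                        shrinkage = 0.1) {
  if (n_targets == 2) fit_cpca_lda(x, labels, var_target, shrinkage)
  else fit_multicoder(x, labels, var_target, shrinkage)
}

check_feature_dim <- function(model, x) {
  if (model$kind != "multicoder" && ncol(x) != length(model$center)) {
    stop("feature dimension ", ncol(x), " does not match the model's ",
         length(model$center))
  }
}

# label-only prediction on a feature matrix (lean path for hot loops)
decoder_predict_labels <- function(model, x) {
  if (model$kind == "multicoder") {
    v <- decoder_predict_labels(model$vertical, x)
    h <- decoder_predict_labels(model$horizontal, x)
    return(combine_components(v, h))
  }
  check_feature_dim(model, x)
  Z <- center_rows(x, model$center) %*% model$basis
  lda_predict(model$lda, Z)
}

#' Predict movement directions from feature vectors
#'
#' @param object a fitted `fus_decoder`.
#' @param newdata feature matrix (trials x features) or a single feature
#'   vector.
#' @param ... unused.
#' @return A tibble with column `prediction` (direction label, possibly
#'   CENTER for the multicoder) plus per-class discriminant scores; the
#'   multicoder also reports the `vertical` and `horizontal` component
#'   predictions.
#' @export
predict.fus_decoder <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (object$kind == "multicoder") {
    pv <- predict(object$vertical, newdata)
    ph <- predict(object$horizontal, newdata)
    return(tibble::tibble(
      prediction = combine_components(pv$prediction, ph$prediction),
      vertical = pv$prediction, horizontal = ph$prediction))
  }
  check_feature_dim(object, newdata)
  Z <- center_rows(newdata, object$center) %*% object$basis
  sc <- lda_scores(object$lda, Z)
  out <- tibble::tibble(
    prediction = object$lda$levels[max.col(sc, ties.method = "first")])
  colnames(sc) <- paste0("score_", object$lda$levels)
  dplyr::bind_cols(out, tibble::as_tibble(sc))
}

#' @export
print.fus_decoder <- function(x, ...) {
  if (x$kind == "multicoder") {
    cat("<fus_decoder> multicoder (vertical + horizontal PCA+LDA), n_train = ",
        x$n_train, "\n", sep = "")
  } else {
    cat("<fus_decoder> ", x$kind, ", classes {",
        paste(x$classes, collapse = ", "), "}, ", sum(x$n_components),
        " components, n_train = ", x$n_train, "\n", sep = "")
  }
  invisible(x)
}

#' Broom-style summaries of fitted decoders
#'
#' `tidy()` returns one row per class of each component model (prior,
#' training count); `glance()` returns one row of model-level facts
#' (kind, training size, retained components/variance).
#'
#' @param x a fitted `fus_decoder`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy fus_decoder
#' @export
tidy.fus_decoder <- function(x, ...) {
  if (x$kind == "multicoder") {
    return(dplyr::bind_rows(
      dplyr::mutate(tidy(x$vertical), component = "vertical", .before = 1),
      dplyr::mutate(tidy(x$horizontal), component = "horizontal",
                    .before = 1)))
  }
  tibble::tibble(class = x$lda$levels, prior = x$lda$priors,
                 n_components = sum(x$n_components))
}

#' @rdname tidy.fus_decoder
#' @method glance fus_decoder
#' @export
glance.fus_decoder <- function(x, ...) {
  if (x$kind == "multicoder") {
    return(tibble::tibble(
      kind = "multicoder", n_train = x$n_train,
      n_components_vertical = x$vertical$n_components,
      n_components_horizontal = x$horizontal$n_components,
      var_retained_vertical = x$vertical$var_retained,
      var_retained_horizontal = x$horizontal$var_retained))
  }
  tibble::tibble(kind = x$kind, n_train = x$n_train,
                 n_components = sum(x$n_components),
                 var_retained = mean(x$var_retained))
}

#' Save and load fitted decoders
#'
#' Models are stored as a JSON file (bases, LDA weights, class labels,
#' configuration and training provenance) at full floating-point precision;
#' a reloaded model makes identical predictions.
#'
#' @param model a fitted `fus_decoder`.
#' @param path file path (`.json`).
#' @return `read_decoder()` returns the `fus_decoder`.
#' @export
write_decoder <- function(model, path) {
  ser <- function(m) {
    if (m$kind == "multicoder") {
      return(list(kind = "multicoder", n_train = m$n_train,
                  vertical = ser(m$vertical), horizontal = ser(m$horizontal)))
    }
    list(kind = m$kind, axis = m$axis %||% NULL, center = m$center,
         basis = list(data = as.vector(m$basis), dim = dim(m$basis)),
         lda = list(W = list(data = as.vector(m$lda$W), dim = dim(m$lda$W)),
                    const = m$lda$const, levels = m$lda$levels,
                    priors = m$lda$priors,
                    means = list(data = as.vector(m$lda$means),
                                 dim = dim(m$lda$means)),
                    shrinkage = m$lda$shrinkage),
         classes = m$classes, var_target = m$var_target,
         var_retained = m$var_retained, n_components = m$n_components,
         n_train = m$n_train)
  }
  jsonlite::write_json(ser(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decoder
#' @export
read_decoder <- function(path) {
  de <- function(j) {
    if (j$kind == "multicoder") {
      return(structure(list(kind = "multicoder",
                            vertical = de(j$vertical),
                            horizontal = de(j$horizontal),
                            n_train = j$n_train),
                       class = "fus_decoder"))
    }
    m <- list(kind = j$kind, center = as.numeric(j$center),
              basis = matrix(as.numeric(j$basis$data), j$basis$dim[1],
                             j$basis$dim[2]),
              lda = list(W = matrix(as.numeric(j$lda$W$data), j$lda$W$dim[1],
                                    j$lda$W$dim[2]),
                         const = as.numeric(j$lda$const),
                         levels = as.character(j$lda$levels),
                         priors = as.numeric(j$lda$priors),
                         means = matrix(as.numeric(j$lda$means$data),
                                        j$lda$means$dim[1], j$lda$means$dim[2]),
                         shrinkage = j$lda$shrinkage),
              classes = as.character(j$classes), var_target = j$var_target,
              var_retained = as.numeric(j$var_retained),
              n_components = as.integer(j$n_components), n_train = j$n_train)
    if (!is.null(j$axis)) m$axis <- j$axis
    structure(m, class = "fus_decoder")
  }
  de(jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
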