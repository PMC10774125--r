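# Cross-session rigid alignment: intensity-based registration of a
# previous session's anatomy to the current session's anatomy, minimizing
# the mean squared intensity difference with a regular-step gradient
# descent over (rotation, translation), on a multi-resolution pyramid for
# capture range. Rigid only: brain size does not change between sessions,
# so no scaling; rotation is about the image centre (any other pivot is
# absorbed by the translation).

mse_cost <- function(moving, fixed, transform, margin) {
  warped <- apply_transform(moving, transform)
  H <- nrow(fixed); W <- ncol(fixed)
  ys <- (1 + margin):(H - margin)
  xs <- (1 + margin):(W - margin)
  d <- warped[ys, xs] - fixed[ys, xs]
  mean(d * d)
}

# Regular-step gradient descent at one pyramid level: step along the
# normalized negative gradient; a step that fails to decrease the cost is
# rejected and the step length halved, guaranteeing monotone descent.
rsgd_level <- function(moving, fixed, p0, margin, step0, min_step,
                       max_iter, grad_delta) {
  cost_p <- function(p) mse_cost(moving, fixed,
                                 rigid_transform2d(p[1], p[2], p[3]), margin)
  p <- p0
  f <- cost_p(p)
  step <- step0
  for (it in seq_len(max_iter)) {
    g <- numeric(3)
    for (j in 1:3) {
      dp <- numeric(3); dp[j] <- grad_delta[j]
      g[j] <- (cost_p(p + dp) - cost_p(p - dp)) / (2 * grad_delta[j])
    }
    gn <- sqrt(sum((g * grad_delta)^2))
    if (gn == 0) break
    dir <- -(g * grad_delta^2) / gn   # descent direction in scaled space
    repeat {
      p_new <- p + step * dir
      f_new <- cost_p(p_new)
      if (f_new < f) {
        p <- p_new; f <- f_new
        break
      }
      step <- step / 2
      if (step < min_step) break
    }
    if (step < min_step) break
  }
  list(p = p, cost = f)
}

#' Rigid intensity-based registration of two anatomy images
#'
#' Finds the rigid transform (rotation about the image centre plus
#' translation) minimizing the mean squared intensity difference between
#' the transformed moving image and the fixed image, by regular-step
#' gradient descent from `init` over a multi-resolution pyramid. A border
#' margin is excluded from the metric so that out-of-view zeros do not
#' bias the fit.
#'
#' @param moving previous session's anatomy image (matrix).
#' @param fixed current session's anatomy image (same dims).
#' @param init starting [rigid_transform2d()] (e.g. a manual guess for
#'   large offsets).
#' @param levels pyramid levels (default 3: 4x, 2x, 1x downsampling).
#' @param max_iter iterations per level.
#' @param step0 initial step length (scaled parameter space, full
#'   resolution units).
#' @param min_step convergence threshold on the step length.
#' @param margin_frac border fraction excluded from the metric.
#' @return The fitted `rigid_transform2d` with attributes `final_mse`,
#'   `initial_mse` and `converged`.
#' @export
register_rigid <- function(moving, fixed, init = rigid_transform2d(),
                           levels = 3, max_iter = 60, step0 = 2,
                           min_step = 1e-3, margin_frac = 0.08) {
  stopifnot(is.matrix(moving), is.matrix(fixed),
            identical(dim(moving), dim(fixed)))
  if (!all(is.finite(moving)) || !all(is.finite(fixed))) {
    stop("images contain non-finite pixels")
  }
  margin0 <- round(margin_frac * min(dim(fixed)))
  mse0 <- mse_cost(moving, fixed, init, margin0)
  p <- c(init$theta_deg, init$tx_px, init$ty_px)
  factors <- rev(2^(seq_len(levels) - 1))
  for (f in factors) {
    mv <- if (f > 1) downsample2(moving, f) else moving
    fx <- if (f > 1) downsample2(fixed, f) else fixed
    p_lvl <- c(p[1], p[2] / f, p[3] / f)
    margin <- max(2, round(margin_frac * min(dim(fx))))
    res <- rsgd_level(mv, fx, p_lvl, margin,
                      step0 = step0 * 2 / f, min_step = min_step,
                      max_iter = max_iter,
                      grad_delta = c(0.2, 0.25, 0.25))
    p <- c(res$p[1], res$p[2] * f, res$p[3] * f)
  }
  out <- rigid_transform2d(p[1], p[2], p[3])
  final <- mse_cost(moving, fixed, out, margin0)
  if (final > mse0) {
    warning("registration did not improve on the initial transform; ",
            "returning the initial transform")
    out <- init
    final <- mse0
    attr(out, "converged") <- FALSE
  } else {
    attr(out, "converged") <- TRUE
  }
  attr(out, "initial_mse") <- mse0
  attr(out, "final_mse") <- final
  out
}

#' Manually nudge an alignment transform
#'
#' Programmatic stand-in for the interactive adjustment step: adds the
#' given increments to the transform parameters (so a nudge followed by
#' its negation restores the original exactly). Typically used to supply
#' `init` to [register_rigid()] when the automated alignment fails on a
#' large offset.
#'
#' @param transform a [rigid_transform2d()].
#' @param d_theta_deg,dx_px,dy_px parameter increments.
#' @return The adjusted `rigid_transform2d`.
#' @export
manual_adjust <- function(transform, d_theta_deg = 0, dx_px = 0, dy_px = 0) {
  stopifnot(inherits(transform, "rigid_transform2d"))
  rigid_transform2d(transform$theta_deg + d_theta_deg,
                    transform$tx_px + dx_px, transform$ty_px + dy_px)
}

#' Save and load alignment transforms
#'
#' JSON storage of `(theta_deg, tx_px, ty_px)` plus the registration MSE
#' when present.
#'
#' @param transform a `rigid_transform2d`.
#' @param path file path.
#' @return `read_transform()` returns the `rigid_transform2d`.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(theta_deg = transform$theta_deg,
                            tx_px = transform$tx_px,
                            ty_px = transform$ty_px,
                            final_mse = attr(transform, "final_mse")),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- rigid_transform2d(j$theta_deg, j$tx_px, j$ty_px)
  if (!is.null(j$final_mse)) attr(out, "final_mse") <- j$final_mse
  out
}
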