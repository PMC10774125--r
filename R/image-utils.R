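# Internal image primitives shared by the generator, preprocessing and
# alignment: rigid 2D resampling with a precomputed bilinear weight cache
# (so a whole frame stack reuses one coordinate mapping), small-kernel 2D
# convolution with exact zero padding, and separable Gaussian smoothing for
# phantom construction. Coordinates: x = column index, y = row index;
# rotation is about the image centre, positive from +x toward +y; the
# transform maps moving-image content by (theta, tx, ty), i.e. a feature at
# moving (x, y) appears in the output at R(theta) (x - c) + c + (tx, ty).

#' Rigid 2D transforms
#'
#' In-plane rotation about the image centre plus translation, the transform
#' family used for cross-session alignment (brain size does not change
#' between sessions, so no scaling). Units: degrees and pixels.
#'
#' @param theta_deg rotation angle in degrees (positive from +x toward +y).
#' @param tx_px,ty_px translation in pixels along columns (x) and rows (y).
#' @return An object of class `rigid_transform2d`.
#' @export
rigid_transform2d <- function(theta_deg = 0, tx_px = 0, ty_px = 0) {
  stopifnot(is.numeric(theta_deg), is.numeric(tx_px), is.numeric(ty_px))
  structure(list(theta_deg = as.numeric(theta_deg),
                 tx_px = as.numeric(tx_px), ty_px = as.numeric(ty_px)),
            class = "rigid_transform2d")
}

#' @export
print.rigid_transform2d <- function(x, ...) {
  cat(sprintf("<rigid_transform2d> theta = %.4f deg, t = (%.3f, %.3f) px\n",
              x$theta_deg, x$tx_px, x$ty_px))
  invisible(x)
}

#' Compose and invert rigid transforms
#'
#' `compose_transform(a, b)` is the transform applying `b` first, then `a`.
#'
#' @param a,b,transform `rigid_transform2d` objects.
#' @return A `rigid_transform2d`.
#' @export
compose_transform <- function(a, b) {
  th_a <- a$theta_deg * pi / 180
  R <- matrix(c(cos(th_a), sin(th_a), -sin(th_a), cos(th_a)), 2, 2)
  t_new <- R %*% c(b$tx_px, b$ty_px) + c(a$tx_px, a$ty_px)
  rigid_transform2d(a$theta_deg + b$theta_deg, t_new[1], t_new[2])
}

#' @rdname compose_transform
#' @export
invert_transform <- function(transform) {
  th <- -transform$theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t_new <- -R %*% c(transform$tx_px, transform$ty_px)
  rigid_transform2d(-transform$theta_deg, t_new[1], t_new[2])
}

# Precompute bilinear sampling indices/weights for applying `transform` to
# any H x W matrix. Output pixel (x,y) samples the moving image at the
# inverse-mapped location; samples outside the grid contribute zero.
resample_cache <- function(dims, transform) {
  H <- dims[1]; W <- dims[2]
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  g <- expand.grid(y = seq_len(H), x = seq_len(W))
  th <- -transform$theta_deg * pi / 180  # inverse rotation
  xs <- g$x - transform$tx_px - cx
  ys <- g$y - transform$ty_px - cy
  xm <- cos(th) * xs - sin(th) * ys + cx
  ym <- sin(th) * xs + cos(th) * ys + cy
  x0 <- floor(xm); y0 <- floor(ym)
  fx <- xm - x0; fy <- ym - y0
  w <- list((1 - fx) * (1 - fy), (1 - fx) * fy, fx * (1 - fy), fx * fy)
  ix <- list(cbind(y0, x0), cbind(y0 + 1, x0),
             cbind(y0, x0 + 1), cbind(y0 + 1, x0 + 1))
  lin <- vector("list", 4)
  for (k in 1:4) {
    yy <- ix[[k]][, 1]; xx <- ix[[k]][, 2]
    inside <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    w[[k]][!inside] <- 0
    yy[!inside] <- 1; xx[!inside] <- 1
    lin[[k]] <- (xx - 1) * H + yy
  }
  list(H = H, W = W, lin = lin, w = w)
}

resample_with_cache <- function(img, cache) {
  v <- cache$w[[1]] * img[cache$lin[[1]]] + cache$w[[2]] * img[cache$lin[[2]]] +
       cache$w[[3]] * img[cache$lin[[3]]] + cache$w[[4]] * img[cache$lin[[4]]]
  matrix(v, cache$H, cache$W)
}

#' Apply a rigid transform to an image or frame stack
#'
#' Resamples with bilinear interpolation; samples falling outside the grid
#' are set to 0. A frame stack (`H x W x T`) is transformed frame by frame
#' with one shared coordinate mapping, exactly as the cross-session
#' pretraining path transforms a previous session's data.
#'
#' @param x `H x W` matrix or `H x W x T` array.
#' @param transform a [rigid_transform2d()].
#' @return Object of the same shape as `x`.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform2d"))
  if (is.matrix(x)) {
    if (identical(unclass(transform), unclass(rigid_transform2d()))) return(x)
    cache <- resample_cache(dim(x), transform)
    return(resample_with_cache(x, cache))
  }
  stopifnot(is.array(x), length(dim(x)) == 3)
  if (identical(unclass(transform), unclass(rigid_transform2d()))) return(x)
  cache <- resample_cache(dim(x)[1:2], transform)
  out <- x
  for (t in seq_len(dim(x)[3])) {
    out[, , t] <- resample_with_cache(x[, , t], cache)
  }
  out
}

# Direct 2D convolution with a small odd-sized kernel, zero-padded
# boundaries; implemented as a shift-and-add over nonzero kernel taps so the
# result is bit-deterministic.
conv2_zero <- function(img, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  H <- nrow(img); W <- ncol(img)
  ry <- (kh - 1) / 2; rx <- (kw - 1) / 2
  out <- matrix(0, H, W)
  for (j in seq_len(kw)) {
    dx <- j - 1 - rx
    for (i in seq_len(kh)) {
      kv <- kernel[i, j]
      if (kv == 0) next
      dy <- i - 1 - ry
      ys <- max(1, 1 - dy):min(H, H - dy)
      xs <- max(1, 1 - dx):min(W, W - dx)
      out[ys, xs] <- out[ys, xs] + kv * img[ys + dy, xs + dx]
    }
  }
  out
}

#' Disk ("pillbox") convolution kernels
#'
#' Builds the unit-sum disk kernel used for spatial smoothing. The default
#' `"area"` dialect weights each pixel of the (2r+1)^2 support by the
#' fraction of its unit square covered by the disk (computed on a midpoint
#' subgrid); the `"binary"` dialect includes a pixel fully iff its centre
#' lies within the radius (13 pixels at radius 2).
#'
#' @param radius_px disk radius in pixels (>= 1).
#' @param dialect `"area"` (default) or `"binary"`.
#' @return Matrix of size `(2*radius+1)^2` summing to 1.
#' @export
pillbox_kernel <- function(radius_px = 2, dialect = c("area", "binary")) {
  stopifnot(radius_px >= 1)
  dialect <- match.arg(dialect)
  r <- radius_px
  n <- 2 * floor(r) + 1
  ctr <- floor(r) + 1
  if (dialect == "binary") {
    k <- outer(seq_len(n) - ctr, seq_len(n) - ctr,
               function(dy, dx) as.numeric(dy^2 + dx^2 <= r^2))
  } else {
    m <- 64L  # midpoint subsamples per axis per pixel
    sub <- (seq_len(m) - 0.5) / m - 0.5
    k <- matrix(0, n, n)
    for (j in seq_len(n)) {
      for (i in seq_len(n)) {
        dy <- (i - ctr) + sub
        dx <- (j - ctr) + sub
        k[i, j] <- mean(outer(dy^2, dx^2, `+`) <= r^2)
      }
    }
  }
  k / sum(k)
}

#' Pillbox spatial filter
#'
#' Convolves a frame with the unit-sum disk kernel of the given radius
#' (zero-padded boundaries), the spatial smoothing applied to each buffered
#' frame before classification.
#'
#' @param frame `H x W` matrix.
#' @inheritParams pillbox_kernel
#' @param kernel optional precomputed kernel (overrides radius/dialect).
#' @return Filtered `H x W` matrix.
#' @export
pillbox_filter <- function(frame, radius_px = 2,
                           dialect = c("area", "binary"), kernel = NULL) {
  stopifnot(is.matrix(frame))
  if (is.null(kernel)) kernel <- pillbox_kernel(radius_px, match.arg(dialect))
  conv2_zero(frame, kernel)
}

# Separable Gaussian blur (reflective boundary) for phantom construction.
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_reflect <- function(m, r, along) {
    if (along == 1) rbind(m[r:1, , drop = FALSE], m,
                          m[nrow(m):(nrow(m) - r + 1), , drop = FALSE])
    else cbind(m[, r:1, drop = FALSE], m,
               m[, ncol(m):(ncol(m) - r + 1), drop = FALSE])
  }
  H <- nrow(img); W <- ncol(img)
  p <- pad_reflect(img, r, 1)
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * p[(i - 1) + seq_len(H), ]
  p <- pad_reflect(out, r, 2)
  out2 <- matrix(0, H, W)
  for (i in seq_along(k)) out2 <- out2 + k[i] * p[, (i - 1) + seq_len(W)]
  out2
}

# Block-mean downsampling by an integer factor (multi-resolution pyramid).
downsample2 <- function(img, factor = 2L) {
  H <- nrow(img); W <- ncol(img)
  H2 <- floor(H / factor); W2 <- floor(W / factor)
  img <- img[seq_len(H2 * factor), seq_len(W2 * factor)]
  a <- array(img, dim = c(factor, H2, factor, W2))
  apply(a, c(2, 4), mean)
}
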