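# Synthetic vascular phantoms: a positive baseline power-Doppler image with
# curvilinear vessel-like structures plus direction-tuned patches whose
# memory-period hemodynamic response drives the decoders.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Exact-area disk mask: the `area` lattice voxels closest to `center`
# (ties broken by scan order). Errors if the mask would leave the grid.
disk_mask <- function(dims, center, area) {
  H <- dims[1]; W <- dims[2]
  r_max <- ceiling(sqrt(area / pi)) + 2
  ys <- (center[1] - r_max):(center[1] + r_max)
  xs <- (center[2] - r_max):(center[2] + r_max)
  g <- expand.grid(y = ys, x = xs)
  d2 <- (g$y - center[1])^2 + (g$x - center[2])^2
  ord <- order(d2, g$x, g$y)
  sel <- g[ord[seq_len(area)], ]
  if (any(sel$y < 1 | sel$y > H | sel$x < 1 | sel$x > W)) {
    stop("patch of ", area, " voxels at (", center[1], ",", center[2],
         ") does not fit inside the ", H, "x", W, " grid")
  }
  sort((sel$x - 1) * H + sel$y)
}

#' Direction tuning curve (von Mises, normalized to 1 at preferred)
#'
#' `exp(kappa * cos(phi - phi_pref)) / exp(kappa)`: equals 1 at the
#' preferred direction and `exp(-2 kappa)` at the anti-preferred direction.
#'
#' @param phi_deg cue direction(s), degrees.
#' @param preferred_deg preferred direction, degrees.
#' @param kappa concentration (>= 0); larger = sharper tuning.
#' @return Numeric tuning gain in (0, 1].
#' @export
von_mises_tuning <- function(phi_deg, preferred_deg, kappa = 2) {
  exp(kappa * cos((phi_deg - preferred_deg) * pi / 180)) / exp(kappa)
}

# Gamma-variate hemodynamic response sampled at the frame period and
# normalized to unit area, so a sustained stimulus asymptotes at gain 1.
hrf_kernel <- function(peak_s = 1.5, fwhm_s = 2, delay_s = 0, dt = 0.5,
                       t_max = 15) {
  sigma <- fwhm_s / (2 * sqrt(2 * log(2)))
  v <- sigma^2
  # gamma with mode (k-1)*theta = peak_s and variance k*theta^2 = v:
  # shape k solves v*k^2 - (2v + peak^2)*k + v = 0 (larger root)
  b <- -(2 * v + peak_s^2)
  k <- ((-b) + sqrt(b^2 - 4 * v * v)) / (2 * v)
  theta <- peak_s / (k - 1)
  tt <- seq(0, t_max, by = dt)
  h <- stats::dgamma(tt - delay_s, shape = k, scale = theta)
  h[!is.finite(h)] <- 0
  h / sum(h)
}

#' Build a synthetic vascular phantom with direction-tuned patches
#'
#' The anatomy is a strictly positive baseline image with smoothed
#' curvilinear vessel-like structures (emulating a mean power-Doppler
#' vascular map). Two tuned patches are placed by default — an "LIP-like"
#' region preferring leftward movements and an "MIP-like" region preferring
#' upward movements — each a compact disk of voxels whose memory-period
#' response follows a von Mises tuning curve convolved with a seconds-scale
#' gamma-variate response function.
#'
#' @param dims grid size `c(H, W)`; default 128 x 160 (12.8 x 16 mm at
#'   0.1 mm voxels).
#' @param patches list of patch specs, each a list with `center` (y, x),
#'   `area` (voxel count), `preferred_deg`, `kappa`, `amplitude`, and
#'   optionally `hrf = list(peak_s, fwhm_s, delay_s)`.
#' @param noise_sd voxel-wise multiplicative noise sd (fraction of baseline).
#' @param drift_sd per-frame global gain random-walk sd.
#' @param pulsatility_amp amplitude of the 0.3 Hz global gain oscillation
#'   (aliased heartbeat surrogate).
#' @param n_vessels number of vessel-like structures to draw.
#' @param seed RNG seed (phantoms are deterministic given the seed).
#' @return An object of class `fus_phantom`.
#' @export
make_phantom <- function(dims = c(128, 160), patches = NULL,
                         noise_sd = 0.02, drift_sd = 0.002,
                         pulsatility_amp = 0.01, n_vessels = 12,
                         seed = 1) {
  stopifnot(length(dims) == 2, all(dims >= 8))
  H <- dims[1]; W <- dims[2]
  anatomy <- with_seed(seed, {
    base <- matrix(1, H, W)
    vessel <- matrix(0, H, W)
    for (v in seq_len(n_vessels)) {
      y <- stats::runif(1, 0.1 * H, 0.9 * H)
      x <- stats::runif(1, 0.05 * W, 0.2 * W)
      ang <- stats::runif(1, -pi / 4, pi / 4)
      amp <- stats::runif(1, 2, 6)
      n_steps <- round(stats::runif(1, 0.6, 1.1) * W)
      for (s in seq_len(n_steps)) {
        ang <- ang + stats::rnorm(1, 0, 0.08)
        y <- y + sin(ang); x <- x + cos(ang)
        iy <- round(y); ix <- round(x)
        if (iy < 1 || iy > H || ix < 1 || ix > W) break
        vessel[iy, ix] <- vessel[iy, ix] + amp
      }
    }
    base + gauss_blur(vessel, 1.2) * 3
  })
  if (is.null(patches)) {
    # ~1% of the field of view per patch (200 voxels at the default grid)
    area0 <- min(200, max(12, round(0.01 * H * W)))
    patches <- list(
      list(center = round(c(0.35 * H, 0.30 * W)), area = area0,
           preferred_deg = 180, kappa = 2, amplitude = 0.10),
      list(center = round(c(0.55 * H, 0.65 * W)), area = area0,
           preferred_deg = 90, kappa = 2, amplitude = 0.10)
    )
  }
  patches <- lapply(patches, function(p) {
    stopifnot(!is.null(p$center), !is.null(p$preferred_deg))
    p$area <- p$area %||% 200
    p$kappa <- p$kappa %||% 2
    p$amplitude <- p$amplitude %||% 0.10
    if (p$amplitude < 0) stop("patch amplitude must be >= 0")
    p$hrf <- utils::modifyList(list(peak_s = 1.5, fwhm_s = 2, delay_s = 0),
                               p$hrf %||% list())
    p$mask <- disk_mask(c(H, W), p$center, p$area)
    p
  })
  structure(list(dims = c(H, W), anatomy = anatomy, background = 1,
                 patches = patches, noise_sd = noise_sd, drift_sd = drift_sd,
                 pulsatility_amp = pulsatility_amp, voxel_size_mm = 0.1,
                 seed = seed),
            class = "fus_phantom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fus_phantom <- function(x, ...) {
  cat("<fus_phantom> ", x$dims[1], "x", x$dims[2], " grid, ",
      length(x$patches), " tuned patch(es), noise_sd = ", x$noise_sd,
      "\n", sep = "")
  invisible(x)
}

#' Rigidly perturb a phantom to emulate a later session
#'
#' Between sessions the brain shifts slightly relative to the transducer;
#' this applies a rigid in-plane transform (and an overall gain) to the
#' anatomy and all patch masks, returning the perturbed phantom with the
#' true transform attached (`attr(_, "true_transform")`) for use as a test
#' oracle. Out-of-grid regions are filled with the background level so the
#' anatomy stays strictly positive.
#'
#' @param phantom a `fus_phantom`.
#' @param rotate_deg rotation, |rotate_deg| <= 10.
#' @param shift_px translation `c(tx, ty)` in pixels (columns, rows),
#'   each |shift| <= 20.
#' @param gain global intensity scale.
#' @param seed unused (kept for interface symmetry); the perturbation is
#'   deterministic.
#' @return A `fus_phantom` with attribute `true_transform`.
#' @export
perturb_for_next_session <- function(phantom, rotate_deg = 0,
                                     shift_px = c(0, 0), gain = 1,
                                     seed = NULL) {
  stopifnot(inherits(phantom, "fus_phantom"))
  if (abs(rotate_deg) > 10) stop("|rotate_deg| must be <= 10")
  if (any(abs(shift_px) > 20)) stop("|shift_px| must be <= 20")
  tr <- rigid_transform2d(rotate_deg, shift_px[1], shift_px[2])
  H <- phantom$dims[1]; W <- phantom$dims[2]
  b0 <- phantom$background
  anat <- apply_transform(phantom$anatomy - b0, tr) + b0
  out <- phantom
  out$anatomy <- anat * gain
  out$background <- b0 * gain
  cache <- resample_cache(c(H, W), tr)
  out$patches <- lapply(phantom$patches, function(p) {
    # forward-map mask voxel centres; all must stay on the grid
    y <- ((p$mask - 1) %% H) + 1
    x <- ((p$mask - 1) %/% H) + 1
    th <- rotate_deg * pi / 180
    cx <- (W + 1) / 2; cy <- (H + 1) / 2
    xn <- cos(th) * (x - cx) - sin(th) * (y - cy) + cx + shift_px[1]
    yn <- sin(th) * (x - cx) + cos(th) * (y - cy) + cy + shift_px[2]
    if (any(xn < 1 | xn > W | yn < 1 | yn > H)) {
      stop("transform pushes a tuned patch off the grid")
    }
    ind <- matrix(0, H, W); ind[p$mask] <- 1
    p$mask <- which(resample_with_cache(ind, cache) >= 0.5)
    p
  })
  attr(out, "true_transform") <- tr
  out
}

#' SVD clutter filter for a slow-time Doppler ensemble
#'
#' Forms a power-Doppler frame from an ensemble of compounded frames:
#' reshape to a (voxels x N) Casorati matrix, zero the
#' `floor(discard_fraction * N)` largest singular components (dominated by
#' quasi-static tissue motion), and return the mean over slow time of the
#' squared residual per voxel. With the default 30% discard fraction, a
#' 200-frame ensemble drops exactly 60 components.
#'
#' @param ensemble `H x W x N` array or `voxels x N` matrix, N >= 4.
#' @param discard_fraction fraction of components to discard, in [0, 1).
#' @return `H x W` matrix (or voxel vector for matrix input) of power
#'   Doppler values.
#' @export
svd_clutter_filter <- function(ensemble, discard_fraction = 0.3) {
  if (discard_fraction < 0 || discard_fraction >= 1) {
    stop("discard_fraction must be in [0, 1)")
  }
  dims <- NULL
  if (is.array(ensemble) && length(dim(ensemble)) == 3) {
    dims <- dim(ensemble)[1:2]
    ensemble <- matrix(ensemble, prod(dims), dim(ensemble)[3])
  }
  stopifnot(is.matrix(ensemble))
  N <- ncol(ensemble)
  if (N < 4) stop("ensemble must contain at least 4 frames")
  n_discard <- floor(discard_fraction * N)
  res <- ensemble
  if (n_discard > 0) {
    sv <- svd(ensemble, nu = n_discard, nv = n_discard)
    clutter <- sv$u %*% (sv$d[seq_len(n_discard)] * t(sv$v))
    res <- ensemble - clutter
  }
  pw <- rowMeans(res^2)
  if (!is.null(dims)) pw <- matrix(pw, dims[1], dims[2])
  pw
}
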