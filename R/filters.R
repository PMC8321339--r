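# Separable spatio-temporal filters.
#
# The detector rests on one pair of separable filters sharing a spatial
# low-pass kernel rho: the LL pair l = rho * phi (temporal low-pass) whose
# response F yields the energy signal sigma_F, and the LH pair h = rho * psi
# (temporal high-pass, psi the discrete time derivative of phi) whose
# response G vanishes exactly when nothing moves. Minima of sigma_F
# correspond to (near-)zeros of sigma_G, which is what makes the cheap
# low-pass signal usable as a stillness detector.

#' Isotropic spatial Gaussian low-pass kernel
#'
#' The spatial smoothing that makes the measure sensitive to object-scale
#' motion rather than single-pixel change. The default standard deviation of
#' 9 px corresponds to roughly one degree of visual angle on a typical
#' face-sized ROI; scale it with the face size for smaller frames.
#'
#' @param rho_std Standard deviation in pixels (> 0).
#' @param truncate Kernel half-width in multiples of `rho_std`; the kernel is
#'   sampled on an odd grid of half-width `ceiling(truncate * rho_std)` and
#'   renormalized to unit DC gain.
#' @return A square matrix summing to 1.
#' @export
make_spatial_gaussian <- function(rho_std, truncate = 3) {
  if (!is.numeric(rho_std) || rho_std <= 0) stop_input("rho_std must be > 0")
  h <- ceiling(truncate * rho_std)
  xs <- seq.int(-h, h)
  g <- exp(-xs^2 / (2 * rho_std^2))
  g <- g / sum(g)
  outer(g, g)
}

# 1-D profile of the separable spatial Gaussian (kernel = outer(g, g)).
spatial_gaussian_profile <- function(rho_std, truncate = 3) {
  h <- ceiling(truncate * rho_std)
  xs <- seq.int(-h, h)
  g <- exp(-xs^2 / (2 * rho_std^2))
  g / sum(g)
}

#' Temporal low-pass kernel phi
#'
#' `size` is the filter length in frames. The working settings for the
#' published datasets are length 8 at 200 fps and length 2 at 25 fps (see
#' [default_phi_size()]); both keep the temporal support at or under the
#' shortest expected micro-expression so that the smoothing cannot erase it.
#'
#' @param kind `"box"` (uniform weights, the default) or `"gaussian"`
#'   (std = size/4, truncated at `size` taps).
#' @param size Length in frames (>= 2).
#' @return A numeric vector summing to 1.
#' @export
make_temporal_lowpass <- function(kind = c("box", "gaussian"), size) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (is.na(size) || size < 2L) stop_input("temporal filter size must be >= 2")
  if (kind == "box") return(rep(1 / size, size))
  xs <- seq_len(size) - (size + 1) / 2
  g <- exp(-xs^2 / (2 * (size / 4)^2))
  g / sum(g)
}

#' Temporal high-pass kernel psi = d(phi)/dt
#'
#' Discrete derivative of the low-pass kernel, computed as the central
#' difference of `phi` extended by zeros outside its support. For any
#' symmetric `phi` the taps sum to exactly 0, and for a Gaussian `phi` the
#' result approximates the sampled derivative-of-Gaussian. This is the
#' derivative pairing under which zeros of the high-pass energy line up with
#' extrema of the low-pass energy.
#'
#' @param phi A temporal low-pass kernel (>= 2 taps).
#' @return A numeric vector of the same length as `phi`.
#' @export
make_temporal_highpass <- function(phi) {
  L <- length(phi)
  if (L < 2L) stop_input("phi needs at least 2 taps")
  padded <- c(0, phi, 0)
  (padded[seq.int(3, L + 2)] - padded[seq_len(L)]) / 2
}

#' Biphasic temporal filter of the motion-energy model
#'
#' The classic Adelson--Bergen temporal impulse response
#' `(k t)^n e^(-k t) [1/n! - (k t)^2/(n+2)!]`, sampled at integer frames
#' `t = 0, ..., 2*support` and mean-subtracted to zero DC gain. It has one
#' positive and one negative lobe, with the sign change of the underlying
#' continuous response at `k t = sqrt((n+1)(n+2))`. Provided for completeness
#' and for cross-checking the high-pass channel; the detector itself only
#' needs the derivative pair from [make_temporal_highpass()].
#'
#' @param n Non-negative integer order (>= 1); default 3, the fast channel
#'   of the original model.
#' @param k Rate parameter in 1/frames (> 0).
#' @param support Half-width in frames (>= n/k).
#' @return A numeric vector of length `2*support + 1` summing to 0.
#' @export
make_biphasic <- function(n = 3L, k = 1, support = 8L) {
  if (n < 1L || n != round(n)) stop_input("n must be a positive integer")
  if (k <= 0) stop_input("k must be > 0")
  if (support < n / k) stop_input("support must be >= n/k")
  t <- seq.int(0L, 2L * support)
  kt <- k * t
  raw <- kt^n * exp(-kt) * (1 / factorial(n) - kt^2 / factorial(n + 2))
  raw - mean(raw)
}

#' Separable spatio-temporal filter
#'
#' Bundles the spatial Gaussian `rho` with the temporal pair `phi` (low-pass)
#' and `psi = d(phi)/dt` (high-pass). `mode` selects which temporal kernel
#' [apply_separable()] uses: `"LL"` gives the smoothed sequence F whose
#' spatial standard deviation is the stillness signal, `"LH"` gives the
#' temporal-derivative sequence G used to verify that minima really are
#' still.
#'
#' @param rho_std Spatial Gaussian standard deviation in pixels.
#' @param phi_kind,phi_size Temporal kernel kind and length, see
#'   [make_temporal_lowpass()].
#' @param mode `"LL"` or `"LH"`.
#' @param truncate Spatial truncation in multiples of `rho_std`.
#' @return An object of class `st_filter` with elements `rho` (2-D kernel),
#'   `rho_1d`, `phi`, `psi`, `mode`, `rho_std`, `phi_kind`, `phi_size`,
#'   `truncate`.
#' @export
st_filter <- function(rho_std = 9, phi_kind = c("box", "gaussian"),
                      phi_size = 2L, mode = c("LL", "LH"), truncate = 3) {
  phi_kind <- match.arg(phi_kind)
  mode <- match.arg(mode)
  g <- spatial_gaussian_profile(rho_std, truncate)
  phi <- make_temporal_lowpass(phi_kind, phi_size)
  psi <- make_temporal_highpass(phi)
  obj <- structure(list(rho = outer(g, g), rho_1d = g, phi = phi, psi = psi,
                        mode = mode, rho_std = rho_std, phi_kind = phi_kind,
                        phi_size = as.integer(phi_size), truncate = truncate),
                   class = "st_filter")
  stopifnot(abs(sum(obj$rho) - 1) < 1e-9, abs(sum(phi) - 1) < 1e-9,
            abs(sum(psi)) < 1e-9)
  obj
}

#' @export
print.st_filter <- function(x, ...) {
  cat(sprintf("st_filter %s: spatial Gaussian std %.3g (%d taps), temporal %s length %d\n",
              x$mode, x$rho_std, length(x$rho_1d), x$phi_kind, x$phi_size))
  invisible(x)
}

#' Apply a separable spatio-temporal filter to a frame stack
#'
#' Spatial convolution with `rho` (as two 1-D Gaussian passes) followed by
#' temporal convolution with `phi` (mode `"LL"`) or `psi` (mode `"LH"`). All
#' boundaries use reflect padding, which avoids spurious energy extrema at
#' clip ends; the operation order is interchangeable by separability.
#'
#' @param stack A [frame_stack()].
#' @param filt An [st_filter()].
#' @return A filtered [frame_stack()] of the same shape.
#' @export
apply_separable <- function(stack, filt) {
  tt <- n_frames(stack)
  tk <- if (filt$mode == "LL") filt$phi else filt$psi
  if (tt < length(tk)) {
    stop_input("stack of ", tt, " frames is shorter than the temporal filter size ",
               length(tk))
  }
  a <- conv_along(stack$frames, filt$rho_1d, 1L)
  a <- conv_along(a, filt$rho_1d, 2L)
  a <- conv_along(a, tk, 3L)
  frame_stack(a, stack$fps, stack$t0)
}
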