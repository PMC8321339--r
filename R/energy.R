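# Temporal energy signals: per-frame spatial standard deviation.

#' Per-frame spatial standard deviation of a stack
#'
#' For every frame `t`, computes
#' `sigma(t) = sqrt( mean over (x, y) of (U(x,y,t) - mu(t))^2 )` with `mu(t)`
#' the spatial mean -- population normalization `1/|Omega|`, not the sample
#' `1/(|Omega|-1)`. Applied to the LL-filtered sequence this is the
#' stillness signal `sigma_F`; applied to the LH-filtered sequence it is the
#' motion signal `sigma_G`, which is zero exactly when the temporal
#' derivative carries no spatial structure.
#'
#' @param stack A [frame_stack()] (typically the output of
#'   [apply_separable()]).
#' @param role Tag recording which signal this is: `"sigma_F"`, `"sigma_G"`
#'   or `"other"`.
#' @return An object of class `energy_signal` with elements `values`
#'   (non-negative, one per frame), `role`, `t_index` (frame numbers in
#'   original-video numbering) and `energy_range` (`max - min` of `values`).
#' @export
spatial_std_signal <- function(stack, role = c("other", "sigma_F", "sigma_G")) {
  role <- match.arg(role)
  tt <- n_frames(stack)
  m <- matrix(stack$frames, ncol = tt)
  mu <- colMeans(m)
  centered <- sweep(m, 2L, mu)
  vals <- sqrt(colMeans(centered^2))
  energy_signal(vals, role = role, t_index = stack$t0 + seq_len(tt) - 1L)
}

#' Construct an energy signal from raw values
#'
#' Low-level constructor, mainly useful for feeding externally computed or
#' hand-crafted signals into the minima analysis.
#'
#' @param values Non-negative numeric vector, one value per frame.
#' @param role Signal tag (`"sigma_F"`, `"sigma_G"` or `"other"`).
#' @param t_index 1-based frame numbers aligned with `values`.
#' @return An object of class `energy_signal`.
#' @export
energy_signal <- function(values, role = "other", t_index = seq_along(values)) {
  stopifnot(length(values) == length(t_index), all(values >= 0))
  structure(list(values = as.numeric(values), role = role,
                 t_index = as.integer(t_index),
                 energy_range = max(values) - min(values)),
            class = "energy_signal")
}

#' @export
print.energy_signal <- function(x, ...) {
  cat(sprintf("energy_signal (%s): %d frames [%d..%d], range %.6g\n",
              x$role, length(x$values), x$t_index[1],
              x$t_index[length(x$t_index)], x$energy_range))
  invisible(x)
}

#' @export
as.data.frame.energy_signal <- function(x, ...) {
  data.frame(frame = x$t_index, sigma = x$values)
}

#' Export an energy signal as two-column CSV
#'
#' Writes `frame,sigma` rows, the plotting/regression-test interchange
#' format.
#'
#' @param sig An `energy_signal`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_energy <- function(sig, path) {
  utils::write.csv(as.data.frame(sig), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Matched pair of energy signals sigma_F and sigma_G
#'
#' Applies an LL and an LH filter to the same stack and returns both energy
#' signals, index-aligned. The two filters must share the spatial kernel and
#' satisfy `psi = d(phi)/dt`; otherwise the minima-of-`sigma_F` /
#' zeros-of-`sigma_G` correspondence that justifies the detector does not
#' hold, and the call is refused.
#'
#' @param stack A [frame_stack()].
#' @param filt_LL An [st_filter()] with mode `"LL"`.
#' @param filt_LH An [st_filter()] with mode `"LH"`.
#' @return A list with elements `sigma_F` and `sigma_G`, both
#'   `energy_signal`s.
#' @export
energy_pair <- function(stack, filt_LL, filt_LH) {
  if (filt_LL$mode != "LL" || filt_LH$mode != "LH") {
    stop_input("energy_pair needs one LL and one LH filter, in that order")
  }
  if (!isTRUE(all.equal(filt_LL$rho, filt_LH$rho, tolerance = 1e-12))) {
    stop_input("the two filters must share the same spatial kernel rho")
  }
  expected_psi <- make_temporal_highpass(filt_LL$phi)
  if (length(expected_psi) != length(filt_LH$psi) ||
      max(abs(expected_psi - filt_LH$psi)) > 1e-12) {
    stop_input("psi of the LH filter must be the derivative of phi of the LL filter")
  }
  F_ <- apply_separable(stack, filt_LL)
  G_ <- apply_separable(stack, filt_LH)
  list(sigma_F = spatial_std_signal(F_, "sigma_F"),
       sigma_G = spatial_std_signal(G_, "sigma_G"))
}
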