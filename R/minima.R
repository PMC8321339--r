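# Local minima of the stillness signal, instability removal, top-K selection.

#' Local minima of an energy signal
#'
#' Interior local minima of `sigma(t)`: positions with
#' `sigma(t) < sigma(t-1)` and `sigma(t) <= sigma(t+1)`. A constant plateau
#' that is lower than both of its neighbors is reported once, at its first
#' frame, so an exactly frozen interval yields a single representative
#' instead of flooding the list. Endpoints are never reported.
#'
#' @param sig An [energy_signal()] of length >= 3.
#' @return A data frame with columns `t` (frame number) and `sigma`,
#'   ordered by `t`.
#' @export
find_local_minima <- function(sig) {
  v <- sig$values
  if (length(v) < 3L) stop_input("signal must have at least 3 frames")
  r <- rle(v)
  k <- length(r$values)
  starts <- cumsum(c(1L, r$lengths[-k]))
  is_min <- logical(k)
  if (k >= 3L) {
    inner <- 2:(k - 1L)
    is_min[inner] <- r$values[inner] < r$values[inner - 1L] &
      r$values[inner] < r$values[inner + 1L]
  }
  idx <- starts[is_min]
  data.frame(t = sig$t_index[idx], sigma = v[idx])
}

#' Instability-removal and merge parameters
#'
#' `d` is the maximum frame distance and `tau` the maximum energy difference
#' (as a fraction of the scene's energy range) under which adjacent minima
#' are considered one unstable oscillation rather than distinct events; `K`
#' is the number of minima kept after sorting by energy. Working defaults:
#' `tau = 0.1` (minima within 10% of the energy range), `d = N/4` with `N`
#' the maximal expected micro-expression length, `K = 3` for 25 fps footage
#' and `K = 5` for 200 fps.
#'
#' @param d Maximum adjacency distance in frames (>= 1).
#' @param tau Maximum relative energy difference, in (0, 1).
#' @param K Number of minima to keep (>= 1).
#' @return An object of class `minima_params`.
#' @export
minima_params <- function(d = 2L, tau = 0.1, K = 3L) {
  if (d < 1L) stop_input("d must be >= 1")
  if (tau <= 0 || tau >= 1) stop_input("tau must be in (0, 1)")
  if (K < 1L) stop_input("K must be >= 1")
  structure(list(d = as.integer(d), tau = tau, K = as.integer(K)),
            class = "minima_params")
}

# One chaining pass: maximal runs of consecutive minima with gap <= d and
# |sigma difference| <= tau * energy_range collapse to their midpoint.
merge_pass <- function(df, sig, d, tau_abs) {
  if (nrow(df) < 2L) return(df)
  gap_ok <- diff(df$t) <= d & abs(diff(df$sigma)) <= tau_abs
  grp <- cumsum(c(0L, !gap_ok))
  out <- lapply(split(seq_len(nrow(df)), grp), function(ix) {
    if (length(ix) == 1L) return(df[ix, ])
    t_hat <- round_half_up((min(df$t[ix]) + max(df$t[ix])) / 2)
    data.frame(t = t_hat, sigma = sig$values[match(t_hat, sig$t_index)])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$t), ]
}

#' Remove instabilities from a minima list
#'
#' Numerical noise in the energy signal produces clusters of nearby local
#' minima with nearly equal values. Maximal chains of consecutive minima
#' whose frame gaps are `<= d` and whose energy differences are
#' `<= tau * energy_range` are treated as one instability set and replaced
#' by the set's midpoint (rounded to the nearest frame, energy read off the
#' signal there). The pass is repeated until nothing changes, so the result
#' is idempotent and no surviving pair still satisfies both closeness
#' conditions.
#'
#' @param minima Data frame from [find_local_minima()], sorted by `t`.
#' @param sig The [energy_signal()] the minima came from (supplies
#'   `energy_range` and midpoint energies).
#' @param params A [minima_params()].
#' @return An object of class `minima_result`: list with `raw` (input
#'   minima), `merged` (data frame after instability removal, sorted by
#'   `t`), `params`, and `energy_range`.
#' @export
merge_instabilities <- function(minima, sig, params) {
  stopifnot(inherits(params, "minima_params"))
  if (is.unsorted(minima$t)) stop_input("minima must be sorted by t")
  tau_abs <- params$tau * sig$energy_range
  cur <- minima
  repeat {
    nxt <- merge_pass(cur, sig, params$d, tau_abs)
    if (nrow(nxt) == nrow(cur) && all(nxt$t == cur$t)) break
    cur <- nxt
  }
  rownames(cur) <- NULL
  structure(list(raw = minima, merged = cur, params = params,
                 energy_range = sig$energy_range),
            class = "minima_result")
}

#' @export
print.minima_result <- function(x, ...) {
  cat(sprintf("minima_result: %d raw -> %d merged (d=%d, tau=%.3g)\n",
              nrow(x$raw), nrow(x$merged), x$params$d, x$params$tau))
  invisible(x)
}

#' Select the K minima of smallest energy
#'
#' Sorts the merged minima by ascending energy value (ties broken by earlier
#' frame) and keeps the first `min(K, M)`. These are the frozen-frame
#' candidates handed to GOF construction.
#'
#' @param result A [merge_instabilities()] result (or a plain data frame
#'   with columns `t`, `sigma`).
#' @param K Number of minima to keep (>= 1).
#' @return Integer vector of frame numbers, in ascending energy order.
#' @export
select_top_k <- function(result, K) {
  if (K < 1L) stop_input("K must be >= 1")
  df <- if (inherits(result, "minima_result")) result$merged else result
  ord <- order(df$sigma, df$t)
  df$t[ord][seq_len(min(K, nrow(df)))]
}
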