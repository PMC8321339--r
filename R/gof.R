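# Groups of frames around selected minima, and frame-retention bookkeeping.

#' Build groups of frames around selected minima
#'
#' Each selected minimum `t` becomes a GOF window
#' `[t - half_before, t + half_after - 1]` (10 frames for the default 5/5 at
#' 25 fps). Two views coexist on purpose:
#' * *extraction* windows are clipped to the clip bounds, for actually
#'   pulling frames;
#' * *bookkeeping* counts `(half_before + half_after) * n_minima` frames with
#'   no clipping and no union, which is the convention under which published
#'   retained-frame percentages for the MEVIEW clips are computed, and a
#'   slightly pessimistic (safe) upper bound for planning.
#'
#' The retained percentage is `100 * retained_count / clip_length`, rounded
#' half-up to an integer and capped at 100.
#'
#' @param minima Integer vector of selected minima frame numbers (may be
#'   empty).
#' @param half_before,half_after Window half-widths in frames; defaults 5/5
#'   suit 25 fps footage, 16/16 suits 200 fps.
#' @param clip Two-element vector `c(first, last)` frame of the clip, or a
#'   single length (interpreted as `c(1, length)`).
#' @return An object of class `gof_set`: list with `windows` (data frame
#'   `minimum`, `start`, `end`, clipped), `half_before`, `half_after`,
#'   `retained_count`, `clip_length`, `retained_percentage`.
#' @export
build_gofs <- function(minima, half_before = 5L, half_after = 5L, clip) {
  if (length(clip) == 1L) clip <- c(1L, as.integer(clip))
  lo <- as.integer(clip[1]); hi <- as.integer(clip[2])
  clip_length <- hi - lo + 1L
  minima <- as.integer(minima)
  if (length(minima) && any(minima < lo | minima > hi)) {
    stop_input("minima must lie within the clip [", lo, ", ", hi, "]")
  }
  if (length(minima)) {
    windows <- data.frame(
      minimum = minima,
      start = pmax(lo, minima - as.integer(half_before)),
      end = pmin(hi, minima + as.integer(half_after) - 1L))
  } else {
    windows <- data.frame(minimum = integer(), start = integer(), end = integer())
  }
  retained <- (as.integer(half_before) + as.integer(half_after)) * length(minima)
  pct <- min(100, round_half_up(100 * retained / clip_length))
  structure(list(windows = windows, half_before = as.integer(half_before),
                 half_after = as.integer(half_after),
                 retained_count = retained, clip_length = clip_length,
                 retained_percentage = as.integer(pct)),
            class = "gof_set")
}

#' @export
print.gof_set <- function(x, ...) {
  cat(sprintf("gof_set: %d windows of %d+%d frames, %d%% of %d frames retained\n",
              nrow(x$windows), x$half_before, x$half_after,
              x$retained_percentage, x$clip_length))
  invisible(x)
}

#' Frame-reduction statistics over a set of clips
#'
#' The point of the preprocessing: how many frames a downstream spotting
#' algorithm no longer has to look at. Per clip the reduction is
#' `100 - retained_percentage`; the summary reports the mean (rounded
#' half-up to an integer), maximum and minimum over clips.
#'
#' @param gofsets A list of [build_gofs()] results (>= 1).
#' @return A list with `mean_reduction`, `max_reduction`, `min_reduction`
#'   (percent), and the per-clip `reductions` vector.
#' @export
reduction_stats <- function(gofsets) {
  if (!length(gofsets)) stop_input("need at least one gof_set")
  red <- vapply(gofsets, function(g) 100 - g$retained_percentage, numeric(1))
  list(mean_reduction = round_half_up(mean(red)),
       max_reduction = max(red), min_reduction = min(red),
       reductions = red)
}

#' Write a GOF report as CSV
#'
#' One row per selected minimum:
#' `sequence_id,minimum_frame,window_start,window_end,retained_percentage`.
#'
#' @param gofsets Named list of [build_gofs()] results (names are sequence
#'   ids).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gof_report <- function(gofsets, path) {
  rows <- lapply(names(gofsets), function(id) {
    g <- gofsets[[id]]
    if (!nrow(g$windows)) {
      return(data.frame(sequence_id = id, minimum_frame = NA_integer_,
                        window_start = NA_integer_, window_end = NA_integer_,
                        retained_percentage = g$retained_percentage))
    }
    data.frame(sequence_id = id, minimum_frame = g$windows$minimum,
               window_start = g$windows$start, window_end = g$windows$end,
               retained_percentage = g$retained_percentage)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
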