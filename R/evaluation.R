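# Correctness criterion, K-sweep, frame-level ROC/AUC.

#' Default maximal expected micro-expression length
#'
#' Micro-expressions last up to about 0.32 s, so the maximal expected length
#' in frames scales with the frame rate: `N = round(0.32 * fps)`. This
#' reproduces the working values N = 64 at 200 fps and N = 8 at 25 fps.
#' `N/2` is the tolerance of the correctness criterion and `N/4` the default
#' instability distance `d`.
#'
#' @param fps Frame rate in Hz (> 0); vectorized.
#' @return Integer number of frames.
#' @export
default_N <- function(fps) {
  if (any(fps <= 0)) stop_input("fps must be > 0")
  as.integer(round_half_up(0.32 * fps))
}

#' Default temporal filter length for a frame rate
#'
#' Preattentive vision samples roughly 13 images per second, so the temporal
#' smoothing window scales with the frame rate: `max(2, round(fps / 25))`,
#' giving length 2 at 25 fps and 8 at 200 fps.
#'
#' @param fps Frame rate in Hz (> 0); vectorized.
#' @return Integer filter length (>= 2).
#' @export
default_phi_size <- function(fps) {
  if (any(fps <= 0)) stop_input("fps must be > 0")
  as.integer(pmax(2, round_half_up(fps / 25)))
}

#' Is a detected minimum a correct frozen-frame assignment?
#'
#' A minimum counts as correct when its distance from the annotated ME onset
#' or offset is strictly less than `N/2`: frozen frames are expected to hug
#' the expression boundaries, and half the maximal ME length is the
#' alignment slack granted.
#'
#' @param minimum Frame number of a detected minimum (vectorized).
#' @param ann One annotation row (list or single-row data frame with
#'   `onset`, `offset`, `N`).
#' @return Logical.
#' @export
is_correct <- function(minimum, ann) {
  pmin(abs(minimum - ann$onset), abs(minimum - ann$offset)) < ann$N / 2
}

#' Percentage of correct assignments as K grows
#'
#' For each `K`, a sequence counts as correct when any of its `K`
#' smallest-energy minima satisfies [is_correct()]. Reported percentages are
#' rounded to two decimals.
#'
#' @param per_sequence_minima Named list: for each sequence id, the integer
#'   vector of minima frame numbers in ascending energy order (the order
#'   returned by [select_top_k()] with large `K`).
#' @param annotations Annotation data frame as from [load_annotations()];
#'   sequences may contribute several rows (one per annotated ME), and a row
#'   counts as correct if any of the first `K` minima of its sequence is.
#' @param K_values Integer vector of K values to sweep (all >= 1).
#' @return Data frame with columns `K`, `n_correct`, `n_total`,
#'   `pct_correct`.
#' @export
k_sweep <- function(per_sequence_minima, annotations, K_values) {
  if (!length(K_values)) stop_input("K_values must not be empty")
  if (any(K_values < 1L)) stop_input("all K values must be >= 1")
  n_total <- nrow(annotations)
  rows <- lapply(as.integer(K_values), function(K) {
    hit <- vapply(seq_len(n_total), function(i) {
      ann <- annotations[i, ]
      mins <- per_sequence_minima[[as.character(ann$sequence_id)]]
      if (is.null(mins) || !length(mins)) return(FALSE)
      any(is_correct(utils::head(mins, K), ann))
    }, logical(1))
    data.frame(K = K, n_correct = sum(hit), n_total = n_total,
               pct_correct = round(100 * sum(hit) / n_total, 2))
  })
  do.call(rbind, rows)
}

# Prediction window of size N centered at a minimum: [t - floor(N/2),
# t + floor(N/2) - 1] for even N, symmetric for odd N; clipped to [1, T].
pred_window <- function(t, N, T_) {
  half <- N %/% 2L
  hi_off <- if (N %% 2L == 0L) half - 1L else half
  lo <- max(1L, t - half)
  hi <- min(T_, t + hi_off)
  if (lo > hi) integer() else lo:hi
}

#' Frame-level ROC curve and AUC over a sweep of K
#'
#' For each `K = 0, ..., max minima count`, the predicted-positive frames of
#' a sequence are the union of size-`N` windows centered at its `K`
#' smallest-energy minima; the ground-truth-positive frames are the closed
#' annotated intervals `[onset, offset]`. TP/FP/TN/FN are pooled frame-wise
#' over all sequences, the ROC is the resulting (FPR, TPR) path augmented
#' with (0,0) and (1,1), and the AUC is its trapezoid area. Both rates are
#' non-decreasing in `K` since windows only accumulate.
#'
#' @param per_sequence_minima Named list of minima frame numbers in
#'   ascending energy order, as in [k_sweep()].
#' @param annotations Annotation data frame; sequences without a clip length
#'   are skipped with a warning.
#' @param N Prediction window size in frames; defaults to the annotations'
#'   maximum `N`.
#' @param clip_lengths Named numeric vector or list mapping sequence id to
#'   clip length in frames.
#' @return An object of class `eval_result`: list with `roc` (data frame
#'   `K`, `TP`, `FP`, `TN`, `FN`, `TPR`, `FPR`), `auc`, `N`.
#' @export
roc_auc <- function(per_sequence_minima, annotations, N = NULL, clip_lengths) {
  seq_ids <- unique(as.character(annotations$sequence_id))
  have_len <- seq_ids %in% names(clip_lengths)
  if (any(!have_len)) {
    warning("skipping sequences without clip length: ",
            paste(seq_ids[!have_len], collapse = ", "))
    seq_ids <- seq_ids[have_len]
  }
  if (!length(seq_ids)) stop_input("no sequences with clip lengths to evaluate")
  if (is.null(N)) N <- max(annotations$N)
  N <- as.integer(N)

  per_seq <- lapply(seq_ids, function(id) {
    T_ <- as.integer(clip_lengths[[id]])
    ann <- annotations[as.character(annotations$sequence_id) == id, , drop = FALSE]
    pos <- logical(T_)
    for (i in seq_len(nrow(ann))) {
      pos[max(1L, ann$onset[i]):min(T_, ann$offset[i])] <- TRUE
    }
    list(T_ = T_, pos = pos,
         minima = per_sequence_minima[[id]] %||% integer())
  })
  K_max <- max(vapply(per_seq, function(s) length(s$minima), integer(1)), 0L)

  rows <- lapply(0:K_max, function(K) {
    tp <- fp <- tn <- fn <- 0L
    for (s in per_seq) {
      pred <- logical(s$T_)
      for (t in utils::head(s$minima, K)) {
        pred[pred_window(as.integer(t), N, s$T_)] <- TRUE
      }
      tp <- tp + sum(pred & s$pos); fp <- fp + sum(pred & !s$pos)
      tn <- tn + sum(!pred & !s$pos); fn <- fn + sum(!pred & s$pos)
    }
    data.frame(K = K, TP = tp, FP = fp, TN = tn, FN = fn,
               TPR = if (tp + fn > 0) tp / (tp + fn) else 0,
               FPR = if (fp + tn > 0) fp / (fp + tn) else 0)
  })
  roc <- do.call(rbind, rows)
  fpr <- c(0, roc$FPR, 1); tpr <- c(0, roc$TPR, 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(roc = roc, auc = auc, N = N), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: AUC %.4f over K = 0..%d (window size N = %d)\n",
              x$auc, max(x$roc$K), x$N))
  invisible(x)
}

#' Write an evaluation report
#'
#' Serializes a K-sweep table and/or an ROC result to JSON (and the tables
#' additionally to CSV next to it when `csv = TRUE`).
#'
#' @param sweep Data frame from [k_sweep()] (or `NULL`).
#' @param roc An `eval_result` from [roc_auc()] (or `NULL`).
#' @param path Output `.json` path.
#' @param csv Also write `*_ksweep.csv` / `*_roc.csv` alongside.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(sweep = NULL, roc = NULL, path, csv = TRUE) {
  out <- list()
  if (!is.null(sweep)) out$k_sweep <- sweep
  if (!is.null(roc)) out$roc <- list(points = roc$roc, auc = roc$auc, N = roc$N)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (csv) {
    stem <- sub("\\.json$", "", path)
    if (!is.null(sweep)) {
      utils::write.csv(sweep, paste0(stem, "_ksweep.csv"), row.names = FALSE, quote = FALSE)
    }
    if (!is.null(roc)) {
      utils::write.csv(roc$roc, paste0(stem, "_roc.csv"), row.names = FALSE, quote = FALSE)
    }
  }
  invisible(path)
}
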