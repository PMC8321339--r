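# End-to-end pipeline: scene partition -> ROI -> LL filtering -> sigma_F ->
# minima -> instability removal -> top-K -> GOFs; plus evaluation wrappers.

#' Run configuration with frame-rate-derived defaults
#'
#' Collects every tunable of the pipeline. Anything left `NULL` is derived
#' from the frame rate: temporal filter length via [default_phi_size()],
#' maximal ME length `N` via [default_N()], instability distance
#' `d = round(N/4)`, `K = 3` below 100 fps and 5 at high frame rates, GOF
#' half-widths 5/5 below 100 fps and 16/16 above.
#'
#' @param fps Frame rate in Hz.
#' @param rho_std Spatial Gaussian std in pixels (default 9, sized for a
#'   face ROI a few hundred pixels across; scale down for smaller frames).
#' @param truncate Spatial kernel truncation (multiples of `rho_std`).
#' @param phi_kind,phi_size Temporal kernel kind and length.
#' @param tau Instability energy threshold (fraction of energy range).
#' @param d Instability distance in frames.
#' @param N Maximal expected ME length in frames.
#' @param K Number of minima selected per scene.
#' @param half_before,half_after GOF half-widths in frames.
#' @param cut_threshold Scene-cut threshold, see [partition_scenes()].
#' @param user_cuts Optional explicit scene cuts.
#' @param verbose Log derived defaults and per-scene progress.
#' @return An object of class `run_config`.
#' @export
run_config <- function(fps, rho_std = 9, truncate = 3,
                       phi_kind = c("box", "gaussian"), phi_size = NULL,
                       tau = 0.1, d = NULL, N = NULL, K = NULL,
                       half_before = NULL, half_after = NULL,
                       cut_threshold = 0.1, user_cuts = NULL,
                       verbose = FALSE) {
  phi_kind <- match.arg(phi_kind)
  N <- as.integer(N %||% default_N(fps))
  phi_size <- as.integer(phi_size %||% default_phi_size(fps))
  d <- as.integer(d %||% max(1L, round_half_up(N / 4)))
  K <- as.integer(K %||% (if (fps >= 100) 5L else 3L))
  hb <- as.integer(half_before %||% (if (fps >= 100) 16L else 5L))
  ha <- as.integer(half_after %||% (if (fps >= 100) 16L else 5L))
  cfg <- structure(list(fps = fps, rho_std = rho_std, truncate = truncate,
                        phi_kind = phi_kind, phi_size = phi_size, tau = tau,
                        d = d, N = N, K = K, half_before = hb, half_after = ha,
                        cut_threshold = cut_threshold, user_cuts = user_cuts,
                        verbose = isTRUE(verbose)),
                   class = "run_config")
  minima_params(d = cfg$d, tau = cfg$tau, K = cfg$K)  # validates jointly
  if (cfg$verbose) {
    message(sprintf(
      "run_config: fps=%g rho_std=%g phi=%s/%d tau=%g d=%d N=%d K=%d gof=%d+%d",
      fps, rho_std, phi_kind, phi_size, tau, cfg$d, N, cfg$K, hb, ha))
  }
  cfg
}

#' Detect frozen frames and build GOFs
#'
#' The full detection pipeline on one clip: partition into stationary
#' scenes, restrict to the face ROI, apply the separable LL filter, compute
#' the stillness signal `sigma_F`, find its local minima, remove
#' instabilities, keep the `K` smallest per scene, and expand them into GOF
#' windows. Scenes shorter than `max(phi_size, 3)` frames are skipped.
#'
#' @param stack A [frame_stack()].
#' @param roi A [roi_spec()] or `NULL` for the whole frame.
#' @param config A [run_config()]; defaults to `run_config(stack$fps)`.
#' @return An object of class `spot_result`: list with `scenes` (data
#'   frame), `energy` (per-scene list of `sigma_F` [energy_signal()]s),
#'   `minima` (per-scene [merge_instabilities()] results), `ranked` (data
#'   frame of all merged minima ordered by ascending energy: `t`, `sigma`,
#'   `scene`), `selected` (frame numbers, ascending energy), `gofs`
#'   (per-scene [build_gofs()]), and `config`.
#' @export
spot_frozen_frames <- function(stack, roi = NULL, config = run_config(stack$fps)) {
  cropped <- crop_roi(stack, roi)
  scenes <- partition_scenes(cropped, config$cut_threshold, config$user_cuts)
  filt <- st_filter(config$rho_std, config$phi_kind, config$phi_size,
                    mode = "LL", truncate = config$truncate)
  energy <- list(); minima <- list(); gofs <- list(); ranked <- list()
  for (i in seq_len(nrow(scenes))) {
    s <- scenes$start[i]; e <- scenes$end[i]
    if (e - s + 1L < max(config$phi_size, 3L)) {
      if (config$verbose) message("scene ", i, " shorter than temporal filter; skipped")
      next
    }
    sub <- frame_stack(cropped$frames[, , s:e, drop = FALSE], cropped$fps,
                       t0 = cropped$t0 + s - 1L)
    F_ <- apply_separable(sub, filt)
    sigF <- spatial_std_signal(F_, "sigma_F")
    raw <- find_local_minima(sigF)
    mres <- merge_instabilities(raw, sigF, minima_params(config$d, config$tau, config$K))
    sel <- select_top_k(mres, config$K)
    key <- as.character(i)
    energy[[key]] <- sigF
    minima[[key]] <- mres
    gofs[[key]] <- build_gofs(sel, config$half_before, config$half_after,
                              clip = c(sub$t0, sub$t0 + (e - s)))
    if (nrow(mres$merged)) {
      ranked[[key]] <- data.frame(t = mres$merged$t, sigma = mres$merged$sigma,
                                  scene = i)
    }
  }
  if (!length(energy)) {
    stop_input("no scene is long enough for the temporal filter size ",
               config$phi_size)
  }
  ranked <- if (length(ranked)) {
    r <- do.call(rbind, ranked)
    r <- r[order(r$sigma, r$t), ]
    rownames(r) <- NULL
    r
  } else data.frame(t = integer(), sigma = numeric(), scene = integer())
  selected <- utils::head(ranked$t, config$K)
  structure(list(scenes = scenes, energy = energy, minima = minima,
                 ranked = ranked, selected = selected, gofs = gofs,
                 config = config),
            class = "spot_result")
}

#' @export
print.spot_result <- function(x, ...) {
  n_min <- sum(vapply(x$minima, function(m) nrow(m$merged), integer(1)))
  cat(sprintf("spot_result: %d scene(s), %d merged minima, selected frames: %s\n",
              nrow(x$scenes), n_min,
              paste(x$selected, collapse = " ")))
  invisible(x)
}

#' Spot frozen frames from an input source and write reports
#'
#' Command-style wrapper: loads frames, runs [spot_frozen_frames()], and
#' writes `energy.csv` (frame, sigma for every analyzed scene),
#' `minima.csv` (merged minima with energies) and `gof_report.csv` into
#' `out_dir`.
#'
#' @param source,kind,fps Passed to [load_frames()].
#' @param roi A [roi_spec()] or `NULL`.
#' @param config A [run_config()]; default derived from `fps`.
#' @param out_dir Output directory (created if missing).
#' @param sequence_id Sequence id written into the reports; defaults to the
#'   base name of `source`.
#' @return Invisibly, the `spot_result`.
#' @export
cmd_spot <- function(source, kind = "image_dir", fps, roi = NULL,
                     config = NULL, out_dir = ".",
                     sequence_id = basename(source)) {
  stack <- load_frames(source, kind, fps = fps)
  config <- config %||% run_config(fps)
  res <- spot_frozen_frames(stack, roi, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  energy <- do.call(rbind, lapply(res$energy, as.data.frame))
  utils::write.csv(energy, file.path(out_dir, "energy.csv"),
                   row.names = FALSE, quote = FALSE)
  minima <- cbind(sequence_id = rep(sequence_id, nrow(res$ranked)),
                  res$ranked)
  utils::write.csv(minima, file.path(out_dir, "minima.csv"),
                   row.names = FALSE, quote = FALSE)
  names(res$gofs) <- paste0("scene", names(res$gofs))
  write_gof_report(res$gofs, file.path(out_dir, "gof_report.csv"))
  invisible(res)
}

#' Evaluate spotting results against annotations
#'
#' Runs the correctness K-sweep and the frame-level ROC/AUC for a set of
#' per-sequence minima lists, and optionally writes the combined report.
#'
#' @param per_sequence_minima Named list of minima in ascending energy
#'   order.
#' @param annotations Annotation data frame ([load_annotations()] layout).
#' @param clip_lengths Named vector of clip lengths.
#' @param K_values K values for the sweep (must be non-empty).
#' @param N ROC window size; default from annotations.
#' @param out Optional path of a JSON report ([write_eval_report()]).
#' @return List with `sweep` (data frame) and `roc` (`eval_result`).
#' @export
cmd_evaluate <- function(per_sequence_minima, annotations, clip_lengths,
                         K_values = c(1, 2, 3, 5, 8, 10), N = NULL,
                         out = NULL) {
  sweep <- k_sweep(per_sequence_minima, annotations, K_values)
  roc <- roc_auc(per_sequence_minima, annotations, N, clip_lengths)
  if (!is.null(out)) write_eval_report(sweep, roc, out)
  list(sweep = sweep, roc = roc)
}

#' Run the pipeline over a synthetic benchmark and evaluate it
#'
#' Convenience wrapper used by the package's own validation: spots frozen
#' frames in every clip of a [make_benchmark()] result and evaluates the
#' detections against the planted burst annotations.
#'
#' @param bench A [make_benchmark()] result.
#' @param config A [run_config()]; the default scales the spatial filter to
#'   the 64-px synthetic face (`rho_std = 3`).
#' @param K_values K values for the sweep.
#' @return List with `sweep`, `roc`, and `minima` (the per-clip ranked
#'   minima lists).
#' @export
evaluate_benchmark <- function(bench,
                               config = run_config(bench$annotations$fps[1],
                                                   rho_std = 3),
                               K_values = c(1, 2, 3, 5)) {
  minima <- lapply(bench$clips, function(cl) {
    spot_frozen_frames(cl$stack, config = config)$ranked$t
  })
  ev <- cmd_evaluate(minima, bench$annotations, bench$clip_lengths,
                     K_values = K_values)
  c(ev, list(minima = minima))
}
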