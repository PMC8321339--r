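# Ground-truthed synthetic frame stacks: a face-like blob with facial-feature
# patches, ongoing sub-pixel micro-motion, short motion bursts (ME
# surrogates), exactly frozen plateaus, sensor noise and luminance drift.
#
# Motion is rendered as *linearized* sub-pixel displacement: translating a
# pattern q by delta changes the frame by -delta * (directional derivative of
# q) to first order, and it is exactly this appearance-change component that
# survives the heavy spatial low-pass of the detector (an exact rigid shift
# only perturbs the energy signal at second order, via temporal motion
# blur). Burst displacement points toward the face centre (a contraction),
# which makes the burst a positive excursion of sigma_F; baseline jitter uses
# two signed displacement amplitudes (horizontal/vertical) shared by all
# feature patches, frozen to zero inside plateaus. See the methods vignette
# for the full reasoning.

gauss_field <- function(H, W, cy, cx, sigma) {
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  list(g = exp(-(yy^2 + xx^2) / (2 * sigma^2)), yy = yy, xx = xx)
}

# -d/du applied to a Gaussian patch of given contrast: the first-order frame
# change per pixel of displacement along unit direction (uy, ux).
lin_disp_pattern <- function(H, W, cy, cx, sigma, contrast, uy, ux) {
  f <- gauss_field(H, W, cy, cx, sigma)
  contrast * (uy * f$yy + ux * f$xx) / sigma^2 * f$g
}

smooth_unit_noise <- function(n, smooth_std = 2) {
  pad <- ceiling(3 * smooth_std)
  z <- stats::rnorm(n + 2L * pad)
  k <- exp(-seq.int(-pad, pad)^2 / (2 * smooth_std^2))
  k <- k / sum(k)
  s <- stats::convolve(z, rev(k), type = "filter")
  s <- s[seq_len(n)]
  s / stats::sd(s)
}

#' Specification of a synthetic clip
#'
#' Describes a clip of `T` frames of a static scene containing a face
#' surrogate (smooth Gaussian blob plus four higher-contrast feature
#' patches), with:
#' * `bursts`: short micro-expression surrogates, each a list
#'   `(start, end, amplitude)` -- a half-sine displacement of an interior
#'   patch toward the face centre, `amplitude` in pixels;
#' * `plateaus`: exactly-frozen intervals `(start, end)` in which all
#'   deterministic motion is suspended (the pose is bit-identical before
#'   noise);
#' * `jitter_amp`: RMS (pixels) of the ongoing two-component head
#'   micro-motion present outside plateaus;
#' * `noise_std`: per-pixel Gaussian sensor noise (0--255 scale), redrawn
#'   every frame -- except inside plateaus when `exact_freeze = TRUE`;
#' * `drift_rate`: global luminance drift per frame, applied to all frames
#'   (a spatially constant offset, which the energy signal is invariant to).
#'
#' @param T Number of frames (>= 8).
#' @param fps Frame rate in Hz.
#' @param frame_shape `c(H, W)` in pixels.
#' @param blob List `center` (c(y, x)), `radius`, `contrast` of the face
#'   surrogate; the blob's Gaussian std is `radius / 2`.
#' @param bursts List of lists `(start, end, amplitude)`.
#' @param plateaus List of two-element vectors `(start, end)`; pairwise
#'   disjoint and disjoint from bursts.
#' @param noise_std Noise level (>= 0).
#' @param drift_rate Luminance change per frame.
#' @param jitter_amp Baseline micro-motion RMS in pixels (0 disables).
#' @param exact_freeze Zero the noise inside plateaus so frozen frames are
#'   bit-identical even with `noise_std > 0`.
#' @param seed RNG seed (mandatory; the generator has no unseeded mode).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(T = 120L, fps = 25, frame_shape = c(64L, 64L),
                           blob = list(center = NULL, radius = 18, contrast = 80),
                           bursts = list(), plateaus = list(),
                           noise_std = 2, drift_rate = 0, jitter_amp = 1.2,
                           exact_freeze = FALSE, seed) {
  if (missing(seed)) stop_input("'seed' is mandatory: no unseeded generation")
  T <- as.integer(T)
  if (T < 8L) stop_input("T must be >= 8")
  if (noise_std < 0) stop_input("noise_std must be >= 0")
  if (is.null(blob$center)) blob$center <- (frame_shape + 1) / 2
  iv <- function(b) c(as.integer(b[[1]]), as.integer(b[[2]]))
  for (b in bursts) {
    r <- iv(b)
    if (r[1] > r[2] || r[1] < 1L || r[2] > T) stop_input("burst outside [1, T] or empty")
  }
  pl <- lapply(plateaus, iv)
  for (p in pl) {
    if (p[1] > p[2] || p[1] < 1L || p[2] > T) stop_input("plateau outside [1, T] or empty")
  }
  if (length(pl) > 1L) {
    o <- order(vapply(pl, `[`, integer(1), 1L))
    pl <- pl[o]
    for (i in seq_len(length(pl) - 1L)) {
      if (pl[[i + 1L]][1] <= pl[[i]][2]) stop_input("plateaus must be pairwise disjoint")
    }
  }
  for (b in bursts) {
    r <- iv(b)
    for (p in pl) {
      if (r[1] <= p[2] && p[1] <= r[2]) {
        stop_input("plateau [", p[1], ",", p[2], "] overlaps burst [",
                   r[1], ",", r[2], "]")
      }
    }
  }
  structure(list(T = T, fps = fps, frame_shape = as.integer(frame_shape),
                 blob = blob, bursts = bursts, plateaus = pl,
                 noise_std = noise_std, drift_rate = drift_rate,
                 jitter_amp = jitter_amp, exact_freeze = isTRUE(exact_freeze),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Jitter envelope: exactly 0 inside plateaus, raised-cosine ramps of
# `ramp` frames just outside them, 1 elsewhere.
plateau_envelope <- function(T, plateaus, ramp = 3L) {
  m <- rep(1, T)
  for (p in plateaus) {
    m[p[1]:p[2]] <- 0
    for (j in seq_len(ramp)) {
      w <- (1 - cos(pi * j / (ramp + 1))) / 2
      lo <- p[1] - j; hi <- p[2] + j
      if (lo >= 1L) m[lo] <- min(m[lo], w)
      if (hi <= T) m[hi] <- min(m[hi], w)
    }
  }
  m
}

#' Generate a synthetic clip with ground truth
#'
#' Renders the scene described by a [synthetic_spec()]: static background and
#' face surrogate, ongoing micro-motion outside the frozen plateaus, planted
#' motion bursts, luminance drift and sensor noise. Fully reproducible from
#' the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `stack` (a [frame_stack()]) and `truth`, a list with
#'   `bursts` (data frame `onset`, `offset`), `plateaus` (data frame
#'   `start`, `end`) and `still` (per-frame logical flag, `TRUE` inside
#'   plateaus).
#' @export
generate_sequence <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$frame_shape[1]; W <- spec$frame_shape[2]
  T <- spec$T
  cy <- spec$blob$center[1]; cx <- spec$blob$center[2]
  sig_b <- spec$blob$radius / 2

  with_seed(spec$seed, {
    base <- 100 + spec$blob$contrast * gauss_field(H, W, cy, cx, sig_b)$g
    # four facial-feature patches (eye/nostril surrogates), fixed geometry
    off <- spec$blob$radius / 3
    locs <- rbind(c(cy - off, cx - off), c(cy - off, cx + off),
                  c(cy + off * 0.8, cx - off * 0.6), c(cy + off * 0.8, cx + off * 0.6))
    sig_p <- 2.5
    cp <- spec$blob$contrast
    for (i in seq_len(nrow(locs))) {
      base <- base + 0.5 * cp * gauss_field(H, W, locs[i, 1], locs[i, 2], sig_p)$g
    }
    # Baseline micro-motion. A live face is never at its neutral
    # minimum-activity pose except when deliberately frozen, so the baseline
    # is a strictly positive "tension" level a1(t) driving an inward
    # displacement of all feature patches (which couples linearly to
    # sigma_F), plus a smaller zero-mean horizontal wobble a2(t).
    j_in <- matrix(0, H, W); j_x <- matrix(0, H, W)
    for (i in seq_len(nrow(locs))) {
      u <- c(cy, cx) - locs[i, ]; u <- u / sqrt(sum(u^2))
      j_in <- j_in + lin_disp_pattern(H, W, locs[i, 1], locs[i, 2], sig_p, cp, u[1], u[2])
      j_x <- j_x + lin_disp_pattern(H, W, locs[i, 1], locs[i, 2], sig_p, cp, 0, 1)
    }
    env <- plateau_envelope(T, spec$plateaus)
    if (spec$jitter_amp > 0) {
      a1 <- spec$jitter_amp * pmax(0.2, 1 + 0.6 * smooth_unit_noise(T)) * env
      a2 <- 0.4 * spec$jitter_amp * smooth_unit_noise(T) * env
    } else {
      a1 <- a2 <- rep(0, T)
    }
    # bursts: contraction toward the face centre at a random interior spot
    burst_pat <- vector("list", length(spec$bursts))
    burst_w <- matrix(0, nrow = T, ncol = length(spec$bursts))
    for (k in seq_along(spec$bursts)) {
      b <- spec$bursts[[k]]
      s <- as.integer(b[[1]]); e <- as.integer(b[[2]])
      amp <- if (length(b) >= 3L) as.numeric(b[[3]]) else 1
      ang <- stats::runif(1, 0, 2 * pi)
      r <- stats::runif(1, 0.15, 0.45) * spec$blob$radius
      py <- cy + r * sin(ang); px <- cx + r * cos(ang)
      # unit vector from patch toward the blob centre
      u <- c(cy - py, cx - px); u <- u / sqrt(sum(u^2))
      burst_pat[[k]] <- amp * lin_disp_pattern(H, W, py, px, sig_p, cp, u[1], u[2])
      L <- e - s + 1L
      burst_w[s:e, k] <- sin(pi * seq_len(L) / (L + 1L))
    }

    frames <- array(0, dim = c(H, W, T))
    for (t in seq_len(T)) {
      fr <- base + a1[t] * j_in + a2[t] * j_x
      for (k in seq_along(burst_pat)) {
        if (burst_w[t, k] != 0) fr <- fr + burst_w[t, k] * burst_pat[[k]]
      }
      frames[, , t] <- fr
    }
    # freeze plateau poses exactly (envelope already zeroes the jitter, and
    # bursts cannot overlap; copying the first plateau frame makes the
    # intent explicit and bit-exact)
    for (p in spec$plateaus) {
      if (p[2] > p[1]) for (t in (p[1] + 1L):p[2]) frames[, , t] <- frames[, , p[1]]
    }
    if (spec$drift_rate != 0) {
      for (t in seq_len(T)) frames[, , t] <- frames[, , t] + spec$drift_rate * t
    }
    if (spec$noise_std > 0) {
      still <- rep(FALSE, T)
      for (p in spec$plateaus) still[p[1]:p[2]] <- TRUE
      for (t in seq_len(T)) {
        if (spec$exact_freeze && still[t]) next
        frames[, , t] <- frames[, , t] +
          matrix(stats::rnorm(H * W, sd = spec$noise_std), H, W)
      }
    }
    frames <- pmin(pmax(frames, 0), 255)

    still <- rep(FALSE, T)
    for (p in spec$plateaus) still[p[1]:p[2]] <- TRUE
    truth <- list(
      bursts = if (length(spec$bursts)) {
        data.frame(onset = vapply(spec$bursts, function(b) as.integer(b[[1]]), integer(1)),
                   offset = vapply(spec$bursts, function(b) as.integer(b[[2]]), integer(1)))
      } else data.frame(onset = integer(), offset = integer()),
      plateaus = if (length(spec$plateaus)) {
        data.frame(start = vapply(spec$plateaus, `[`, integer(1), 1L),
                   end = vapply(spec$plateaus, `[`, integer(1), 2L))
      } else data.frame(start = integer(), end = integer()),
      still = still)
    list(stack = frame_stack(frames, fps = spec$fps), truth = truth)
  })
}

#' Generate a ground-truthed benchmark of clips
#'
#' Each clip contains one or two motion bursts (4--5 frames, amplitude
#' 0.8--1.5 px), each flanked by an exactly-frozen plateau of 4--5 frames
#' immediately before, after, or on both sides (the three concealment
#' patterns seen in spontaneous footage: freezing into the expression,
#' freezing out of it, or both). Placement is randomized but deterministic
#' from `seed`; annotations carry the surrogate onset/offset and
#' `N = default_N(fps)`.
#'
#' @param n_clips Number of clips (>= 1).
#' @param seed RNG seed.
#' @param fps Frame rate (default 25).
#' @param noise_std,drift_rate,jitter_amp,exact_freeze Passed to
#'   [synthetic_spec()].
#' @param T Frames per clip.
#' @return A list with `clips` (list of [generate_sequence()] outputs, named
#'   by sequence id), `annotations` (data frame in [load_annotations()]
#'   layout, one row per burst), and `clip_lengths` (named vector).
#' @export
make_benchmark <- function(n_clips, seed, fps = 25, noise_std = 2,
                           drift_rate = 0, jitter_amp = 1.2,
                           exact_freeze = FALSE, T = 120L) {
  if (n_clips < 1L) stop_input("n_clips must be >= 1")
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_clips)
    clips <- list(); ann <- list()
    for (i in seq_len(n_clips)) {
      n_b <- sample(c(1L, 2L), 1L, prob = c(0.7, 0.3))
      s1 <- sample(25:50, 1L)
      starts <- if (n_b == 2L) c(s1, s1 + sample(38:48, 1L)) else s1
      bursts <- list(); plats <- list()
      for (s in starts) {
        len <- sample(4:5, 1L)
        e <- s + len - 1L
        bursts[[length(bursts) + 1L]] <- list(s, e, stats::runif(1, 0.8, 1.5))
        mode <- sample(c("both", "before", "after"), 1L, prob = c(0.8, 0.1, 0.1))
        pl <- sample(3:4, 1L)
        if (mode %in% c("both", "before")) {
          plats[[length(plats) + 1L]] <- c(s - pl, s - 1L)
        }
        if (mode %in% c("both", "after")) {
          plats[[length(plats) + 1L]] <- c(e + 1L, e + pl)
        }
      }
      spec <- synthetic_spec(T = T, fps = fps, bursts = bursts, plateaus = plats,
                             noise_std = noise_std, drift_rate = drift_rate,
                             jitter_amp = jitter_amp, exact_freeze = exact_freeze,
                             seed = sub_seeds[i])
      id <- sprintf("clip%03d", i)
      clips[[id]] <- generate_sequence(spec)
      tb <- clips[[id]]$truth$bursts
      ann[[id]] <- data.frame(sequence_id = id, onset = tb$onset,
                              apex = NA_integer_, offset = tb$offset,
                              fps = fps, N = default_N(fps))
    }
    annotations <- do.call(rbind, ann)
    rownames(annotations) <- NULL
    list(clips = clips, annotations = annotations,
         clip_lengths = stats::setNames(rep(T, n_clips), names(clips)))
  })
}

#' Write a benchmark clip to disk in the package's I/O formats
#'
#' Writes the frames as a PNG image directory plus `ground_truth.csv`
#' (plateau intervals and per-frame stillness flag) and `annotations.csv`
#' (the [load_annotations()] format).
#'
#' @param clip A [generate_sequence()] output.
#' @param dir Output directory.
#' @param sequence_id Sequence id used in the CSVs.
#' @return Invisibly, `dir`.
#' @export
write_synthetic_clip <- function(clip, dir, sequence_id = "synthetic") {
  write_frames(clip$stack, file.path(dir, "frames"))
  gt <- data.frame(frame = seq_along(clip$truth$still), still = clip$truth$still)
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE, quote = FALSE)
  tb <- clip$truth$bursts
  ann <- data.frame(sequence_id = sequence_id, onset = tb$onset,
                    apex = NA_integer_, offset = tb$offset,
                    fps = clip$stack$fps)
  utils::write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
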