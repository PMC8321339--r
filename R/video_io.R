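# Frame-stack input, ROI cropping, scene partitioning, annotation tables.

#' Construct a frame stack
#'
#' A frame stack is the basic video container of the package: an ordered set
#' of grayscale frames with a frame rate. Frames are stored as a 3-D array
#' indexed `[y, x, t]` with luminance values in `[0, 255]`. Frame numbering
#' is 1-based and, via `t0`, can be anchored to the numbering of the original
#' video so that reported minima match dataset annotations.
#'
#' @param frames 3-D numeric array `[y, x, t]`, values in `[0, 255]`.
#' @param fps Frame rate in Hz (> 0).
#' @param t0 Frame number of the first frame in original-video numbering.
#' @return An object of class `frame_stack` with elements `frames`, `fps`,
#'   `t0`.
#' @export
frame_stack <- function(frames, fps, t0 = 1L) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop_input("'frames' must be a 3-D array [y, x, t]")
  }
  if (dim(frames)[3] < 2L) stop_input("a frame stack needs at least 2 frames")
  if (!all(is.finite(frames))) stop_input("frame values must be finite")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop_input("'fps' must be a single positive number")
  }
  structure(list(frames = frames, fps = as.numeric(fps), t0 = as.integer(t0)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d frames of %dx%d px, %.6g fps, first frame #%d\n",
              d[3], d[1], d[2], x$fps, x$t0))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]

#' @export
dim.frame_stack <- function(x) dim(x$frames)

# Rec.601 luma weights, the conventional luminance conversion for video.
to_gray <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  nc <- dim(img)[3]
  if (nc == 1L) return(img[, , 1L])
  # channels beyond the third (alpha) are ignored
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_input("unsupported image format '.", ext, "' for ", path,
               " (supported: png, tif/tiff)"))
  to_gray(img) * 255
}

#' Load a frame stack from disk
#'
#' Reads either a directory of single-frame images (one file per frame,
#' lexicographic order -- the layout used by CASME II-style datasets) or a
#' multi-page TIFF acting as a video container. All frames are converted to
#' luminance in `[0, 255]`. General video containers (MP4 etc.) must be
#' exploded into an image directory first, e.g. with ffmpeg.
#'
#' @param source Path to a directory (`kind = "image_dir"`) or a multi-page
#'   TIFF file (`kind = "video_file"`).
#' @param kind `"image_dir"` or `"video_file"`.
#' @param fps Frame rate in Hz; required (image files and TIFF carry no
#'   frame-rate metadata).
#' @param as_gray Convert color frames to Rec.601 luminance (always done;
#'   kept as an explicit flag so intent is visible at call sites).
#' @param t0 Frame number of the first loaded frame.
#' @return A [frame_stack()].
#' @export
load_frames <- function(source, kind = c("image_dir", "video_file"), fps,
                        as_gray = TRUE, t0 = 1L) {
  kind <- match.arg(kind)
  if (missing(fps)) stop_input("'fps' is required: image sources carry no frame-rate metadata")
  if (!file.exists(source)) stop_input("source does not exist: ", source)
  if (!isTRUE(as_gray)) stop_input("only grayscale analysis is supported; use as_gray = TRUE")
  if (kind == "image_dir") {
    files <- list.files(source, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- files[order(basename(files), method = "radix")]
    if (length(files) < 2L) {
      stop_input("image directory must contain at least 2 readable frames: ", source)
    }
    imgs <- lapply(files, read_one_image)
  } else {
    pages <- tiff::readTIFF(source, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L) stop_input("video file must decode to at least 2 frames: ", source)
    imgs <- lapply(pages, function(p) to_gray(p) * 255)
  }
  shp <- dim(imgs[[1]])
  same <- vapply(imgs, function(m) identical(dim(m), shp), logical(1))
  if (!all(same)) {
    stop_input("frames have inconsistent shapes (first offender: frame ",
               which(!same)[1], ")")
  }
  frames <- array(unlist(imgs, use.names = FALSE), dim = c(shp[1], shp[2], length(imgs)))
  frame_stack(frames, fps = fps, t0 = t0)
}

#' Write a frame stack as a PNG image directory
#'
#' Inverse of [load_frames()] for the `image_dir` kind; used by the synthetic
#' generator's CLI and in round-trip tests. Values are clamped to `[0, 255]`
#' and quantized to 16-bit PNG.
#'
#' @param stack A [frame_stack()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix; frames are numbered with 5 digits.
#' @return Invisibly, the vector of file paths written.
#' @export
write_frames <- function(stack, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tt <- n_frames(stack)
  paths <- file.path(dir, sprintf("%s_%05d.png", prefix, seq_len(tt)))
  for (t in seq_len(tt)) {
    img <- pmin(pmax(stack$frames[, , t] / 255, 0), 1)
    png::writePNG(img, paths[t], dpi = NULL)
  }
  invisible(paths)
}

#' Rectangular region of interest
#'
#' The face region the analysis is restricted to. Coordinates are 0-based
#' pixel offsets of the top-left corner, matching the common
#' `x0,y0,width,height` CLI convention.
#'
#' @param x0,y0 Top-left corner (0-based pixels).
#' @param width,height Extent in pixels (>= 1).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(x0, y0, width, height) {
  if (width < 1L || height < 1L) stop_input("ROI width and height must be >= 1")
  if (x0 < 0L || y0 < 0L) stop_input("ROI corner must be non-negative")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi_spec")
}

#' Crop a frame stack to a region of interest
#'
#' Restricts every frame to the rectangle given by `roi`; the time axis is
#' untouched. All downstream energy computations see only pixels inside the
#' ROI.
#'
#' @param stack A [frame_stack()].
#' @param roi A [roi_spec()], or `NULL` for the identity.
#' @return A cropped [frame_stack()].
#' @export
crop_roi <- function(stack, roi) {
  if (is.null(roi)) return(stack)
  d <- dim(stack$frames)
  if (roi$x0 + roi$width > d[2] || roi$y0 + roi$height > d[1]) {
    stop_input("ROI [", roi$x0, ",", roi$y0, " ", roi$width, "x", roi$height,
               "] exceeds frame bounds ", d[2], "x", d[1])
  }
  rows <- (roi$y0 + 1L):(roi$y0 + roi$height)
  cols <- (roi$x0 + 1L):(roi$x0 + roi$width)
  frame_stack(stack$frames[rows, cols, , drop = FALSE], stack$fps, stack$t0)
}

#' Partition a stack into stationary scenes
#'
#' Declares a scene cut between consecutive frames whose mean absolute
#' luminance difference, normalized by the 255 range, exceeds
#' `cut_threshold`. The clips the method is designed for are single-scene,
#' so the detector only needs to be safe for hard cuts; an explicit
#' `user_cuts` list takes precedence when given.
#'
#' @param stack A [frame_stack()].
#' @param cut_threshold Fraction in (0, 1]; default 0.1.
#' @param user_cuts Optional strictly increasing 1-based frame indices at
#'   which new scenes start.
#' @return A data frame with columns `start`, `end` (1-based, inclusive);
#'   rows are disjoint and cover `[1, T]`.
#' @export
partition_scenes <- function(stack, cut_threshold = 0.1, user_cuts = NULL) {
  tt <- n_frames(stack)
  if (!is.null(user_cuts)) {
    uc <- as.integer(user_cuts)
    if (any(diff(uc) <= 0L)) stop_input("user_cuts must be strictly increasing")
    if (any(uc < 2L | uc > tt)) stop_input("user_cuts must lie in [2, ", tt, "]")
    starts <- c(1L, uc)
  } else {
    if (cut_threshold <= 0 || cut_threshold > 1) {
      stop_input("cut_threshold must be in (0, 1]")
    }
    diffs <- vapply(seq_len(tt - 1L), function(t) {
      mean(abs(stack$frames[, , t + 1L] - stack$frames[, , t])) / 255
    }, numeric(1))
    starts <- c(1L, which(diffs > cut_threshold) + 1L)
  }
  ends <- c(starts[-1L] - 1L, tt)
  data.frame(start = starts, end = ends)
}

#' Load an annotation table
#'
#' Reads a CSV of per-sequence micro-expression annotations with header
#' `sequence_id,onset,apex,offset,fps[,N]` (the layout of CASME II / MEVIEW
#' style ground truth; `apex` entries may be empty). The maximal expected ME
#' length `N` is taken from the optional `N` column or derived from the frame
#' rate with [default_N()].
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `sequence_id`, `onset`, `apex` (may be
#'   `NA`), `offset`, `fps`, `N`, one row per annotated ME.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop_input("annotation file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "onset", "offset", "fps")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input("annotation CSV lacks columns: ", paste(miss, collapse = ", "))
  if (!"apex" %in% names(df)) df$apex <- NA_integer_
  df$onset <- as.integer(df$onset)
  df$apex <- suppressWarnings(as.integer(df$apex))
  df$offset <- as.integer(df$offset)
  if ("N" %in% names(df)) {
    df$N <- as.integer(df$N)
    fill <- is.na(df$N)
    df$N[fill] <- default_N(df$fps[fill])
  } else {
    df$N <- default_N(df$fps)
  }
  for (i in seq_len(nrow(df))) {
    ap <- df$apex[i]
    bad <- df$offset[i] < df$onset[i] ||
      (!is.na(ap) && (ap < df$onset[i] || df$offset[i] < ap))
    if (bad) {
      stop_input("row ", i, " (sequence '", df$sequence_id[i],
                 "'): requires onset <= apex <= offset")
    }
    if (df$N[i] < 2L) stop_input("row ", i, ": N must be >= 2")
  }
  df[c("sequence_id", "onset", "apex", "offset", "fps", "N")]
}
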