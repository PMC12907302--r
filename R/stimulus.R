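# Grayscale movie stimuli: container, synthetic fixture generators, and
# numbered-image-stack I/O. Gray levels live in [1, 255] (no color).

#' Grayscale movie stimulus
#'
#' @param frames numeric array T x H x W of gray levels in [1, 255] (values
#'   outside are clamped).
#' @param fps frame rate, Hz (> 0).
#' @param px_size spatial calibration: length of one pixel side, in
#'   \code{modality} units per pixel.
#' @param modality one of \code{"mm"}, \code{"degrees"}, \code{"pixels"}.
#' @return object of class \code{"stimulus"}.
#' @export
stimulus <- function(frames, fps, px_size = 0.01,
                     modality = c("mm", "degrees", "pixels")) {
  modality <- match.arg(modality)
  stopifnot(fps > 0, px_size > 0)
  if (length(dim(frames)) == 2L) {
    frames <- array(frames, dim = c(1L, dim(frames)))
  }
  stopifnot(length(dim(frames)) == 3L, all(dim(frames) >= 1L))
  frames[] <- pmin(pmax(frames, 1), 255)
  structure(
    list(frames = frames, fps = fps, px_size = px_size, modality = modality),
    class = "stimulus"
  )
}

#' @export
print.stimulus <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<stimulus> %d frames of %dx%d px @ %g fps (%g %s/px), gray [%g, %g]\n",
    d[1], d[2], d[3], x$fps, x$px_size, x$modality,
    min(x$frames), max(x$frames)))
  invisible(x)
}

#' Number of frames / duration of a stimulus
#' @param stim a [stimulus()].
#' @return frame count (integer) / duration in seconds.
#' @export
n_frames <- function(stim) dim(stim$frames)[1]

#' @rdname n_frames
#' @export
stim_duration <- function(stim) n_frames(stim) / stim$fps

#' Moving-bar stimulus
#'
#' A bright vertical bar sweeping horizontally over a dark background: the
#' leading edge sits at \code{x0 + speed * t} (pixel units, pixel centers at
#' 0, 1, ...), the bar covering \code{width} pixels behind it.
#'
#' @param width bar width, px (> 0, must not exceed the frame width).
#' @param speed sweep speed, px/s.
#' @param duration movie length, s.
#' @param fps frame rate, Hz.
#' @param size frame size \code{c(H, W)} in px.
#' @param x0 leading-edge start position, px.
#' @param bar_level,bg_level gray levels of bar and background.
#' @param px_size,modality spatial calibration (see [stimulus()]).
#' @return a [stimulus()] with \code{round(duration * fps)} frames.
#' @export
make_moving_bar <- function(width, speed, duration, fps, size = c(32, 32),
                            x0 = 0, bar_level = 255, bg_level = 1,
                            px_size = 0.01, modality = "mm") {
  stopifnot(width > 0, duration > 0, fps > 0)
  if (width > size[2]) {
    stop(validation_error("bar is wider than the frame"))
  }
  nt <- round(duration * fps)
  frames <- array(bg_level, dim = c(nt, size[1], size[2]))
  xs <- seq_len(size[2]) - 1  # pixel center coordinates
  for (k in seq_len(nt)) {
    t <- (k - 1) / fps
    edge <- x0 + speed * t
    inbar <- xs > (edge - width) & xs <= edge
    if (any(inbar)) frames[k, , inbar] <- bar_level
  }
  stimulus(frames, fps, px_size, modality)
}

#' Full-field stimulus
#' @param level uniform gray level.
#' @param duration movie length, s.
#' @param fps frame rate, Hz.
#' @param size frame size \code{c(H, W)}.
#' @inheritParams make_moving_bar
#' @return a [stimulus()].
#' @export
make_full_field <- function(level, duration, fps, size = c(32, 32),
                            px_size = 0.01, modality = "mm") {
  nt <- round(duration * fps)
  stimulus(array(level, dim = c(nt, size[1], size[2])), fps, px_size,
           modality)
}

#' Drifting sinusoidal grating
#'
#' \code{I(x, t) = mean_level + amplitude * sin(2 pi (f_s x - f_t t))},
#' clamped to the gray range; vertical stripes drifting along x.
#'
#' @param spatial_freq cycles per px.
#' @param temporal_freq drift rate, Hz.
#' @param duration,fps,size,px_size,modality as in [make_moving_bar()].
#' @param mean_level,amplitude gray-level mean and modulation depth.
#' @return a [stimulus()].
#' @export
make_grating <- function(spatial_freq, temporal_freq, duration, fps,
                         size = c(32, 32), mean_level = 128, amplitude = 100,
                         px_size = 0.01, modality = "mm") {
  stopifnot(spatial_freq > 0, duration > 0, fps > 0)
  nt <- round(duration * fps)
  xs <- seq_len(size[2]) - 1
  frames <- array(0, dim = c(nt, size[1], size[2]))
  for (k in seq_len(nt)) {
    t <- (k - 1) / fps
    row <- mean_level + amplitude * sin(2 * pi * (spatial_freq * xs -
                                                    temporal_freq * t))
    frames[k, , ] <- matrix(row, nrow = size[1], ncol = size[2],
                            byrow = TRUE)
  }
  stimulus(frames, fps, px_size, modality)
}

#' Load a stimulus from a numbered image stack
#'
#' Reads every \code{.png}/\code{.tif}/\code{.tiff} file in a directory in
#' lexicographic order (zero-pad frame numbers). RGB frames are converted to
#' grayscale by channel mean; intensities in [0, 1] are scaled to gray
#' levels and clamped to [1, 255]. If the directory holds a
#' \code{manifest.json} (as written by [save_stimulus()]), fps and
#' calibration are taken from it; arguments override.
#'
#' @param path directory of image frames.
#' @param fps,px_size,modality stimulus metadata (used when no manifest).
#' @return a [stimulus()].
#' @export
load_stimulus <- function(path, fps = NULL, px_size = NULL, modality = NULL) {
  if (!dir.exists(path)) {
    stop(validation_error(sprintf("stimulus directory '%s' does not exist",
                                  path)))
  }
  manifest <- file.path(path, "manifest.json")
  meta <- if (file.exists(manifest)) {
    jsonlite::read_json(manifest, simplifyVector = TRUE)
  } else list()
  fps <- fps %||% meta$fps %||% 30
  px_size <- px_size %||% meta$px_size %||% 0.01
  modality <- modality %||% meta$modality %||% "mm"
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           full.names = TRUE, ignore.case = TRUE))
  if (!length(files)) {
    stop(validation_error(sprintf("no image frames found in '%s'", path)))
  }
  read_one <- function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
      png::readPNG(f)
    } else {
      tiff::readTIFF(f)
    }
    if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE],
                                             c(1, 2), mean)
    round(img * 255)
  }
  imgs <- lapply(files, read_one)
  d <- dim(imgs[[1]])
  frames <- array(0, dim = c(length(imgs), d[1], d[2]))
  for (k in seq_along(imgs)) frames[k, , ] <- imgs[[k]]
  stimulus(frames, fps, px_size, modality)
}

#' Save a stimulus as a numbered PNG stack with a manifest
#' @param stim a [stimulus()].
#' @param path destination directory (created).
#' @return \code{path}, invisibly.
#' @export
save_stimulus <- function(stim, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nt <- n_frames(stim)
  fmt <- paste0("frame_%0", max(4, nchar(nt)), "d.png")
  for (k in seq_len(nt)) {
    png::writePNG(stim$frames[k, , ] / 255,
                  file.path(path, sprintf(fmt, k)))
  }
  jsonlite::write_json(
    list(fps = stim$fps, px_size = stim$px_size, modality = stim$modality,
         n_frames = nt),
    file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
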