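#' Ordered grayscale frame sequence
#'
#' Holds a chest video as a list of intensity matrices in `[0, 1]` plus the
#' frame rate. Matrices are indexed `[row, column]`; the public coordinate
#' convention is 0-based with the origin at the top-left corner, `x` the
#' column (rightward) and `y` the row (downward).
#'
#' @param frames list of numeric matrices, all with identical dimensions and
#'   values in `[0, 1]`.
#' @param frame_rate frames per second (> 0).
#' @param audio optional [uniform_signal()] soundtrack used for tap
#'   synchronization.
#' @param rotation_deg rotation applied at load time, degrees
#'   counterclockwise (bookkeeping only; see [rotate_frame()]).
#' @return An object of class `frame_sequence` with fields `frames`,
#'   `frame_rate`, `width`, `height`, `audio`, `rotation_deg`.
#' @examples
#' fr <- replicate(3, matrix(runif(64), 8, 8), simplify = FALSE)
#' fs <- frame_sequence(fr, frame_rate = 60)
#' @export
frame_sequence <- function(frames, frame_rate, audio = NULL, rotation_deg = 0) {
  if (!is.list(frames) || length(frames) < 1L) {
    stop_scg("scg_domain_error", "frames must be a non-empty list of matrices")
  }
  dims <- dim(frames[[1L]])
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || !identical(dim(f), dims)) {
      stop_scg("scg_domain_error", "frame %d does not match dimensions of frame 1", i)
    }
    if (!all(is.finite(f)) || min(f) < 0 || max(f) > 1) {
      stop_scg("scg_domain_error", "frame %d has intensities outside [0, 1]", i)
    }
  }
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop_scg("scg_domain_error", "frame_rate must be positive")
  }
  if (!is.null(audio)) stopifnot(inherits(audio, "uniform_signal"))
  structure(
    list(frames = frames, frame_rate = as.numeric(frame_rate),
         width = dims[2L], height = dims[1L], audio = audio,
         rotation_deg = rotation_deg),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames %dx%d px @ %g fps%s\n",
              length(x$frames), x$width, x$height, x$frame_rate,
              if (is.null(x$audio)) "" else " (+audio)"))
  invisible(x)
}

#' Rotate a frame counterclockwise
#'
#' Used to align the tracked target with the camera axes before tracking.
#' Multiples of 90 degrees are exact pixel permutations; other angles rotate
#' about the frame center with bilinear interpolation (out-of-frame samples
#' take the frame's median intensity).
#'
#' @param frame numeric intensity matrix.
#' @param deg rotation angle in degrees, counterclockwise.
#' @return Rotated matrix (same dimensions unless `deg` is an odd multiple
#'   of 90, which transposes them).
#' @export
rotate_frame <- function(frame, deg) {
  deg <- deg %% 360
  if (isTRUE(all.equal(deg %% 90, 0))) {
    k <- round(deg / 90) %% 4
    out <- frame
    for (i in seq_len(k)) {
      # 90 degrees CCW: new[row, col] = old[col, nrow_new + 1 - row]
      out <- t(out)[rev(seq_len(ncol(out))), , drop = FALSE]
    }
    return(out)
  }
  h <- nrow(frame); w <- ncol(frame)
  th <- deg * pi / 180
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  g <- expand.grid(x = 0:(w - 1), y = 0:(h - 1))
  # inverse map: source coords obtained by rotating by -deg about the center
  xs <- cos(th) * (g$x - cx) + sin(th) * (g$y - cy) + cx
  ys <- -sin(th) * (g$x - cx) + cos(th) * (g$y - cy) + cy
  inside <- xs >= 0 & xs <= w - 1 & ys >= 0 & ys <= h - 1
  vals <- rep(median(frame), nrow(g))
  vals[inside] <- bilinear_sample(frame, xs[inside], ys[inside])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Rotate all frames of a sequence
#'
#' @param frames a [frame_sequence()].
#' @param deg degrees counterclockwise.
#' @return A new `frame_sequence` with `rotation_deg` updated.
#' @export
rotate_frames <- function(frames, deg) {
  stopifnot(inherits(frames, "frame_sequence"))
  if (deg == 0) return(frames)
  rotated <- lapply(frames$frames, rotate_frame, deg = deg)
  rotated <- lapply(rotated, function(f) pmin(pmax(f, 0), 1))
  frame_sequence(rotated, frames$frame_rate, audio = frames$audio,
                 rotation_deg = frames$rotation_deg + deg)
}

#' Load a frame sequence from a directory of PNG images
#'
#' Frames are read in lexicographic filename order and converted to
#' grayscale luma (Rec. 601 weights) in `[0, 1]`.
#'
#' @param dir directory containing `.png` frames.
#' @param frame_rate frames per second of the stack.
#' @param rotation_deg optional rotation applied to every frame at load time.
#' @return A [frame_sequence()].
#' @export
read_frame_directory <- function(dir, frame_rate, rotation_deg = 0) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_scg("scg_io_error", "reading PNG frame stacks requires the 'png' package")
  }
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) {
    stop_scg("scg_io_error", "no PNG frames found in '%s'", dir)
  }
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) {
      # luma from RGB planes
      img <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    }
    img
  })
  fs <- frame_sequence(frames, frame_rate)
  if (rotation_deg != 0) fs <- rotate_frames(fs, rotation_deg) else fs
}

#' Write a frame sequence as a PNG stack
#'
#' @param frames a [frame_sequence()].
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_frame_directory <- function(frames, dir) {
  stopifnot(inherits(frames, "frame_sequence"))
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_scg("scg_io_error", "writing PNG frame stacks requires the 'png' package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames$frames)) {
    png::writePNG(frames$frames[[i]],
                  file.path(dir, sprintf("frame_%05d.png", i)))
  }
  invisible(dir)
}

#' Cut the tracking template from the first frame
#'
#' The template is the high-contrast target region (e.g. a texture-patterned
#' QR code) that the tracker follows through the video. It is defined once,
#' on frame 1, together with its absolute pixel coordinate grid.
#'
#' @param frames a [frame_sequence()].
#' @param roi integer vector `c(x0, y0, w, h)`: 0-based top-left corner and
#'   size of the region, half-open, with `w, h >= 8`.
#' @return An object of class `template_region` with fields `patch` (the
#'   `h x w` intensity matrix), `origin` (`c(x0, y0)`), and `coords`
#'   (matrices `x`, `y` of the 0-based frame coordinates of each template
#'   pixel).
#' @examples
#' fr <- list(matrix(runif(100 * 100), 100, 100))
#' tpl <- extract_template(frame_sequence(fr, 60), roi = c(10, 20, 32, 32))
#' @export
extract_template <- function(frames, roi) {
  stopifnot(inherits(frames, "frame_sequence"))
  roi <- as.numeric(roi)
  if (length(roi) != 4L || any(!is.finite(roi))) {
    stop_scg("scg_domain_error", "roi must be c(x0, y0, w, h)")
  }
  x0 <- roi[1L]; y0 <- roi[2L]; w <- roi[3L]; h <- roi[4L]
  if (w < 8 || h < 8) {
    stop_scg("scg_bounds_error", "roi must be at least 8x8 px, got %gx%g", w, h)
  }
  if (x0 < 0 || y0 < 0 || x0 + w > frames$width || y0 + h > frames$height) {
    stop_scg("scg_bounds_error",
             "roi [%g,%g,%g,%g] extends outside the %dx%d frame",
             x0, y0, w, h, frames$width, frames$height)
  }
  patch <- frames$frames[[1L]][(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), drop = FALSE]
  if (sd(as.vector(patch)) == 0) {
    stop_scg("scg_untrackable_error",
             "template region has zero intensity variance (untrackable)")
  }
  xs <- matrix(rep(x0:(x0 + w - 1), each = h), nrow = h)
  ys <- matrix(rep(y0:(y0 + h - 1), times = w), nrow = h)
  structure(
    list(patch = patch, origin = c(x0, y0), coords = list(x = xs, y = ys)),
    class = "template_region"
  )
}

#' @export
print.template_region <- function(x, ...) {
  cat(sprintf("<template_region> %dx%d px at (%g, %g)\n",
              ncol(x$patch), nrow(x$patch), x$origin[1L], x$origin[2L]))
  invisible(x)
}
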