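#' Per-transition gaze velocity
#'
#' Computes the speed of gaze movement for every pair of valid samples that
#' are adjacent in the raw stream: Euclidean displacement in screen pixels
#' divided by the time step in milliseconds. Transitions that span an invalid
#' sample (blink / track loss) are omitted entirely — gaze position during
#' track loss is unknown and must not be interpolated as motion.
#'
#' @param recording a [gaze_recording()] with at least two valid samples.
#' @return An object of class `velocity_trace`: list with `speeds` (px/ms),
#'   `dt` (ms), `disp` (px), `from`/`to` (sample row indices) and
#'   `clip_bound` (`NA` until [clip_dynamics()] is applied).
#' @seealso [clip_dynamics()], [speed_to_gray()]
#' @export
compute_velocity <- function(recording) {
  stopifnot(inherits(recording, "gaze_recording"))
  s <- recording$samples
  if (sum(s$valid) < 2L) stop("fewer than 2 valid samples")
  n <- nrow(s)
  i <- seq_len(n - 1L)
  keep <- s$valid[i] & s$valid[i + 1L]
  from <- i[keep]; to <- from + 1L
  dt <- s$t[to] - s$t[from]
  if (any(dt <= 0)) stop("data error: non-positive time step between samples")
  disp <- sqrt((s$x[to] - s$x[from])^2 + (s$y[to] - s$y[from])^2)
  structure(list(speeds = disp / dt, dt = dt, disp = disp,
                 from = from, to = to, clip_bound = NA_real_),
            class = "velocity_trace")
}

#' Quarter-diagonal displacement bound
#'
#' @param screen screen dimensions `c(width, height)` px.
#' @return One quarter of the screen diagonal, in pixels.
#' @export
quarter_diagonal <- function(screen) {
  stopifnot(length(screen) == 2L, all(screen > 0))
  sqrt(screen[1]^2 + screen[2]^2) / 4
}

#' Clip gaze dynamics to the quarter-diagonal bound
#'
#' Any single-transition displacement larger than a quarter of the screen
#' diagonal is not physiologically plausible gaze motion at tracker rates;
#' such transitions have their speed rescaled as if the displacement were
#' exactly the bound (the time step is unchanged). Speeds below the bound are
#' untouched, so clipping is idempotent.
#'
#' @param trace a `velocity_trace` from [compute_velocity()].
#' @param screen screen dimensions `c(width, height)` px.
#' @return The trace with `speeds` clipped and `clip_bound` set.
#' @export
clip_dynamics <- function(trace, screen) {
  stopifnot(inherits(trace, "velocity_trace"))
  bound <- quarter_diagonal(screen)
  over <- trace$disp > bound
  trace$speeds[over] <- bound / trace$dt[over]
  trace$disp[over] <- bound
  trace$clip_bound <- bound
  trace
}

#' Partition a recording into scanpath segments
#'
#' Images are constrained to carry roughly the same amount of information:
#' the ordered valid samples of a recording are partitioned into consecutive,
#' non-overlapping runs of at most `max_points` samples, each run becoming
#' one scanpath image. A trailing run shorter than `min_points` is dropped
#' (too few strokes to depict a gaze pattern). Limits of 100-150 points give
#' sparse, poorly discriminating images; 200 balances detail against clutter.
#'
#' @param recording a [gaze_recording()].
#' @param max_points maximum samples per segment (default 200).
#' @param min_points minimum samples in a trailing segment (default 20).
#' @return list of `scanpath_segment` objects with contiguous
#'   `segment_index` starting at 0; empty list if nothing qualifies.
#' @export
segment_scanpath <- function(recording, max_points = 200L, min_points = 20L) {
  stopifnot(inherits(recording, "gaze_recording"), max_points >= 2L)
  s <- recording$samples
  idx <- which(s$valid)
  if (length(idx) < 2L) return(list())
  starts <- seq(1L, length(idx), by = max_points)
  segs <- list()
  for (k in seq_along(starts)) {
    rows <- idx[starts[k]:min(starts[k] + max_points - 1L, length(idx))]
    if (length(rows) < max(2L, if (k > 1L) min_points else 2L)) next
    sub <- s[rows, , drop = FALSE]
    adjacent <- diff(rows) == 1L           # transitions not spanning track loss
    dt <- diff(sub$t)
    disp <- sqrt(diff(sub$x)^2 + diff(sub$y)^2)
    segs[[length(segs) + 1L]] <- structure(list(
      samples = data.frame(t = sub$t, x = sub$x, y = sub$y, row = rows),
      speeds = (disp / dt)[adjacent],
      dt = dt[adjacent], disp = disp[adjacent],
      adjacent = adjacent,
      screen = recording$screen,
      sampling_rate = recording$sampling_rate,
      participant_id = recording$participant_id,
      stimulus_id = recording$stimulus_id,
      segment_index = length(segs)), class = "scanpath_segment")
  }
  segs
}

#' @export
print.scanpath_segment <- function(x, ...) {
  cat(sprintf("<scanpath_segment> %s/%s #%d  %d samples, %d drawable transitions\n",
              x$participant_id, x$stimulus_id, x$segment_index,
              nrow(x$samples), sum(x$adjacent)))
  invisible(x)
}

#' Map a gaze speed to a grayscale intensity
#'
#' Velocity is encoded in the stroke color: speed is normalised by the
#' maximum plausible speed (the quarter-diagonal clip bound traversed in one
#' nominal sample interval) and mapped linearly onto the grayscale spectrum.
#' By default slow motion renders bright (1.0) and the fastest motion renders
#' at the floor `g_min = 0.1`, keeping every stroke visible on the black
#' background; `invert = TRUE` flips the direction.
#'
#' @param speed speed(s) in px/ms, non-negative.
#' @param clip_bound displacement bound in px (see [quarter_diagonal()]).
#' @param nominal_dt nominal inter-sample interval in ms (1000 / rate).
#' @param g_min intensity floor for the fastest motion.
#' @param invert if TRUE, slow is dark and fast is bright.
#' @return intensity value(s) in `[g_min, 1]`.
#' @export
speed_to_gray <- function(speed, clip_bound, nominal_dt, g_min = 0.1,
                          invert = FALSE) {
  if (any(speed < 0)) stop("speed must be non-negative")
  stopifnot(clip_bound > 0, nominal_dt > 0, g_min >= 0, g_min < 1)
  s <- pmin(speed / (clip_bound / nominal_dt), 1)
  if (invert) g_min + (1 - g_min) * s else 1 - (1 - g_min) * s
}

#' Render a scanpath segment to a velocity-encoded grayscale image
#'
#' Draws one straight stroke per drawable transition of the segment, colored
#' by [speed_to_gray()] of the (quarter-diagonal-clipped) transition speed,
#' on a black background. Screen coordinates are scaled to the raster and
#' vertically mirrored, because the raw data's origin is at the bottom of the
#' screen while rasters grow downwards; the bottom of the screen therefore
#' maps to the bottom rows of the image. Rasterization uses integer Bresenham
#' lines with maximum compositing on overlap, so rendering is deterministic
#' to the bit.
#'
#' Clipping affects only the color-mapped dynamics: stroke endpoints are
#' drawn at the recorded positions.
#'
#' @param segment a `scanpath_segment` with at least 2 samples.
#' @param dims raster dimensions `c(width, height)`, default `c(640, 480)`.
#' @param g_min,invert grayscale mapping, see [speed_to_gray()].
#' @return An object of class `scanpath_image`: list with `pixels`
#'   (height-by-width matrix in `[0,1]`, row 1 at the top), `meta`, and
#'   `n_strokes` (number of stroke primitives drawn).
#' @export
render_segment <- function(segment, dims = c(640L, 480L), g_min = 0.1,
                           invert = FALSE) {
  stopifnot(inherits(segment, "scanpath_segment"))
  if (nrow(segment$samples) < 2L) stop("segment must have at least 2 samples")
  W <- as.integer(dims[1]); H <- as.integer(dims[2])
  sw <- segment$screen[1]; sh <- segment$screen[2]
  bound <- quarter_diagonal(segment$screen)
  over <- segment$disp > bound
  speeds <- segment$speeds
  speeds[over] <- bound / segment$dt[over]
  nominal_dt <- 1000 / segment$sampling_rate
  gray <- speed_to_gray(speeds, bound, nominal_dt, g_min, invert)

  # scale to raster, mirror vertically (data origin bottom-left)
  px <- as.integer(round(segment$samples$x / sw * (W - 1)))
  py <- (H - 1L) - as.integer(round(segment$samples$y / sh * (H - 1)))
  i <- which(segment$adjacent)
  pixels <- .draw_strokes_cpp(H, W, px[i], py[i], px[i + 1L], py[i + 1L], gray)
  structure(list(pixels = pixels,
                 meta = list(participant_id = segment$participant_id,
                             stimulus_id = segment$stimulus_id,
                             segment_index = segment$segment_index),
                 n_strokes = length(i)),
            class = "scanpath_image")
}

#' Construct a scanpath image from a pixel matrix
#'
#' @param pixels height-by-width numeric matrix in `[0,1]`.
#' @param meta list of provenance fields (participant_id, stimulus_id,
#'   segment_index, label, ...).
#' @return A `scanpath_image`.
#' @export
scanpath_image <- function(pixels, meta = list()) {
  stopifnot(is.matrix(pixels), all(pixels >= 0 & pixels <= 1))
  structure(list(pixels = pixels, meta = meta, n_strokes = NA_integer_),
            class = "scanpath_image")
}

#' @export
print.scanpath_image <- function(x, ...) {
  cat(sprintf("<scanpath_image> %dx%d  %s strokes  %.1f%% lit\n",
              ncol(x$pixels), nrow(x$pixels),
              ifelse(is.na(x$n_strokes), "?", x$n_strokes),
              100 * mean(x$pixels > 0)))
  invisible(x)
}

#' @export
plot.scanpath_image <- function(x, ...) {
  op <- graphics::par(mar = c(0, 0, 1, 0)); on.exit(graphics::par(op))
  graphics::image(t(x$pixels)[, nrow(x$pixels):1, drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  asp = nrow(x$pixels) / ncol(x$pixels),
                  main = paste0(x$meta$participant_id, "/",
                                x$meta$stimulus_id, " #",
                                x$meta$segment_index), ...)
  invisible(x)
}

#' Write a scanpath image as an 8-bit grayscale PNG
#'
#' @param image a `scanpath_image`.
#' @param path output `.png` path; defaults to the
#'   `{participant}_{stimulus}_{segment}.png` pattern inside `dir`.
#' @param dir directory used when `path` is missing.
#' @return The path written, invisibly.
#' @export
write_scanpath_png <- function(image, path = NULL, dir = ".") {
  stopifnot(inherits(image, "scanpath_image"))
  if (is.null(path)) {
    m <- image$meta
    path <- file.path(dir, sprintf("%s_%s_%s.png", m$participant_id,
                                   m$stimulus_id, m$segment_index))
  }
  png::writePNG(image$pixels, path)
  invisible(path)
}

#' Read a grayscale PNG back into a scanpath image
#'
#' @param path `.png` file (first channel used if multi-channel).
#' @param meta optional provenance list.
#' @return A `scanpath_image`.
#' @export
read_scanpath_png <- function(path, meta = list()) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  scanpath_image(px, meta)
}

#' Render every segment of a set of recordings
#'
#' Convenience wrapper: segment each recording, render each segment, and
#' return the images together with an inventory data.frame in the manifest
#' schema.
#'
#' @param recordings list of [gaze_recording()].
#' @param dims,g_min,invert see [render_segment()].
#' @param max_points,min_points see [segment_scanpath()].
#' @return list with `images` (list of `scanpath_image`), `segments`
#'   (matching list of `scanpath_segment`) and `inventory` (data.frame).
#' @export
render_recordings <- function(recordings, dims = c(640L, 480L),
                              max_points = 200L, min_points = 20L,
                              g_min = 0.1, invert = FALSE) {
  images <- list(); segments <- list(); inv <- list()
  for (rec in recordings) {
    for (seg in segment_scanpath(rec, max_points, min_points)) {
      img <- render_segment(seg, dims, g_min, invert)
      images[[length(images) + 1L]] <- img
      segments[[length(segments) + 1L]] <- seg
      inv[[length(inv) + 1L]] <- data.frame(
        image = sprintf("%s_%s_%d.png", rec$participant_id, rec$stimulus_id,
                        seg$segment_index),
        participant_id = rec$participant_id,
        stimulus_id = rec$stimulus_id,
        segment = seg$segment_index, stringsAsFactors = FALSE)
    }
  }
  list(images = images, segments = segments,
       inventory = if (length(inv)) do.call(rbind, inv) else NULL)
}
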