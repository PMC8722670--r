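#' Mean gaze velocity of one scanpath image
#'
#' Arithmetic mean of the segment's transition speeds after quarter-diagonal
#' clipping — the same dynamics the rendered image encodes in its grayscale.
#' Set `clip = FALSE` for the raw (unclipped) speeds.
#'
#' @param segment a `scanpath_segment` with at least one transition.
#' @param clip apply the quarter-diagonal displacement bound (default TRUE).
#' @return mean speed in px/ms.
#' @export
mean_velocity_per_image <- function(segment, clip = TRUE) {
  stopifnot(inherits(segment, "scanpath_segment"))
  if (length(segment$speeds) == 0L)
    stop("segment has no transition speeds")
  sp <- segment$speeds
  if (clip) {
    bound <- quarter_diagonal(segment$screen)
    over <- segment$disp > bound
    sp[over] <- bound / segment$dt[over]
  }
  mean(sp)
}

#' Maximal information coefficient
#'
#' MIC detects linear and nonlinear dependence between two variables by
#' maximising, over all grids with `nx * ny <= n^grid_exponent`, the mutual
#' information of the induced bivariate distribution normalised by
#' `log2(min(nx, ny))`. The search uses the ApproxMaxMI heuristic: one axis
#' is equipartitioned and the other optimised by dynamic programming over
#' clumps of consecutive points (at most `clumps` times the column count),
#' in both axis orientations. Scores lie in `[0, 1]`; a noiseless functional
#' relationship scores 1 and statistically independent variables score near
#' 0 for large n. The score is invariant to strictly monotone transforms of
#' either variable because only rank orderings enter the grid search.
#'
#' @param x,y numeric vectors of equal length, at least 30 points.
#' @param grid_exponent exponent of the grid-size budget `B(n) = n^0.6`.
#' @param clumps clump factor of the x-axis optimisation (default 15).
#' @return MIC score in `[0, 1]`.
#' @export
mic_score <- function(x, y, grid_exponent = 0.6, clumps = 15L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 30L) stop("MIC requires at least 30 points")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  .mic_cpp(as.numeric(x), as.numeric(y), grid_exponent, as.integer(clumps))
}

#' Velocity-severity correlation over a cohort
#'
#' Builds one (mean clipped velocity, CARS) pair per scanpath image of a
#' CARS-scored participant — so each child's severity score is weighted by
#' the number of images they contributed, which damps the influence of
#' outlier recordings — and returns the MIC of the pairs together with the
#' table for plotting.
#'
#' By default only participants with a variable severity score (CARS above
#' the scale minimum of 15, i.e. the ASD group whose non-ASD peers all score
#' the constant 15) enter the computation: a constant-valued block would
#' inflate apparent dependence. Set `include_constant = TRUE` to keep them.
#'
#' @param manifest a [cohort_manifest()] whose participants carry `cars`.
#' @param segments list of `scanpath_segment` (one per image).
#' @param clip use clipped velocities (default TRUE).
#' @param include_constant include constant-CARS (non-ASD) participants.
#' @param min_pairs minimum usable pairs (default 30).
#' @param grid_exponent,clumps passed to [mic_score()].
#' @return An object of class `velocity_severity`: list with `mic`, `pairs`
#'   (data.frame velocity, cars, participant_id, image) and `n`.
#' @export
correlate_cohort <- function(manifest, segments, clip = TRUE,
                             include_constant = FALSE, min_pairs = 30L,
                             grid_exponent = 0.6, clumps = 15L) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  p <- manifest$participants
  rows <- lapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    cars <- p$cars[match(seg$participant_id, p$participant_id)]
    if (is.na(cars)) return(NULL)
    if (!include_constant && cars <= 15) return(NULL)
    data.frame(velocity = mean_velocity_per_image(seg, clip), cars = cars,
               participant_id = seg$participant_id,
               image = sprintf("%s_%s_%d", seg$participant_id,
                               seg$stimulus_id, seg$segment_index),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) < min_pairs)
    stop(sprintf("insufficient velocity-severity pairs (%d < %d)",
                 if (is.null(pairs)) 0L else nrow(pairs), min_pairs))
  structure(list(mic = mic_score(pairs$velocity, pairs$cars,
                                 grid_exponent, clumps),
                 pairs = pairs, n = nrow(pairs)),
            class = "velocity_severity")
}

#' @export
print.velocity_severity <- function(x, ...) {
  cat(sprintf("<velocity_severity> MIC = %.3f over %d image-level pairs (%d participants)\n",
              x$mic, x$n, length(unique(x$pairs$participant_id))))
  invisible(x)
}

#' @export
plot.velocity_severity <- function(x, ...) {
  graphics::plot(x$pairs$velocity, x$pairs$cars, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.6),
                 xlab = "Mean gaze velocity per image (px/ms)",
                 ylab = "CARS score",
                 main = sprintf("MIC = %.2f", x$mic), ...)
  invisible(x)
}
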