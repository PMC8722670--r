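#' Construct a gaze recording
#'
#' A gaze recording holds the time-stamped point-of-gaze (POG) samples of one
#' participant viewing one stimulus on a screen-based eye tracker. Samples
#' flagged invalid (blinks, track loss, off-screen coordinates) are retained
#' in place so that downstream velocity computation can refuse to bridge them.
#'
#' Coordinates follow the raw-export convention: origin at the bottom-left of
#' the screen, x rightwards and y upwards, in screen pixels. The conversion to
#' raster (top-left origin) space happens only in [render_segment()].
#'
#' @param samples data.frame with columns `t` (ms), `x`, `y` (screen px) and
#'   logical `valid`.
#' @param participant_id,stimulus_id opaque identifier strings.
#' @param screen integer vector `c(width, height)` in pixels.
#' @param sampling_rate nominal tracker rate in Hz.
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(samples, participant_id = "p0", stimulus_id = "s0",
                           screen = c(1280L, 1024L), sampling_rate = 250) {
  stopifnot(is.data.frame(samples),
            all(c("t", "x", "y", "valid") %in% names(samples)))
  if (length(screen) != 2L || any(!is.finite(screen)) || any(screen <= 0))
    stop("screen dimensions must be two positive numbers")
  t <- samples$t
  if (any(!is.finite(t)) || any(t < 0))
    stop("timestamps must be finite and non-negative")
  if (nrow(samples) > 1L) {
    bad <- which(diff(t) <= 0)
    if (length(bad))
      stop(sprintf("timestamps not strictly increasing at row %d", bad[1] + 1L))
  }
  samples$valid <- samples$valid &
    is.finite(samples$x) & is.finite(samples$y) &
    samples$x >= 0 & samples$x <= screen[1] &
    samples$y >= 0 & samples$y <= screen[2]
  structure(list(participant_id = as.character(participant_id),
                 stimulus_id = as.character(stimulus_id),
                 screen = as.numeric(screen),
                 sampling_rate = sampling_rate,
                 samples = samples),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> participant=%s stimulus=%s  %d samples (%d valid)  %g Hz  screen %dx%d\n",
              x$participant_id, x$stimulus_id, nrow(x$samples),
              sum(x$samples$valid), x$sampling_rate,
              as.integer(x$screen[1]), as.integer(x$screen[2])))
  invisible(x)
}

#' Default column map for delimited gaze exports
#'
#' Maps logical roles to header names in a delimited gaze export. `x`/`y` may
#' instead be given as `x_left`,`x_right`,`y_left`,`y_right` for binocular
#' exports; when both eyes are valid their POG is averaged, otherwise the
#' valid eye is used. `participant` and `stimulus` are optional block columns.
#'
#' @param t,x,y,valid,participant,stimulus header names (NA to omit).
#' @return A named list usable as `column_map` in [read_gaze_records()].
#' @export
gaze_column_map <- function(t = "time_ms", x = "x_px", y = "y_px",
                            valid = "validity",
                            participant = NA, stimulus = NA) {
  list(t = t, x = x, y = y, valid = valid,
       participant = participant, stimulus = stimulus)
}

#' Read raw gaze exports from delimited text
#'
#' Parses a CSV/TSV eye-tracking export into one [gaze_recording()] per
#' participant-by-stimulus block. Rows with missing or out-of-range
#' coordinates, or a zero/falsey validity marker, become samples with
#' `valid = FALSE`; they are kept so that no stroke or velocity is ever
#' interpolated across track loss.
#'
#' @param path delimited text file; the separator is sniffed from the header
#'   (comma or tab).
#' @param screen screen dimensions `c(width, height)` px.
#' @param column_map see [gaze_column_map()]; binocular maps with
#'   `x_left`/`x_right` etc. are averaged over valid eyes.
#' @param sampling_rate tracker rate in Hz (default 250).
#' @param participant_id,stimulus_id identifiers used when the export has no
#'   block columns; default to the file name.
#' @return list of `gaze_recording` objects.
#' @export
read_gaze_records <- function(path, screen = c(1280L, 1024L),
                              column_map = gaze_column_map(),
                              sampling_rate = 250,
                              participant_id = NULL, stimulus_id = "s0") {
  if (!file.exists(path)) stop("gaze file not found: ", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L || !nzchar(trimws(header)))
    stop("format error: empty gaze file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("format error: no data rows in ", path)

  need <- function(role) {
    nm <- column_map[[role]]
    if (is.null(nm) || is.na(nm)) return(NULL)
    if (!nm %in% names(df))
      stop(sprintf("format error: column '%s' (%s) absent from %s", nm, role, path))
    df[[nm]]
  }
  t <- need("t")
  if (is.null(t)) stop("column_map must name a timestamp column")
  t <- suppressWarnings(as.numeric(t))
  if (any(is.na(t))) stop("format error: non-numeric timestamps in ", path)

  # monocular or binocular coordinates
  if (!is.null(column_map$x_left)) {
    xl <- suppressWarnings(as.numeric(need("x_left")))
    xr <- suppressWarnings(as.numeric(need("x_right")))
    yl <- suppressWarnings(as.numeric(need("y_left")))
    yr <- suppressWarnings(as.numeric(need("y_right")))
    okl <- is.finite(xl) & is.finite(yl)
    okr <- is.finite(xr) & is.finite(yr)
    x <- ifelse(okl & okr, (xl + xr) / 2, ifelse(okl, xl, xr))
    y <- ifelse(okl & okr, (yl + yr) / 2, ifelse(okl, yl, yr))
  } else {
    x <- suppressWarnings(as.numeric(need("x")))
    y <- suppressWarnings(as.numeric(need("y")))
  }
  vcol <- need("valid")
  valid <- if (is.null(vcol)) rep(TRUE, nrow(df)) else {
    v <- suppressWarnings(as.numeric(vcol))
    if (all(is.na(v))) !(tolower(as.character(vcol)) %in% c("false", "invalid", "lost"))
    else !is.na(v) & v != 0
  }
  valid <- valid & is.finite(x) & is.finite(y)
  x[!is.finite(x)] <- -1; y[!is.finite(y)] <- -1

  pid <- need("participant")
  sid <- need("stimulus")
  if (is.null(participant_id))
    participant_id <- tools::file_path_sans_ext(basename(path))
  if (is.null(pid)) pid <- rep(participant_id, nrow(df))
  if (is.null(sid)) sid <- rep(stimulus_id, nrow(df))

  key <- paste(pid, sid, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                function(idx) {
    gaze_recording(data.frame(t = t[idx], x = x[idx], y = y[idx],
                              valid = valid[idx]),
                   participant_id = pid[idx[1]], stimulus_id = sid[idx[1]],
                   screen = screen, sampling_rate = sampling_rate)
  })
  names(out) <- NULL
  out
}

#' Write a gaze recording to delimited text
#'
#' Emits the same four-column CSV dialect [read_gaze_records()] reads by
#' default, so simulated recordings can round-trip through the reader.
#'
#' @param recording a `gaze_recording`.
#' @param path output file.
#' @export
write_gaze_record <- function(recording, path) {
  s <- recording$samples
  df <- data.frame(time_ms = s$t, x_px = s$x, y_px = s$y,
                   validity = as.integer(s$valid),
                   participant_id = recording$participant_id,
                   stimulus_id = recording$stimulus_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

normalize_group <- function(g) {
  g <- tolower(trimws(as.character(g)))
  out <- ifelse(g %in% c("asd", "autism"), "ASD",
         ifelse(g %in% c("non-asd", "nonasd", "td", "control", "non_asd"),
                "non-ASD", NA))
  if (any(is.na(out)))
    stop("unknown group label(s): ", paste(unique(g[is.na(out)]), collapse = ", "))
  out
}

#' Construct a cohort manifest
#'
#' Bundles the participant table (ID, group, CARS severity score, age) with
#' the inventory of scanpath images derived from their recordings. CARS has a
#' scale minimum of 15 with an autism cutoff above 30; scores below 15 are
#' rejected.
#'
#' @param participants data.frame with columns `participant_id`, `group`
#'   (`ASD`/`non-ASD`), optional `cars`, optional `age_months`.
#' @param images data.frame with columns `image`, `participant_id`,
#'   `stimulus_id`, `segment` (and optionally `label`, `augmented_from`);
#'   may be empty.
#' @return An object of class `cohort_manifest`.
#' @export
cohort_manifest <- function(participants, images = NULL) {
  stopifnot(is.data.frame(participants),
            all(c("participant_id", "group") %in% names(participants)))
  participants$participant_id <- as.character(participants$participant_id)
  if (anyDuplicated(participants$participant_id))
    stop("consistency error: duplicate participant_id in manifest")
  participants$group <- normalize_group(participants$group)
  if (!"cars" %in% names(participants)) participants$cars <- NA_real_
  cars <- participants$cars
  if (any(!is.na(cars) & cars < 15))
    stop("validation error: CARS below scale minimum 15")
  if (is.null(images) || nrow(as.data.frame(images)) == 0L) {
    images <- data.frame(image = character(), participant_id = character(),
                         stimulus_id = character(), segment = integer(),
                         label = character(), stringsAsFactors = FALSE)
  } else {
    images <- as.data.frame(images)
    stopifnot(all(c("image", "participant_id") %in% names(images)))
    images$participant_id <- as.character(images$participant_id)
    unknown <- setdiff(images$participant_id, participants$participant_id)
    if (length(unknown))
      stop("consistency error: image references unknown participant: ",
           paste(unknown, collapse = ", "))
    if (!"stimulus_id" %in% names(images)) images$stimulus_id <- "s0"
    if (!"segment" %in% names(images)) images$segment <- 0L
    if (!"label" %in% names(images))
      images$label <- participants$group[match(images$participant_id,
                                               participants$participant_id)]
  }
  structure(list(participants = participants, images = images),
            class = "cohort_manifest")
}

#' @export
print.cohort_manifest <- function(x, ...) {
  tab <- table(x$participants$group)
  cat(sprintf("<cohort_manifest> %d participants (%s)  %d images\n",
              nrow(x$participants),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              nrow(x$images)))
  invisible(x)
}

#' Read a cohort manifest from JSON or CSV
#'
#' JSON manifests hold both the `participants` and `images` tables; a CSV
#' manifest is a bare participant table (the image inventory is then filled
#' by the rendering stage).
#'
#' @param path `.json` or `.csv` file.
#' @return A [cohort_manifest()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    cohort_manifest(as.data.frame(obj$participants),
                    if (!is.null(obj$images)) as.data.frame(obj$images))
  } else {
    cohort_manifest(utils::read.csv(path, stringsAsFactors = FALSE))
  }
}

#' Write a cohort manifest to JSON
#'
#' @param manifest a [cohort_manifest()].
#' @param path output `.json` file.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  jsonlite::write_json(list(participants = manifest$participants,
                            images = manifest$images),
                       path, auto_unbox = FALSE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Cohort bookkeeping statistics
#'
#' Counts images overall and per group and reports the mean number of images
#' per participant (rounded to 2 decimals for reporting, as conventional for
#' cohort tables).
#'
#' @param manifest a [cohort_manifest()] with a non-empty image inventory.
#' @return list with `n_participants`, `n_images`, `per_group` (data.frame of
#'   participant count, image count and mean images per participant by
#'   group), and `mean_images_per_participant`.
#' @export
cohort_statistics <- function(manifest) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  p <- manifest$participants
  im <- manifest$images
  if (nrow(p) == 0L || nrow(im) == 0L)
    stop("empty manifest: no participants or no images")
  grp <- p$group[match(im$participant_id, p$participant_id)]
  groups <- sort(unique(p$group))
  per_group <- data.frame(
    group = groups,
    n_participants = as.integer(table(factor(p$group, groups))),
    n_images = as.integer(table(factor(grp, groups))))
  per_group$mean_images <- round(per_group$n_images / per_group$n_participants, 2)
  list(n_participants = nrow(p),
       n_images = nrow(im),
       per_group = per_group,
       mean_images_per_participant = round(nrow(im) / nrow(p), 2))
}
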