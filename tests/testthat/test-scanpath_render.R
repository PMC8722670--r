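test_that("transition speeds are Euclidean displacement over time step", {
  rec <- make_recording(rbind(c(0, 0), c(3, 4)))
  expect_equal(compute_velocity(rec)$speeds, 1.25)

  still <- make_recording(cbind(rep(100, 10), rep(100, 10)))
  expect_true(all(compute_velocity(still)$speeds == 0))

  gap <- make_recording(rbind(c(0, 0), c(10, 10), c(20, 20)),
                        valid = c(TRUE, FALSE, TRUE))
  expect_length(compute_velocity(gap)$speeds, 0)

  expect_error(compute_velocity(make_recording(rbind(c(0, 0), c(1, 1)),
                                               valid = c(TRUE, FALSE))),
               "fewer than 2")
})

test_that("speeds agree with a brute-force pairwise oracle", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(10:1000, 1)
    rec <- random_recording(n)
    rec$samples$valid <- runif(n) > 0.1
    if (sum(rec$samples$valid) < 2) next
    got <- compute_velocity(rec)$speeds
    want <- brute_force_speeds(rec)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("clipping rescales only displacements beyond the quarter diagonal and is idempotent", {
  expect_equal(quarter_diagonal(c(1280, 1024)), sqrt(1280^2 + 1024^2) / 4,
               tolerance = 1e-12)
  expect_equal(quarter_diagonal(c(1280, 1024)), 409.82, tolerance = 1e-4)

  small <- make_recording(rbind(c(0, 0), c(100, 0)))
  tr <- clip_dynamics(compute_velocity(small), c(1280, 1024))
  expect_equal(tr$speeds, 25)                      # 100 px / 4 ms, untouched

  big <- make_recording(rbind(c(0, 0), c(10000, 0)), screen = c(1e5, 1e5))
  tr2 <- compute_velocity(big)
  tr2$clip_bound <- NULL
  clipped <- clip_dynamics(tr2, c(1280, 1024))
  expect_equal(clipped$speeds, quarter_diagonal(c(1280, 1024)) / 4,
               tolerance = 1e-9)                   # ~102.45 px/ms
  expect_equal(clip_dynamics(clipped, c(1280, 1024))$speeds, clipped$speeds)
})

test_that("segmentation chunks valid samples at the point threshold", {
  expect_length(segment_scanpath(random_recording(150)), 1)
  segs <- segment_scanpath(random_recording(400))
  expect_length(segs, 2)
  expect_equal(vapply(segs, function(s) nrow(s$samples), 0L), c(200L, 200L))
  expect_equal(vapply(segs, `[[`, 0L, "segment_index"), 0:1)

  # trailing run below min_points is dropped
  expect_length(segment_scanpath(random_recording(410), min_points = 20), 2)
  # but kept when long enough
  expect_length(segment_scanpath(random_recording(430), min_points = 20), 3)
})

test_that("gray mapping is linear, floored and monotone non-increasing", {
  expect_equal(speed_to_gray(0, 409.82, 4), 1.0)
  expect_equal(speed_to_gray(409.82 / 4, 409.82, 4), 0.1)
  expect_equal(speed_to_gray(1000, 409.82, 4), 0.1)    # above max, clamped
  expect_equal(speed_to_gray(409.82 / 8, 409.82, 4), 0.55)
  expect_error(speed_to_gray(-1, 409.82, 4), "non-negative")

  s <- sort(runif(100, 0, 200))
  g <- speed_to_gray(s, 409.82, 4)
  expect_true(all(diff(g) <= 1e-12))
  gi <- speed_to_gray(s, 409.82, 4, invert = TRUE)
  expect_true(all(diff(gi) >= -1e-12))
})

test_that("rendering draws one stroke per transition and mirrors vertically", {
  set.seed(5)
  seg <- random_segment(80)
  img <- render_segment(seg)
  expect_equal(img$n_strokes, 79)
  expect_equal(dim(img$pixels), c(480, 640))

  # data near the bottom of the screen lands in the bottom rows of the raster
  low <- segment_scanpath(make_recording(rbind(c(600, 0), c(640, 20))),
                          max_points = 2)[[1]]
  px <- render_segment(low)$pixels
  lit_rows <- which(rowSums(px) > 0)
  expect_true(all(lit_rows > 450))

  # and data near the top lands in the top rows
  high <- segment_scanpath(make_recording(rbind(c(600, 1000), c(640, 1024))),
                           max_points = 2)[[1]]
  lit_rows <- which(rowSums(render_segment(high)$pixels) > 0)
  expect_true(all(lit_rows < 30))

  expect_error(render_segment(structure(list(samples = data.frame(t = 0)),
                                        class = "scanpath_segment")),
               "at least 2")
})

test_that("rendering is bit-deterministic with intensities in {0} U [g_min, 1]", {
  set.seed(6)
  for (i in 1:10) {
    seg <- random_segment(sample(20:200, 1))
    a <- render_segment(seg)
    b <- render_segment(seg)
    expect_identical(a$pixels, b$pixels)
    v <- a$pixels[a$pixels > 0]
    expect_true(length(v) > 0)
    expect_true(all(v >= 0.1 - 1e-12 & v <= 1))
  }
})

test_that("track-loss gaps break strokes", {
  rec <- make_recording(rbind(c(0, 0), c(100, 100), c(1200, 1000), c(1210, 1010)),
                        valid = c(TRUE, TRUE, FALSE, TRUE))
  seg <- segment_scanpath(rec, max_points = 10, min_points = 2)[[1]]
  img <- render_segment(seg)
  expect_equal(img$n_strokes, 1)   # only the adjacent valid pair draws
})

test_that("image inventory conserves the segment count across a cohort", {
  set.seed(9)
  recs <- lapply(1:4, function(i)
    generate_recording(gaze_profile(), 2, seed = i,
                       participant_id = paste0("p", i)))
  rend <- render_recordings(recs, dims = c(160L, 120L))
  n_segs <- sum(vapply(recs, function(r) length(segment_scanpath(r)), 0L))
  expect_length(rend$images, n_segs)
  expect_equal(nrow(rend$inventory), n_segs)
})

test_that("scanpath images round-trip through 8-bit PNG", {
  set.seed(10)
  img <- render_segment(random_segment(60))
  f <- withr::local_tempfile(fileext = ".png")
  write_scanpath_png(img, f)
  back <- read_scanpath_png(f)
  expect_equal(dim(back$pixels), dim(img$pixels))
  expect_lt(max(abs(back$pixels - img$pixels)), 1 / 255)
})
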