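test_that("delimited gaze exports parse into recordings with validity flags", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_ms,x_px,y_px,validity",
               "0,0,0,1", "4,3,4,1", "8,6,8,1"), f)
  recs <- read_gaze_records(f)
  expect_length(recs, 1)
  expect_equal(nrow(recs[[1]]$samples), 3)
  expect_true(all(recs[[1]]$samples$valid))

  # out-of-range coordinate flagged invalid, recording still returned
  writeLines(c("time_ms,x_px,y_px,validity",
               "0,0,0,1", "4,-1,4,1", "8,6,8,1"), f)
  recs <- read_gaze_records(f)
  expect_equal(recs[[1]]$samples$valid, c(TRUE, FALSE, TRUE))

  # validity marker zero also flags invalid
  writeLines(c("time_ms,x_px,y_px,validity",
               "0,0,0,1", "4,3,4,0", "8,6,8,1"), f)
  expect_equal(read_gaze_records(f)[[1]]$samples$valid, c(TRUE, FALSE, TRUE))
})

test_that("empty or malformed gaze files raise format errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  file.create(f)
  expect_error(read_gaze_records(f), "empty")
  writeLines(c("time_ms,x_px,y_px,validity", "0,0,0,1", "0,1,1,1"), f)
  expect_error(read_gaze_records(f), "row 2")
  expect_error(read_gaze_records(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("participant/stimulus block columns split one file into recordings", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_ms,x_px,y_px,validity,pid,stim",
               "0,1,1,1,a,s1", "4,2,2,1,a,s1",
               "0,1,1,1,a,s2", "4,2,2,1,a,s2",
               "0,1,1,1,b,s1", "4,2,2,1,b,s1"), f)
  recs <- read_gaze_records(f, column_map = gaze_column_map(
    participant = "pid", stimulus = "stim"))
  expect_length(recs, 3)
  expect_equal(vapply(recs, `[[`, "", "participant_id"), c("a", "a", "b"))
})

test_that("binocular exports average the two eyes when both are valid", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,xl,xr,yl,yr",
               "0,10,20,10,20",
               "4,NA,20,NA,20"), f)
  cm <- list(t = "t", x_left = "xl", x_right = "xr",
             y_left = "yl", y_right = "yr",
             valid = NA, participant = NA, stimulus = NA)
  rec <- read_gaze_records(f, column_map = cm)[[1]]
  expect_equal(rec$samples$x, c(15, 20))
  expect_equal(rec$samples$y, c(15, 20))
})

test_that("simulated recordings round-trip through the CSV writer", {
  rec <- generate_recording(gaze_profile(), 1, seed = 5, participant_id = "p7")
  f <- withr::local_tempfile(fileext = ".csv")
  write_gaze_record(rec, f)
  back <- read_gaze_records(f, column_map = gaze_column_map(
    participant = "participant_id", stimulus = "stimulus_id"))[[1]]
  expect_equal(back$participant_id, "p7")
  expect_equal(back$samples$t, rec$samples$t)
  expect_equal(back$samples$x, rec$samples$x, tolerance = 1e-6)
  expect_equal(back$samples$valid, rec$samples$valid)
})

test_that("manifest validation enforces CARS minimum, uniqueness and referential integrity", {
  p <- data.frame(participant_id = c("a", "b"), group = c("ASD", "non-ASD"),
                  cars = c(35, 15))
  im <- data.frame(image = sprintf("i%d.png", 1:6),
                   participant_id = rep(c("a", "b"), each = 3),
                   stimulus_id = "s0", segment = 0:2)
  m <- cohort_manifest(p, im)
  expect_equal(nrow(m$images), 6)
  expect_error(cohort_manifest(data.frame(participant_id = "a", group = "ASD",
                                          cars = 10)),
               "below scale minimum")
  expect_error(cohort_manifest(data.frame(participant_id = c("a", "a"),
                                          group = "ASD")),
               "duplicate")
  expect_error(cohort_manifest(p, data.frame(image = "x.png",
                                             participant_id = "zzz")),
               "unknown participant")
})

test_that("manifests round-trip through JSON identically", {
  p <- data.frame(participant_id = c("a", "b"), group = c("ASD", "non-ASD"),
                  cars = c(35, 15))
  im <- data.frame(image = c("a_s0_0.png", "b_s0_0.png"),
                   participant_id = c("a", "b"), stimulus_id = "s0",
                   segment = c(0L, 0L))
  m <- cohort_manifest(p, im)
  f <- withr::local_tempfile(fileext = ".json")
  write_manifest(m, f)
  back <- read_manifest(f)
  expect_equal(back$participants$participant_id, m$participants$participant_id)
  expect_equal(back$participants$cars, m$participants$cars)
  expect_equal(back$images$image, m$images$image)
  expect_equal(back$images$segment, m$images$segment)
})

test_that("cohort statistics conserve counts and report per-group means", {
  p <- data.frame(participant_id = c("a", "b", "c"),
                  group = c("ASD", "ASD", "non-ASD"), cars = c(35, 31, 15))
  im <- data.frame(image = sprintf("i%d", 1:7),
                   participant_id = c("a", "a", "a", "b", "c", "c", "c"))
  st <- cohort_statistics(cohort_manifest(p, im))
  expect_equal(st$n_images, sum(st$per_group$n_images))
  expect_equal(st$n_participants, sum(st$per_group$n_participants))
  expect_equal(st$per_group$mean_images[st$per_group$group == "ASD"], 2)
  expect_equal(st$mean_images_per_participant, 2.33)

  one <- cohort_manifest(p[1, ], im[1, ])
  expect_equal(cohort_statistics(one)$mean_images_per_participant, 1.00)
  expect_error(cohort_statistics(cohort_manifest(p)), "empty")
})
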