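test_that("per-image mean velocity averages the clipped transition speeds", {
  still <- segment_scanpath(make_recording(cbind(rep(5, 10), rep(5, 10))),
                            max_points = 10, min_points = 2)[[1]]
  expect_equal(mean_velocity_per_image(still), 0)

  # constant speed v across transitions returns v
  xy <- cbind(seq(0, 90, by = 10), rep(0, 10))
  seg <- segment_scanpath(make_recording(xy), max_points = 10,
                          min_points = 2)[[1]]
  expect_equal(mean_velocity_per_image(seg), 2.5)    # 10 px / 4 ms

  # hand-computed mean of heterogeneous speeds [1, 2, 3] px/ms
  xy2 <- rbind(c(0, 0), c(4, 0), c(12, 0), c(24, 0))
  seg2 <- segment_scanpath(make_recording(xy2), max_points = 4,
                           min_points = 2)[[1]]
  expect_equal(mean_velocity_per_image(seg2), 2)

  empty <- segment_scanpath(make_recording(rbind(c(0, 0), c(1, 1), c(2, 2)),
                                           valid = c(TRUE, FALSE, TRUE)),
                            max_points = 3, min_points = 2)[[1]]
  expect_error(mean_velocity_per_image(empty), "no transition")
})

test_that("MIC saturates on noiseless functional relationships", {
  x <- seq(0, 1, length.out = 100)
  expect_equal(mic_score(x, x), 1)
  expect_equal(mic_score(x, x^3), 1)
  expect_gt(mic_score(x, sin(4 * pi * x)), 0.6)   # non-monotone dependence
})

test_that("MIC is symmetric and invariant to strictly monotone transforms", {
  set.seed(41)
  x <- runif(200)
  y <- x^2 + rnorm(200, 0, 0.1)
  expect_equal(mic_score(x, y), mic_score(y, x), tolerance = 1e-12)
  expect_equal(mic_score(exp(3 * x), y), mic_score(x, y), tolerance = 1e-6)
  expect_equal(mic_score(x, rank(y)), mic_score(x, y), tolerance = 1e-6)
})

test_that("MIC stays near zero for independent variables", {
  set.seed(43)
  scores <- replicate(5, mic_score(runif(1000), runif(1000)))
  expect_lt(stats::median(scores), 0.2)
})

test_that("MIC validates its inputs", {
  expect_error(mic_score(1:40, 1:39), "equal length")
  expect_error(mic_score(1:10, 1:10), "at least 30")
  expect_error(mic_score(c(1:39, NA), 1:40), "non-finite")
})

test_that("MIC is sandwiched by exhaustive grid-search bounds", {
  set.seed(44)
  # soundness: the grid-search heuristic can never exceed the true maximum
  for (i in 1:8) {
    x <- runif(30); y <- runif(30)
    expect_lte(mic_score(x, y), brute_force_mic(x, y) + 1e-9)
  }
  # exactness on functional data, where the equal-frequency row partition is
  # optimal: heuristic and exhaustive search coincide
  x <- sort(runif(30))
  for (y in list(x, x^2, as.numeric(x > 0.5))) {
    expect_equal(mic_score(x, y), brute_force_mic(x, y), tolerance = 1e-9)
  }
  # tightness at larger n: at least the best exhaustively-found 2x2 grid
  for (i in 1:5) {
    x <- runif(200)
    y <- 0.5 * x + runif(200)
    expect_gte(mic_score(x, y), brute_force_mic_2x2(x, y) - 0.05)
  }
})

test_that("cohort correlation pairs one velocity per image with the child's CARS", {
  coh <- generate_cohort(cohort_spec(n_asd = 6, n_td = 4, duration_s = 6,
                                     seed = 3))
  segs <- unlist(lapply(coh$recordings, segment_scanpath), recursive = FALSE)
  corr <- correlate_cohort(coh$manifest, segs)
  expect_s3_class(corr, "velocity_severity")
  expect_true(all(corr$pairs$cars > 30))            # ASD only by default
  expect_true(all(corr$pairs$velocity >= 0))
  # a participant's CARS repeats across that participant's images
  reps <- tapply(corr$pairs$cars, corr$pairs$participant_id,
                 function(v) length(unique(v)))
  expect_true(all(reps == 1))
  # including the constant-CARS group adds the non-ASD pairs
  all_in <- correlate_cohort(coh$manifest, segs, include_constant = TRUE)
  expect_gt(all_in$n, corr$n)

  one <- cohort_manifest(coh$manifest$participants[1, , drop = FALSE])
  expect_error(correlate_cohort(one, segs[1:2]), "insufficient")
})

test_that("breaking the velocity-severity link weakens the correlation", {
  coh <- generate_cohort(cohort_spec(seed = 13))
  segs <- unlist(lapply(coh$recordings, segment_scanpath), recursive = FALSE)
  corr <- correlate_cohort(coh$manifest, segs)
  expect_gt(corr$mic, 0.6)

  # permuting severity across participants destroys the monotone link (rank
  # correlation collapses). MIC itself stays high: per-image velocities
  # cluster tightly per child, so velocity still predicts the (shuffled)
  # score through participant identity -- a real many-to-one dependence
  shuf <- coh$manifest
  set.seed(77)
  asd <- shuf$participants$group == "ASD"
  shuf$participants$cars[asd] <- sample(shuf$participants$cars[asd])
  corr_shuf <- correlate_cohort(shuf, segs)
  expect_lt(abs(cor(corr_shuf$pairs$velocity, corr_shuf$pairs$cars,
                    method = "spearman")), 0.35)
  expect_gt(cor(corr$pairs$velocity, corr$pairs$cars,
                method = "spearman"), 0.8)

  # true image-level independence: severity drawn iid per image sits at the
  # MIC independence baseline
  set.seed(78)
  v <- corr$pairs$velocity
  expect_lte(mic_score(v, runif(length(v), 30, 45)), 0.25)
})
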