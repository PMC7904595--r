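test_that("phantom volume matches the analytic ellipsoid volume", {
  # degenerate semi-axes -> empty phantom
  ph0 <- makePhantom(c(8L, 8L, 8L), semi_axes_mm = c(0, 0, 0),
                     spacing_mm = 10)
  expect_equal(sum(ph0@density), 0)
  # sphere on a fine grid: voxel sum x voxel volume ~ 4/3 pi r^3
  r <- 50
  ph <- makePhantom(c(56L, 56L, 56L), semi_axes_mm = c(r, r, r),
                    spacing_mm = 2)
  vol <- sum(ph@density) * 2^3
  expect_equal(vol, 4 / 3 * pi * r^3, tolerance = 0.02)
  expect_error(makePhantom(c(8L, 8L, 8L), semi_axes_mm = c(200, 50, 50),
                           spacing_mm = 10), "exceed")
})

test_that("signal is linear in phantom density", {
  sc <- small_scene()
  traj <- sampleTrajectory("drift", magnitude = 2, n_tr = 6, seed = 2)
  s1 <- forwardFidnav(sc$phantom, sc$coils, traj, noise = NULL)
  ph2 <- sc$phantom
  ph2@density <- 2 * ph2@density
  s2 <- forwardFidnav(ph2, sc$coils, traj, noise = NULL)
  expect_equal(fidSignal(s2), 2 * fidSignal(s1))
})

test_that("coil arrays are seed-deterministic with distinct centres", {
  ph <- small_scene()$phantom
  a <- makeCoilArray(ph, n_channels = 8, seed = 3)
  b <- makeCoilArray(ph, n_channels = 8, seed = 3)
  expect_identical(a@sens, b@sens)
  c2 <- makeCoilArray(ph, n_channels = 8, seed = 4)
  expect_false(identical(a@sens, c2@sens))
  expect_equal(nrow(unique(round(a@centers, 6))), 8)
  # single-channel array is valid; the correlation metric then refuses it
  one <- makeCoilArray(ph, n_channels = 1, seed = 1)
  s <- forwardFidnav(ph, one, sampleTrajectory("still", n_tr = 4),
                     noise = NULL)
  expect_error(cccMetric(s), "2 channels")
})

test_that("opposite coils see opposite-signed changes under a lateral
           shift", {
  ph <- small_scene()$phantom
  co <- makeCoilArray(ph, n_channels = 2, seed = 1,
                      centers = rbind(c(120, 0, 0), c(-120, 0, 0)))
  traj <- sampleTrajectory("still", n_tr = 2)
  traj@poses[2, 1] <- 10   # translate +x
  s <- forwardFidnav(ph, co, traj, noise = NULL)
  mags <- Mod(fidSignal(s))
  d <- mags[, 2] - mags[, 1]
  expect_gt(d[1], 0)   # coil on +x gains signal
  expect_lt(d[2], 0)   # coil on -x loses signal
})

test_that("trajectory archetypes have their defining shapes", {
  still <- sampleTrajectory("still", n_tr = 10)
  expect_equal(still@poses, matrix(0, 10, 6), ignore_attr = TRUE)
  # abrupt: constant before and after a single step at the event
  ab <- sampleTrajectory("abrupt", magnitude = 5, n_tr = 20,
                         event_times = 8, seed = 6)
  expect_equal(ab@poses[1:7, ], matrix(0, 7, 6), ignore_attr = TRUE)
  expect_equal(diff(ab@poses[8:20, 1]), rep(0, 12))
  disp <- sqrt(sum(ab@poses[8, 1:3]^2) +
                 sum((ab@poses[8, 4:6] * 60 * pi / 180)^2))
  expect_equal(disp, 5, tolerance = 1e-10)
  # drift ends at the target magnitude
  dr <- sampleTrajectory("drift", magnitude = 3, n_tr = 15, seed = 2)
  end <- sqrt(sum(dr@poses[15, 1:3]^2) +
                sum((dr@poses[15, 4:6] * 60 * pi / 180)^2))
  expect_equal(end, 3, tolerance = 1e-10)
  # zero-magnitude continuous walk stays at the identity
  cw <- sampleTrajectory("continuous", magnitude = 0, n_tr = 10, seed = 1)
  expect_equal(cw@poses, matrix(0, 10, 6), ignore_attr = TRUE)
  expect_error(sampleTrajectory("abrupt", n_tr = 10, event_times = 1),
               "event times")
  expect_error(sampleTrajectory("wiggle"), "arg")
})

test_that("noiseless still simulation is constant and scores zero", {
  s <- small_sim("still", n_tr = 10, noise = NULL)
  expect_equal(max(Mod(fidSignal(s) - fidSignal(s)[, 1])), 0)
  df <- subjectScores(trimPresteady(s, 3))
  expect_equal(unlist(df[-1]), setNames(rep(0, 8), names(df)[-1]))
})

test_that("signal change grows monotonically with displacement size", {
  sc <- small_scene()
  resp <- vapply(c(0.5, 1, 2, 3.5, 5), function(mm) {
    traj <- sampleTrajectory("abrupt", magnitude = mm, n_tr = 4,
                             event_times = 3, seed = 12)
    s <- forwardFidnav(sc$phantom, sc$coils, traj, noise = NULL)
    max(metricValues(deltaPrev(s)))
  }, numeric(1))
  expect_true(all(diff(resp) > 0))
})

test_that("end-to-end metrics are invariant to a global coil gain", {
  sc <- small_scene()
  co2 <- sc$coils
  co2@sens <- 3.7 * co2@sens
  traj <- sampleTrajectory("continuous", magnitude = 0.4, n_tr = 10,
                           seed = 8)
  s1 <- forwardFidnav(sc$phantom, sc$coils, traj, noise = NULL)
  s2 <- forwardFidnav(sc$phantom, co2, traj, noise = NULL)
  m1 <- fidnavMetrics(s1); m2 <- fidnavMetrics(s2)
  for (nm in names(m1))
    expect_equal(metricValues(m1[[nm]]), metricValues(m2[[nm]]),
                 tolerance = 1e-10)
})

test_that("grading bins weighted mean displacement as documented", {
  still <- sampleTrajectory("still", n_tr = 10)
  expect_equal(gradeFromTrajectory(still), 5L)
  # displacement just above the largest cut-point -> grade 1
  big <- sampleTrajectory("abrupt", magnitude = 1, n_tr = 10,
                          event_times = 2, seed = 3)
  big <- fidnavQC:::.scale_to_displacement(big, 5.6, rep(1, 10), 60)
  expect_equal(gradeFromTrajectory(big, rep(1, 10)), 1L)
  expect_error(gradeFromTrajectory(still, thresholds = c(1, 1, 2, 3)),
               "increasing")
  # k-space weighting changes the grade when motion is confined to the
  # low-weight periphery of acquisition
  n <- 40
  traj <- sampleTrajectory("still", n_tr = n)
  traj@poses[2:6, 1] <- 4   # early excursion, returns before the centre
  w <- stepWeights(defaultKspaceWeights(n))
  unweighted <- gradeFromTrajectory(traj, NULL)
  weighted <- gradeFromTrajectory(traj, w)
  expect_gt(weighted, unweighted)
})

test_that("integrated scores rise with motion magnitude across subjects", {
  sc <- small_scene()
  # fixed walk shape scaled over a magnitude sweep in the
  # motion-dominated regime, with noise on
  mags <- seq(0.3, 3, length.out = 20)
  scores <- vapply(seq_along(mags), function(i) {
    traj <- sampleTrajectory("continuous", magnitude = mags[i], n_tr = 24,
                             seed = 100)
    s <- forwardFidnav(sc$phantom, sc$coils, traj, tr_seconds = 1.54,
                       noise = noiseModel(), seed = 100 + i)
    scoreValue(integrateScore(cccMetric(s), 24, 1.54))
  }, numeric(1))
  expect_gt(cor(mags, scores, method = "spearman"), 0.95)
})

test_that("cohort generation is reproducible and honours the grade mix", {
  coh <- generateCohort(n_subjects = 5, grade_mix = rep(0.2, 5),
                        n_tr = 12, n_channels = 4,
                        grid_shape = c(12L, 12L, 12L), spacing_mm = 18,
                        seed = 42)
  expect_equal(sort(coh$manifest$grade), 1:5)
  expect_equal(nrow(coh$manifest), 5)
  coh2 <- generateCohort(n_subjects = 5, grade_mix = rep(0.2, 5),
                         n_tr = 12, n_channels = 4,
                         grid_shape = c(12L, 12L, 12L), spacing_mm = 18,
                         seed = 42)
  expect_identical(lapply(coh$series, fidSignal),
                   lapply(coh2$series, fidSignal))
  expect_identical(coh$manifest, coh2$manifest)
  expect_error(generateCohort(n_subjects = 3, grade_mix = rep(0.2, 5),
                              n_tr = 8, n_channels = 2,
                              grid_shape = c(10L, 10L, 10L),
                              spacing_mm = 18),
               "fewer subjects")
  expect_error(generateCohort(n_subjects = 4, grade_mix = rep(1, 5)),
               "sum to 1")
})

test_that("cohort files round-trip through the navigator CSV format", {
  out <- withr::local_tempdir()
  coh <- generateCohort(n_subjects = 2, grade_mix = c(0.5, 0, 0, 0, 0.5),
                        n_tr = 8, n_channels = 3,
                        grid_shape = c(12L, 12L, 12L), spacing_mm = 18,
                        seed = 7, out_dir = out)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  back <- readNavigatorCsv(coh$manifest$file[1])
  expect_equal(fidSignal(back), fidSignal(coh$series[[1]]))
  expect_equal(trSeconds(back), 1.54)
})
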