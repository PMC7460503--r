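test_that("phase schedule honors fractions and cyclic order", {
  # equal split, 8-sample cycle: fs/cadence = 8
  p <- gait_profile(speed = 1, cadence = 25,
                    phase_fractions = rep(0.25, 4))
  lab <- make_phase_schedule(p, 16, fs = 200)
  expect_identical(lab, rep(c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L), 2))

  # default fractions, long horizon: proportions near the fractions
  p <- gait_profile(speed = 1.0)
  lab <- make_phase_schedule(p, 10000, fs = 200)
  prop <- tabulate(lab + 1L, 4) / length(lab)
  expect_true(all(abs(prop - p$phase_fractions) < 0.02))

  # stance = HS + FF + HO is about 60% of the cycle
  expect_equal(sum(p$phase_fractions[1:3]), 0.6, tolerance = 1e-12)
  expect_lt(abs(sum(prop[1:3]) - 0.6), 0.02)

  # cyclic order: transitions only advance 0->1->2->3->0
  steps <- diff(lab)
  expect_true(all(steps %in% c(0L, 1L, -3L)))
})

test_that("label proportions over whole cycles match durations exactly", {
  p <- gait_profile(speed = 1.0, cadence = 0.8)
  d <- gaitphase:::phase_durations(p, fs = 200)
  n_cycles <- 7L
  lab <- make_phase_schedule(p, n_cycles * sum(d), fs = 200)
  # independent counting oracle
  counts <- vapply(0:3, function(k) sum(lab == k), integer(1))
  expect_identical(counts, unname(d) * n_cycles)
})

test_that("profile validation rejects bad inputs", {
  expect_error(gait_profile(speed = -1), "speed")
  expect_error(gait_profile(cadence = 0), "cadence")
  expect_error(gait_profile(phase_fractions = c(0.3, 0.3, 0.3, 0.3)),
               "sum to 1")
  expect_error(gait_profile(noise_sd = -0.1), "noise_sd")
  expect_error(make_phase_schedule(gait_profile(), 100, fs = -5), "fs")
})

test_that("synthesized recordings are deterministic, bounded and sized", {
  p <- gait_profile(speed = 1.0, seed = 11)
  r1 <- synthesize_recording(p, 120)
  expect_length(r1$ax, 24000)  # 120 s at 200 Hz
  r2 <- synthesize_recording(p, 120)
  expect_identical(r1$ax, r2$ax)
  expect_identical(r1$labels, r2$labels)
  # amplitude envelope of calf accelerometry
  for (a in list(r1$ax, r1$ay, r1$az)) {
    expect_gte(min(a), -1)
    expect_lte(max(a), 2)
    expect_true(all(is.finite(a)))
  }
})

test_that("noise-free signals are exactly cycle-periodic", {
  p <- gait_profile(speed = 1.0, noise_sd = 0)
  r <- synthesize_recording(p, 10)
  C <- sum(gaitphase:::phase_durations(p, 200))
  n <- length(r$ax)
  idx <- seq_len(n - C)
  expect_equal(r$ax[idx], r$ax[idx + C], tolerance = 1e-9)
  expect_equal(r$ay[idx], r$ay[idx + C], tolerance = 1e-9)
  expect_identical(r$labels[idx], r$labels[idx + C])
})

test_that("speed presets give distinct, monotone cadences", {
  cad <- vapply(c(0.78, 1.0, 1.25),
                function(s) gait_profile(speed = s)$cadence, numeric(1))
  expect_true(all(diff(cad) > 0))
})

test_that("cohort simulation isolates RNG per subject and seed", {
  recs <- simulate_cohort(speed = 1.0, subjects = 2, duration_s = 5,
                          seed = 3)
  expect_false(identical(recs[[1]]$ax, recs[[2]]$ax))
  again <- simulate_cohort(speed = 1.0, subjects = 2, duration_s = 5,
                           seed = 3)
  expect_identical(recs[[1]]$ax, again[[1]]$ax)
  other <- simulate_cohort(speed = 1.0, subjects = 2, duration_s = 5,
                           seed = 4)
  expect_false(identical(recs[[1]]$ax, other[[1]]$ax))
  # simulate() method mirrors the cohort generator
  sim <- simulate(gait_profile(speed = 1.0), nsim = 2, seed = 3,
                  duration_s = 5)
  expect_identical(sim[[1]]$ax, recs[[1]]$ax)
})

test_that("CSV round trip preserves a recording", {
  p <- gait_profile(speed = 1.25, seed = 5)
  rec <- synthesize_recording(p, 0.5)  # 100 samples
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$labels, rec$labels)
  expect_equal(back$ax, rec$ax, tolerance = 1e-9)
  expect_equal(back$ay, rec$ay, tolerance = 1e-9)
  expect_equal(back$az, rec$az, tolerance = 1e-9)
})

test_that("malformed recording files raise parse errors naming the line", {
  p <- gait_profile(seed = 2)
  rec <- synthesize_recording(p, 0.1)
  path <- withr::local_tempfile(fileext = ".csv")

  write_recording(rec, path)
  lines <- readLines(path)
  # missing column
  writeLines(gsub("^t,ax,ay,az,phase$", "t,ax,ay,phase", lines[1]),
             con = path)
  expect_error(read_recording(path), "missing column")

  # non-numeric acceleration cell on line 4
  bad <- lines
  bad[4] <- sub(",[^,]*,", ",abc,", bad[4])
  writeLines(bad, path)
  expect_error(read_recording(path), "line 4")

  # illegal phase code on line 3
  bad <- lines
  bad[3] <- sub(",[0-3]$", ",4", bad[3])
  writeLines(bad, path)
  expect_error(read_recording(path), "phase code.*line 3|line 3.*phase code")
})
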