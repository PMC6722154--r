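# Session data model, JSON dialect, roster and schedule.

test_that("default roster has 15 well-separated targets with the documented spans", {
  r <- default_roster()
  expect_equal(nrow(r), 15)
  expect_equal(max(r$azimuth_deg) - min(r$azimuth_deg), 180)
  expect_equal(max(r$elevation_deg) - min(r$elevation_deg), 110)
  expect_true(any(r$elevation_deg == 90 & !r$analyse_azimuth)) # straight up
  expect_gte(sum(r$side == "left"), 1)
  expect_gte(sum(r$side == "right"), 1)
  # side labels consistent with azimuth sign
  expect_true(all((r$side == "left") == (r$azimuth_deg < -5)))
  expect_true(all((r$side == "right") == (r$azimuth_deg > 5)))
  # pairwise great-circle separation >= 5 degrees (distinguishability)
  for (i in 1:14) for (j in (i + 1):15) {
    expect_gte(great_circle_angle(r$azimuth_deg[i], r$elevation_deg[i],
                                  r$azimuth_deg[j], r$elevation_deg[j]), 5)
  }
  # positions lie on the surfaces of the 6 x 7 x 3 room
  lay <- room_layout()
  expect_true(all(r$x_m >= -1e-9 & r$x_m <= lay$width_m + 1e-9))
  expect_true(all(r$y_m >= -1e-9 & r$y_m <= lay$depth_m + 1e-9))
  expect_true(all(r$z_m >= -1e-9 & r$z_m <= lay$height_m + 1e-9))
  on_surface <- abs(r$x_m) < 1e-9 | abs(r$x_m - lay$width_m) < 1e-9 |
    abs(r$y_m) < 1e-9 | abs(r$y_m - lay$depth_m) < 1e-9 |
    abs(r$z_m) < 1e-9 | abs(r$z_m - lay$height_m) < 1e-9
  expect_true(all(on_surface))
  # positions and stated true directions agree
  obs <- c(lay$observer_xy, lay$eye_height_m)
  d <- cbind(r$x_m - obs[1], r$y_m - obs[2], r$z_m - obs[3])
  ang <- vector_to_angles(d, lay$facing_heading_deg)
  expect_equal(ang$elevation_deg, r$elevation_deg, tolerance = 1e-9)
  ok_az <- r$analyse_azimuth
  expect_true(all(abs(circ_distance(ang$azimuth_deg[ok_az],
                                    r$azimuth_deg[ok_az])) < 1e-9))
})

test_that("schedules have block structure and lateral alternation", {
  r <- default_roster()
  s8 <- build_schedule(r, 8, "fixed")
  expect_length(s8, 120)
  s6 <- build_schedule(r, 6, "fixed")
  expect_length(s6, 90)
  side <- setNames(r$side, r$name)

  check_schedule <- function(s, reps) {
    # every target exactly once per block
    for (b in seq_len(reps)) {
      blk <- s[((b - 1) * 15 + 1):(b * 15)]
      expect_setequal(blk, r$name)
    }
    # lateral targets strictly alternate side (centers may interpose)
    lat <- side[s][side[s] != "center"]
    expect_true(all(lat[-1] != lat[-length(lat)]))
    # and in particular no two consecutive same-side entries
    expect_false(any(side[s][-1] != "center" &
                       side[s][-length(s)] == side[s][-1]))
  }
  check_schedule(s8, 8)
  for (seed in 1:5) {
    check_schedule(build_schedule(r, 6, "randomized", seed = seed), 6)
  }

  # seeded determinism; different seeds differ
  expect_identical(build_schedule(r, 6, "randomized", seed = 42),
                   build_schedule(r, 6, "randomized", seed = 42))
  expect_false(identical(build_schedule(r, 6, "randomized", seed = 1),
                         build_schedule(r, 6, "randomized", seed = 2)))
  # fixed mode ignores the seed
  expect_identical(build_schedule(r, 3, "fixed", seed = 1),
                   build_schedule(r, 3, "fixed", seed = 99))

  one_side <- r[r$side != "left", ]
  expect_error(build_schedule(one_side, 2), "alternation impossible")
})

test_that("a single-trial session converts north to straight ahead", {
  tr <- trials_from_angles(0, 0, "front_center")
  expect_equal(c(tr$e, tr$n, tr$u), c(0, 1, 0))
  s <- make_test_session(tr)
  p <- tempfile(fileext = ".json")
  write_session(s, p)
  s2 <- read_session(p)
  expect_equal(nrow(s2$trials), 1)
  a <- vector_to_angles(c(s2$trials$e, s2$trials$n, s2$trials$u),
                        s2$layout$facing_heading_deg)
  expect_equal(a$azimuth_deg, 0)
})

test_that("write/read round trip is the identity, bit-exact on vectors", {
  cfg <- sim_config(n_participants = 1, seed = 5)
  s <- simulate_session(cfg, 1)$day1
  p <- tempfile(fileext = ".json")
  write_session(s, p)
  s2 <- read_session(p)
  expect_identical(s2$trials$e, s$trials$e)
  expect_identical(s2$trials$n, s$trials$n)
  expect_identical(s2$trials$u, s$trials$u)
  expect_identical(s2$trials$index, as.integer(s$trials$index))
  expect_identical(s2$trials$condition, s$trials$condition)
  expect_identical(s2$trials$target, s$trials$target)
  expect_equal(s2$participant_id, s$participant_id)
  expect_equal(s2$rotation_side, s$rotation_side)
  expect_equal(s2$roster$name, s$roster$name)
  expect_equal(s2$roster$azimuth_deg, s$roster$azimuth_deg)
  expect_equal(s2$layout$facing_heading_deg, s$layout$facing_heading_deg)
})

test_that("a simulated day-1 EO block has 120 trials over 15 targets, 8 reps each", {
  cfg <- sim_config(n_participants = 1, seed = 2)
  s <- simulate_session(cfg, 1)$day1
  p <- tempfile(fileext = ".json")
  write_session(s, p)
  s2 <- read_session(p)
  eo <- s2$trials[s2$trials$condition == "EO", ]
  expect_equal(nrow(eo), 120)
  expect_equal(length(unique(eo$target)), 15)
  expect_true(all(table(eo$target) == 8))
  expect_true(all(tapply(eo$repetition, eo$target, function(x)
    identical(sort(x), 1:8))))
})

test_that("by-target order groups repetitions alphabetically; collected preserves order", {
  roster <- make_roster(room_layout(), c("B", "A", "L1", "R1"),
                        c(0, 0, -30, 30), c(0, 10, 0, 0))
  tr <- trials_from_angles(c(-30, 0, 0, 30), c(0, 0, 10, 0),
                           c("L1", "B", "A", "R1"))
  s <- make_test_session(tr, roster = roster)
  p <- tempfile(fileext = ".json")
  write_session(s, p, order = "by_target")
  raw <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  file_order <- vapply(raw$trials, function(t) t$target, "")
  expect_identical(file_order, c("A", "B", "L1", "R1"))

  write_session(s, p, order = "collected")
  raw <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  expect_identical(vapply(raw$trials, function(t) t$target, ""),
                   c("L1", "B", "A", "R1"))
  # reader recovers collected order from indices either way
  write_session(s, p, order = "by_target")
  expect_identical(read_session(p)$trials$target, c("L1", "B", "A", "R1"))
})

test_that("strict mode rejects corrupt vectors; lenient mode drops them with a flag", {
  tr <- trials_from_angles(c(0, 10), c(0, 0), "front_center")
  tr$e[2] <- 3; tr$n[2] <- 0; tr$u[2] <- 0 # norm 3: corrupt
  s <- make_test_session(tr)
  p <- tempfile(fileext = ".json")
  write_session(s, p)
  expect_error(read_session(p, strict = TRUE), "corrupt")
  s2 <- read_session(p, strict = FALSE)
  expect_equal(nrow(s2$trials), 1)
  expect_equal(attr(s2, "dropped_trials"), 1)

  # mildly off-norm vectors are renormalised, with the raw norm recorded
  tr <- trials_from_angles(c(0, 10), c(0, 0), "front_center")
  tr[, c("e", "n", "u")] <- tr[, c("e", "n", "u")] * 1.001
  s <- make_test_session(tr)
  write_session(s, p)
  s3 <- read_session(p, strict = FALSE)
  expect_equal(s3$trials$raw_norm, c(1.001, 1.001), tolerance = 1e-9)
  expect_equal(sqrt(s3$trials$e^2 + s3$trials$n^2 + s3$trials$u^2), c(1, 1),
               tolerance = 1e-12)
})

test_that("unknown top-level keys survive a round trip; bad JSON and versions error", {
  tr <- trials_from_angles(0, 0, "front_center")
  s <- make_test_session(tr, extra = list(gps = list(lat = 48.1, lon = 11.6),
                                          app_build = "2.0.1"))
  p <- tempfile(fileext = ".json")
  write_session(s, p)
  s2 <- read_session(p)
  expect_equal(s2$extra$app_build, "2.0.1")
  expect_equal(s2$extra$gps$lat, 48.1)

  writeLines("{not json", p)
  expect_error(read_session(p, strict = TRUE), "malformed JSON")
  writeLines('{"format_version": 99}', p)
  expect_error(read_session(p), "format_version")
  expect_error(read_session(tempfile()), "no such file")
})

test_that("validate_session reports unknown targets and unknown conditions", {
  tr <- trials_from_angles(c(0, 5), c(0, 0), c("front_center", "nowhere"))
  s <- make_test_session(tr)
  v <- validate_session(s)
  expect_true(any(grepl("nowhere", v)))
  tr2 <- trials_from_angles(0, 0, "front_center", condition = "XX")
  expect_true(any(grepl("condition", validate_session(make_test_session(tr2)))))
  good <- make_test_session(trials_from_angles(0, 0, "front_center"))
  expect_length(validate_session(good), 0)
})
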