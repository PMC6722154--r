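# Baselines, expected directions, error scoring, summaries, condition
# effects and questionnaire correlations.

noise_free_config <- function(...) {
  sim_config(n_participants = 2, azimuth_sd_deg = 1e-9,
             elevation_sd_deg = 1e-9, participant_bias_sd_deg = 0,
             mr_flip_prob = 0, contralateral_factor = 1, seed = 3, ...)
}

test_that("baseline equals the pointed direction for repeated identical vectors", {
  roster <- default_roster()
  az <- rep(c(30, -45), each = 8)
  el <- rep(c(10, 0), each = 8)
  tg <- rep(c("wall_high_right", "wall_mid_left"), each = 8)
  s <- make_test_session(trials_from_angles(az, el, tg))
  bl <- compute_baseline(s)
  expect_equal(bl$azimuth_deg[bl$target == "wall_high_right"], 30,
               tolerance = 1e-9)
  expect_equal(bl$elevation_deg[bl$target == "wall_mid_left"], 0,
               tolerance = 1e-9)
  expect_equal(bl$n, c(8, 8))
})

test_that("zero-noise simulator baselines equal the roster's true directions", {
  one <- simulate_session(noise_free_config(), 1)
  bl <- compute_baseline(list(one$day1, one$day2))
  r <- one$day1$roster
  i <- match(bl$target, r$name)
  ok <- r$analyse_azimuth[i]
  expect_lt(max(abs(circ_distance(bl$azimuth_deg[ok], r$azimuth_deg[i][ok]))),
            1e-6)
  expect_lt(max(abs(bl$elevation_deg - r$elevation_deg[i])), 1e-6)
})

test_that("baseline standard error shrinks as circ_sd/sqrt(n)", {
  set.seed(55)
  kappa <- 50
  sd_deg <- sqrt(-2 * log(besselI(kappa, 1, TRUE) / besselI(kappa, 0, TRUE))) *
    180 / pi
  n <- 8
  means <- replicate(400, circ_mean(rvonmises(n, 0, kappa))$mean_deg)
  se_mc <- sqrt(mean(means^2))
  expect_equal(se_mc, sd_deg / sqrt(n), tolerance = 0.15)
})

test_that("expected directions: MR shifts azimuth by -/+90, others unchanged", {
  e <- expected_direction(30, 10, "MR", mr_side = "right")
  expect_equal(e$azimuth_deg, -60)
  expect_equal(e$elevation_deg, 10) # elevation never transformed
  expect_equal(expected_direction(30, 10, "MR", mr_side = "left")$azimuth_deg,
               120)
  expect_equal(expected_direction(30, 10, "RR")$azimuth_deg, 30)
  expect_equal(expected_direction(30, 10, "EC")$azimuth_deg, 30)
  # paper-literal mode: baseline unchanged even for MR
  expect_equal(expected_direction(30, 10, "MR", mr_side = "right",
                                  apply_mr_transform = FALSE)$azimuth_deg, 30)
})

test_that("error records: zero at expectation, signed wraparound, elevation-only zenith", {
  roster <- default_roster()
  # EO baseline at the true directions, one EC trial 20 deg right of a
  # target whose baseline azimuth is 350 (i.e. -10)
  eo <- trials_from_angles(rep(c(-10, 0), each = 4), rep(c(0, 90), each = 4),
                           rep(c("front_center", "zenith"), each = 4))
  ec <- trials_from_angles(c(10, 0), c(0, 80), c("front_center", "zenith"),
                           condition = "EC")
  ec$index <- ec$index + nrow(eo)
  s <- make_test_session(rbind(eo, ec))
  err <- compute_errors(s)
  fc <- err[err$condition == "EC" & err$target == "front_center", ]
  expect_equal(fc$azimuth_error_deg, 20, tolerance = 1e-9)
  expect_equal(fc$elevation_error_deg, 0, tolerance = 1e-9)
  ze <- err[err$condition == "EC" & err$target == "zenith", ]
  expect_true(is.na(ze$azimuth_error_deg)) # scored in elevation only
  expect_equal(ze$elevation_error_deg, -10, tolerance = 1e-9)
  expect_equal(ze$total_angle_error_deg, 10, tolerance = 1e-9)
  # EO trials at their own baseline: zero error
  eo_err <- err[err$condition == "EO" & err$target == "front_center", ]
  expect_lt(max(abs(eo_err$azimuth_error_deg)), 1e-9)
})

test_that("a perfect mental rotator scores near zero with the MR transform, +/-90 without", {
  one <- simulate_session(noise_free_config(), 1) # rotates right, imagines left
  sessions <- list(one$day1, one$day2)
  with_tf <- compute_errors(sessions, apply_mr_transform = TRUE)
  mr <- with_tf[with_tf$condition == "MR" & !is.na(with_tf$azimuth_error_deg), ]
  expect_lt(max(abs(mr$azimuth_error_deg)), 1e-6)

  without <- compute_errors(sessions, apply_mr_transform = FALSE)
  mr0 <- without[without$condition == "MR" & !is.na(without$azimuth_error_deg), ]
  expect_true(all(abs(abs(mr0$azimuth_error_deg) - 90) < 1e-6))
})

test_that("scoring is equivariant under a common rotation of vectors and facing", {
  cfg <- sim_config(n_participants = 1, seed = 11)
  s <- simulate_session(cfg, 1)$day1
  base_err <- compute_errors(s)

  rot <- 73
  s2 <- s
  s2$layout$facing_heading_deg <- s$layout$facing_heading_deg + rot
  th <- rot / 180 * pi # rotate all vectors clockwise (heading sense) by rot
  e <- s$trials$e; n <- s$trials$n
  s2$trials$e <- e * cos(th) + n * sin(th)
  s2$trials$n <- -e * sin(th) + n * cos(th)
  rot_err <- compute_errors(s2)
  expect_equal(rot_err$azimuth_error_deg, base_err$azimuth_error_deg,
               tolerance = 1e-9)
  expect_equal(rot_err$elevation_error_deg, base_err$elevation_error_deg,
               tolerance = 1e-9)
  expect_equal(rot_err$total_angle_error_deg, base_err$total_angle_error_deg,
               tolerance = 1e-9)
})

test_that("summaries group correctly and mark contralateral eccentric targets", {
  err <- data.frame(
    participant_id = "p1",
    condition = rep(c("EC", "RR"), each = 4),
    target = rep(c("eccentric_left", "front_center"), 4),
    repetition = 1, day = 1,
    azimuth_error_deg = c(rep(0, 4), 10, -10, 10, -10),
    elevation_error_deg = 0, total_angle_error_deg = 0,
    sensor_flip_suspect = FALSE, stringsAsFactors = FALSE
  )
  sm <- summarize_errors(err, by = "condition")
  expect_equal(sm$mean_abs_az_error_deg[sm$condition == "EC"], 0)
  expect_equal(sm$mean_abs_az_error_deg[sm$condition == "RR"], 10)
  expect_equal(sm$n, c(4, 4))

  sm2 <- summarize_errors(err, by = c("condition", "target"),
                          roster = default_roster(), pointing_hand = "right")
  expect_true(all(sm2$contralateral_eccentric[sm2$target == "eccentric_left"]))
  expect_false(any(sm2$contralateral_eccentric[sm2$target == "front_center"]))
})

test_that("rm-ANOVA F matches aov and equals the paired t^2 with two conditions", {
  set.seed(61)
  tab <- expand.grid(participant_id = paste0("p", 1:10),
                     condition = c("EC", "RR", "MR"),
                     stringsAsFactors = FALSE)
  tab$value <- rnorm(30) + rep(c(0, 0.5, 1.2), each = 10) +
    rep(rnorm(10), 3)
  eff <- condition_effect(tab, n_perm = 199, seed = 1)
  fit <- aov(value ~ condition + Error(factor(participant_id)),
             data = tab)
  aov_tab <- summary(fit)[["Error: Within"]][[1]]
  expect_equal(eff$F, aov_tab["condition", "F value"], tolerance = 1e-10)
  expect_equal(eff$df_between, 2)
  expect_equal(eff$df_within, 18)
  expect_equal(eff$p_parametric, aov_tab["condition", "Pr(>F)"],
               tolerance = 1e-10)

  # two conditions: F == t^2 from the paired t test
  tab2 <- tab[tab$condition %in% c("EC", "MR"), ]
  eff2 <- condition_effect(tab2, n_perm = 99, seed = 1)
  tt <- t.test(value ~ condition, data = tab2, paired = TRUE)
  expect_equal(eff2$F, unname(tt$statistic)^2, tolerance = 1e-8)

  # a strongly shifted condition is detected by the permutation test
  tab$value[tab$condition == "MR"] <- tab$value[tab$condition == "MR"] + 10
  eff3 <- condition_effect(tab, n_perm = 999, seed = 2)
  expect_lte(eff3$p_permutation, 0.005)

  bad <- tab[-1, ]
  expect_error(condition_effect(bad), "incomplete")
})

test_that("questionnaire correlations: exact, null and recovery behaviour", {
  met <- data.frame(participant_id = paste0("p", 1:50), m = rnorm(50))
  sc <- data.frame(participant_id = paste0("p", 1:50))
  sc$s_exact <- -2 * met$m
  set.seed(71)
  sc$s_noise <- rnorm(50)
  out <- correlate_selfreport(met, sc,
                              list(c("m", "s_exact"), c("m", "s_noise")))
  expect_equal(out$r[1], -1, tolerance = 1e-12)
  expect_lt(out$p[1], 1e-12)
  expect_lt(abs(out$r[2]), 0.35)
  expect_true(all(out$n == 50))
  expect_true(all(out$p_adj >= out$p - 1e-15))

  # population r = 0.6 recovered within +/-0.1 at n = 200
  set.seed(72)
  x <- rnorm(200)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(200)
  met2 <- data.frame(participant_id = paste0("q", 1:200), m = x)
  sc2 <- data.frame(participant_id = paste0("q", 1:200), s = y)
  out2 <- correlate_selfreport(met2, sc2, list(c("m", "s")))
  expect_lt(abs(out2$r - 0.6), 0.1)

  # zero variance -> undefined flag, not an error
  sc2$flat <- 1
  out3 <- correlate_selfreport(met2, sc2, list(c("m", "flat")))
  expect_true(out3$undefined)
  expect_true(is.na(out3$r))
})

test_that("excluding eccentric targets shrinks the azimuth/elevation SD ratio", {
  cfg <- sim_config(n_participants = 6, seed = 17, contralateral_factor = 2)
  co <- simulate_cohort(cfg)
  ts <- target_summaries(co$sessions)
  ts <- ts[ts$condition == "EO", ]
  r <- default_roster()
  i <- match(ts$target, r$name)
  ratio_all <- mean(ts$az_sd_deg[r$analyse_azimuth[i]], na.rm = TRUE) /
    mean(ts$el_sd_deg, na.rm = TRUE)
  keep <- abs(r$azimuth_deg[i]) <= 60 & r$analyse_azimuth[i]
  ratio_central <- mean(ts$az_sd_deg[keep], na.rm = TRUE) /
    mean(ts$el_sd_deg, na.rm = TRUE)
  expect_lt(ratio_central, ratio_all)
})

test_that("report bundle lists tables, figures and skipped analyses", {
  cfg <- sim_config(n_participants = 3, seed = 23)
  co <- simulate_cohort(cfg)
  an <- analyze_cohort(co$sessions, n_perm = 49)
  out <- tempfile()
  manifest <- write_report(an, co$sessions, out,
                           figure_targets = c("front_center", "zenith"))
  paths <- vapply(manifest$artifacts, function(a) a$path, "")
  expect_true("summary.json" %in% paths)
  expect_true("condition_summary.csv" %in% paths)
  # one polar histogram per requested target and plane
  expect_true(all(c("figures/polar_azimuth_front_center.png",
                    "figures/polar_elevation_front_center.png",
                    "figures/polar_azimuth_zenith.png",
                    "figures/polar_elevation_zenith.png") %in% paths))
  expect_true(all(file.exists(file.path(out, paths))))
  # no scores supplied -> correlations listed as skipped
  expect_true(any(grepl("selfreport", manifest$skipped)))
  # summary JSON parses and round-trips the key quantities
  sj <- jsonlite::fromJSON(file.path(out, "summary.json"))
  expect_equal(sj$n_participants, 3)
  expect_true(all(c("EO", "EC", "RR", "MR") %in%
                    sj$condition_summary$condition))
  unlink(out, recursive = TRUE)
})
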