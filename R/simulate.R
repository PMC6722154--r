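## Seeded generative model of pointing sessions: the statistical structure
## the analysis pipeline assumes, standing in for a study cohort.
##
## Azimuth noise is von Mises about the expected direction (mental rotation
## adds flip components at configured angles); elevation noise is truncated
## normal on [-90, 90] since elevation cannot wrap. Dispersion defaults are
## anchored to the published eyes-open values (7.93 deg azimuth, 3.83 deg
## elevation); the eyes-closed / real-rotation / mental-rotation multipliers
## are free parameters chosen to reproduce the qualitative difficulty
## ordering, not published values.

#' Simulation configuration
#'
#' @param n_participants cohort size (default 20).
#' @param layout a [room_layout()].
#' @param roster a `target_roster` (default [default_roster()]).
#' @param repetitions named list of repetition counts per condition block:
#'   day-1 EO, EC, day-2 EO, RR, MR.
#' @param azimuth_sd_deg eyes-open azimuth dispersion, degrees (circular SD).
#' @param elevation_sd_deg eyes-open elevation SD, degrees.
#' @param condition_multipliers dispersion multipliers for EC/RR/MR relative
#'   to EO (free parameters, not published values).
#' @param participant_bias_sd_deg SD of the per-participant constant
#'   azimuth/elevation bias, degrees.
#' @param mr_flip_prob probability that a mental-rotation trial lands on a
#'   flip component instead of the main mode.
#' @param flip_angles_deg candidate flip offsets, degrees (default
#'   c(-90, 90, 180)).
#' @param flip_angle_probs sampling weights over `flip_angles_deg`.
#' @param contralateral_factor azimuth-SD inflation for eccentric targets
#'   (|true azimuth| >= 75 deg) contralateral to the pointing hand.
#' @param sensor_flip_prob probability of a 180-degree compass-flip artifact
#'   on trials whose target elevation is below -15 deg (default 0).
#' @param schedule_mode "fixed" or "randomized" target order.
#' @param seed master seed; together with the participant index it fully
#'   determines a session.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 20,
                       layout = room_layout(),
                       roster = default_roster(layout),
                       repetitions = list(EO1 = 8, EC = 6, EO2 = 6,
                                          RR = 6, MR = 6),
                       azimuth_sd_deg = 7.93,
                       elevation_sd_deg = 3.83,
                       condition_multipliers = c(EO = 1, EC = 1.5,
                                                 RR = 2, MR = 2.5),
                       participant_bias_sd_deg = 2,
                       mr_flip_prob = 0.2,
                       flip_angles_deg = c(-90, 90, 180),
                       flip_angle_probs = NULL,
                       contralateral_factor = 2,
                       sensor_flip_prob = 0,
                       schedule_mode = c("fixed", "randomized"),
                       seed = 1) {
  schedule_mode <- match.arg(schedule_mode)
  if (is.null(flip_angle_probs)) {
    flip_angle_probs <- rep(1 / length(flip_angles_deg),
                            length(flip_angles_deg))
  }
  stopifnot(
    n_participants >= 1,
    azimuth_sd_deg > 0, elevation_sd_deg > 0,
    all(condition_multipliers >= 1),
    mr_flip_prob >= 0, mr_flip_prob <= 1,
    sensor_flip_prob >= 0, sensor_flip_prob <= 1,
    contralateral_factor >= 1,
    length(flip_angle_probs) == length(flip_angles_deg),
    all(flip_angle_probs >= 0), sum(flip_angle_probs) > 0
  )
  structure(
    list(
      n_participants = n_participants, layout = layout, roster = roster,
      repetitions = repetitions,
      azimuth_sd_deg = azimuth_sd_deg, elevation_sd_deg = elevation_sd_deg,
      condition_multipliers = condition_multipliers,
      participant_bias_sd_deg = participant_bias_sd_deg,
      mr_flip_prob = mr_flip_prob,
      flip_angles_deg = flip_angles_deg,
      flip_angle_probs = flip_angle_probs / sum(flip_angle_probs),
      contralateral_factor = contralateral_factor,
      sensor_flip_prob = sensor_flip_prob,
      schedule_mode = schedule_mode,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

## concentration giving a target circular SD (degrees): solve
## sqrt(-2 log A(kappa)) = sd
kappa_for_sd <- function(sd_deg) {
  vm_A_inv(exp(-(sd_deg / DEG)^2 / 2))
}

## truncated normal on [lo, hi] via inverse-CDF
rtruncnorm <- function(n, mean, sd, lo = -90, hi = 90) {
  if (sd == 0) return(pmin(hi, pmax(lo, rep(mean, length.out = n))))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (any(phi - plo < 1e-12)) {
    stop("infeasible truncation: no mass in [lo, hi]")
  }
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

## deterministic sub-seed per (seed, participant, stream), kept < 2^31
stream_seed <- function(seed, participant_index, stream) {
  as.integer((as.numeric(seed) * 2654435 + participant_index * 97003 +
                stream * 101) %% 2147483123)
}

#' Simulate one participant (two days)
#'
#' Draws a per-participant constant bias, then for every scheduled trial an
#' azimuth from a von Mises centred at the expected direction (for MR, a
#' mixture with flip components at the configured angles) and an elevation
#' from a truncated normal on [-90, 90]. Eccentric targets contralateral to
#' the pointing hand get inflated azimuth dispersion; trials at strongly
#' downward targets can carry a 180-degree compass-flip artifact. Bias,
#' schedule, noise and artifact draws use separate named random streams, so
#' enabling an artifact does not perturb the other draws under the same
#' seed. Fully reproducible from (seed, participant_index).
#'
#' Day 1 runs EO then EC; day 2 runs EO, RR, MR in that order. A perfect
#' mental rotator is simulated: MR trial directions are centred on the
#' target azimuth minus 90 degrees for an imagined rightward rotation (plus
#' 90 for leftward). Real rotation leaves the world-frame target direction
#' unchanged.
#'
#' @param config a [sim_config()].
#' @param participant_index 1-based participant number.
#' @param rotation_side "left" or "right"; default balances by parity.
#' @param pointing_hand pointing hand (default "right").
#' @return list with `day1` and `day2` (`pointing_session` objects) and
#'   `truth` (latent bias, per-trial flip/artifact indicators, expected
#'   directions, kappas).
#' @export
simulate_session <- function(config, participant_index,
                             rotation_side = NULL, pointing_hand = "right") {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(rotation_side)) {
    rotation_side <- if (participant_index %% 2 == 1) "right" else "left"
  }
  mr_side <- opposite_side(rotation_side)
  roster <- config$roster
  reps <- config$repetitions
  pid <- sprintf("sim%03d", participant_index)

  ## stream 1: participant bias
  set.seed(stream_seed(config$seed, participant_index, 1))
  bias_az <- stats::rnorm(1, 0, config$participant_bias_sd_deg)
  bias_el <- stats::rnorm(1, 0, config$participant_bias_sd_deg)

  ## stream 2: schedules
  blocks <- list(
    list(day = 1L, condition = "EO", reps = reps$EO1),
    list(day = 1L, condition = "EC", reps = reps$EC),
    list(day = 2L, condition = "EO", reps = reps$EO2),
    list(day = 2L, condition = "RR", reps = reps$RR),
    list(day = 2L, condition = "MR", reps = reps$MR)
  )
  sched <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    build_schedule(roster, b$reps, mode = config$schedule_mode,
                   seed = stream_seed(config$seed, participant_index,
                                      20L + i))
    })

  mult <- config$condition_multipliers
  true_az <- stats::setNames(roster$azimuth_deg, roster$name)
  true_el <- stats::setNames(roster$elevation_deg, roster$name)
  contra <- stats::setNames(
    abs(roster$azimuth_deg) >= 75 &
      roster$side == opposite_side(pointing_hand),
    roster$name
  )

  all_trials <- list()
  truth_rows <- list()
  idx <- 0L
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    targets <- sched[[bi]]
    nt <- length(targets)
    sd_az <- config$azimuth_sd_deg * mult[[b$condition]]
    sd_el <- config$elevation_sd_deg * mult[[b$condition]]

    center_az <- wrap_angle(true_az[targets] + bias_az)
    if (b$condition == "MR") {
      center_az <- wrap_angle(center_az + if (mr_side == "right") -90 else 90)
    }
    center_el <- pmin(90, pmax(-90, true_el[targets] + bias_el))

    sd_az_t <- ifelse(contra[targets], sd_az * config$contralateral_factor,
                      sd_az)

    ## stream 3x: flips (MR mixture + sensor artifact)
    set.seed(stream_seed(config$seed, participant_index, 40L + bi))
    flip_offset <- rep(0, nt)
    mr_flip <- rep(FALSE, nt)
    if (b$condition == "MR" && config$mr_flip_prob > 0) {
      mr_flip <- stats::runif(nt) < config$mr_flip_prob
      flip_offset[mr_flip] <- config$flip_angles_deg[
        sample.int(length(config$flip_angles_deg), sum(mr_flip),
                   replace = TRUE, prob = config$flip_angle_probs)]
    }
    sensor_flip <- rep(FALSE, nt)
    if (config$sensor_flip_prob > 0) {
      low <- true_el[targets] < -15
      sensor_flip <- low & stats::runif(nt) < config$sensor_flip_prob
    }

    ## stream 4x: pointing noise
    set.seed(stream_seed(config$seed, participant_index, 60L + bi))
    az <- numeric(nt)
    for (i in seq_len(nt)) {
      mu <- wrap_angle(center_az[i] + flip_offset[i])
      az[i] <- if (sd_az_t[i] == 0) mu else
        rvonmises(1, mu, kappa_for_sd(sd_az_t[i]))
    }
    el <- rtruncnorm(nt, center_el, sd_el)
    az[sensor_flip] <- wrap_angle(az[sensor_flip] + 180)

    v <- angles_to_vector(az, el, config$layout$facing_heading_deg)
    rep_count <- stats::ave(seq_len(nt), targets, FUN = seq_along)
    all_trials[[bi]] <- data.frame(
      index = idx + seq_len(nt),
      day = b$day, condition = b$condition, target = targets,
      repetition = rep_count,
      e = v[, "e"], n = v[, "n"], u = v[, "u"],
      flags = "",
      stringsAsFactors = FALSE
    )
    truth_rows[[bi]] <- data.frame(
      index = idx + seq_len(nt),
      condition = b$condition, target = targets,
      expected_az = unname(center_az), expected_el = unname(center_el),
      sd_az = unname(sd_az_t), sd_el = sd_el,
      mr_flip = mr_flip, flip_offset = flip_offset,
      sensor_flip = sensor_flip,
      stringsAsFactors = FALSE
    )
    idx <- idx + nt
  }
  trials <- do.call(rbind, all_trials)
  truth <- list(
    participant_id = pid,
    bias_az = bias_az, bias_el = bias_el,
    rotation_side = rotation_side, mr_side = mr_side,
    trials = do.call(rbind, truth_rows)
  )

  mk <- function(day) {
    pointing_session(
      participant_id = pid, day = day,
      trials = trials[trials$day == day, , drop = FALSE],
      roster = roster, layout = config$layout,
      pointing_hand = pointing_hand, handedness = pointing_hand,
      rotation_side = rotation_side
    )
  }
  list(day1 = mk(1L), day2 = mk(2L), truth = truth)
}

#' Simulate a cohort
#'
#' Rotation sides are balanced to within one participant. Returns all
#' sessions plus the full ground-truth record (latent biases, flips, true
#' directions) for recovery tests.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort` with `sessions` (flat list of
#'   `pointing_session`, two per participant) and `truth` (per-participant
#'   latents).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$n_participants >= 2)
  sessions <- list()
  truth <- list()
  for (i in seq_len(config$n_participants)) {
    one <- simulate_session(config, i)
    sessions[[length(sessions) + 1]] <- one$day1
    sessions[[length(sessions) + 1]] <- one$day2
    truth[[one$truth$participant_id]] <- one$truth
  }
  structure(list(sessions = sessions, truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d participants, %d sessions, seed %d\n",
              x$config$n_participants, length(x$sessions), x$config$seed))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' One session JSON per participant-day plus a ground-truth JSON sidecar.
#'
#' @param cohort a `sim_cohort`.
#' @param out_dir output directory.
#' @return character vector of written session paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(cohort$sessions, function(s) {
    p <- file.path(out_dir,
                   sprintf("%s_day%d.json", s$participant_id, s$day))
    write_session(s, p)
    p
  }, "")
  truth <- lapply(cohort$truth, function(t) {
    t$trials <- t$trials
    t
  })
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = I(17), dataframe = "rows",
                       pretty = TRUE)
  invisible(paths)
}
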