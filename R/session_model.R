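## Session data model: room layout, target roster, trials, and the
## pointing-session JSON dialect (format_version 1, flat trial list).

CONDITIONS <- c("EO", "EC", "RR", "MR")

#' Room layout
#'
#' Describes the testing room and the observer's pose inside it. The default
#' matches a medium-sized testing room of about 6 x 7 m with the participant
#' standing near one end, facing along the room's long axis (compass North by
#' convention).
#'
#' @param width_m,depth_m,height_m room dimensions in meters.
#' @param observer_xy observer position (x = across width, y = along depth),
#'   meters; must lie inside the footprint.
#' @param eye_height_m eye/device height in meters.
#' @param facing_heading_deg compass heading the participant faces (degrees
#'   clockwise from North).
#' @return an object of class `room_layout`.
#' @export
room_layout <- function(width_m = 6, depth_m = 7, height_m = 3,
                        observer_xy = c(3, 0.75), eye_height_m = 1.6,
                        facing_heading_deg = 0) {
  stopifnot(width_m > 0, depth_m > 0, height_m > 0, eye_height_m > 0)
  if (observer_xy[1] < 0 || observer_xy[1] > width_m ||
      observer_xy[2] < 0 || observer_xy[2] > depth_m) {
    stop("observer position outside the room footprint")
  }
  structure(
    list(
      width_m = width_m, depth_m = depth_m, height_m = height_m,
      observer_xy = as.numeric(observer_xy), eye_height_m = eye_height_m,
      facing_heading_deg = facing_heading_deg
    ),
    class = "room_layout"
  )
}

#' @export
print.room_layout <- function(x, ...) {
  cat(sprintf(
    "Room %g x %g x %g m; observer at (%g, %g), eye height %g m, facing %g deg\n",
    x$width_m, x$depth_m, x$height_m, x$observer_xy[1], x$observer_xy[2],
    x$eye_height_m, x$facing_heading_deg
  ))
  invisible(x)
}

## Side label from body azimuth: left < -5 deg, right > +5 deg, else center.
azimuth_side <- function(azimuth_deg) {
  ifelse(azimuth_deg < -5, "left", ifelse(azimuth_deg > 5, "right", "center"))
}

## Cast a ray from the observer's eye along (azimuth, elevation) until it
## hits a wall, the floor or the ceiling; returns the room-frame xyz of the
## hit point. Room frame: x across width (east when facing north), y along
## depth (towards the far wall), z up.
ray_to_room_boundary <- function(layout, azimuth_deg, elevation_deg) {
  v <- angles_to_vector(azimuth_deg, elevation_deg, 0)
  o <- c(layout$observer_xy, layout$eye_height_m)
  d <- c(v[1, "e"], v[1, "n"], v[1, "u"])
  lims <- rbind(
    c(0, layout$width_m),
    c(0, layout$depth_m),
    c(0, layout$height_m)
  )
  ts <- c()
  for (i in 1:3) {
    if (abs(d[i]) > 1e-12) {
      for (bound in lims[i, ]) {
        t <- (bound - o[i]) / d[i]
        if (t > 1e-9) ts <- c(ts, t)
      }
    }
  }
  t <- min(ts)
  o + t * d
}

#' Build a target roster from direction angles
#'
#' Positions are derived by casting each direction ray from the observer to
#' the nearest room surface, so every target lies on a wall, the floor or
#' the ceiling of the given layout.
#'
#' @param layout a [room_layout()].
#' @param names character vector of target names.
#' @param azimuth_deg,elevation_deg true body-referenced direction of each
#'   target, degrees.
#' @param analyse_azimuth logical; `FALSE` marks a target (e.g. straight up)
#'   whose azimuth is not analysable.
#' @return a data.frame of class `target_roster` with columns `name`, `x_m`,
#'   `y_m`, `z_m`, `azimuth_deg`, `elevation_deg`, `side`, `analyse_azimuth`.
#' @export
make_roster <- function(layout, names, azimuth_deg, elevation_deg,
                        analyse_azimuth = NULL) {
  stopifnot(length(names) == length(azimuth_deg),
            length(names) == length(elevation_deg),
            !anyDuplicated(names))
  if (is.null(analyse_azimuth)) analyse_azimuth <- abs(elevation_deg) <= 89.9
  pos <- t(vapply(
    seq_along(names),
    function(i) ray_to_room_boundary(layout, azimuth_deg[i], elevation_deg[i]),
    numeric(3)
  ))
  out <- data.frame(
    name = names,
    x_m = pos[, 1], y_m = pos[, 2], z_m = pos[, 3],
    azimuth_deg = azimuth_deg,
    elevation_deg = elevation_deg,
    side = azimuth_side(azimuth_deg),
    analyse_azimuth = analyse_azimuth,
    stringsAsFactors = FALSE
  )
  class(out) <- c("target_roster", "data.frame")
  out
}

#' Default 15-target roster
#'
#' Fifteen named targets spanning exactly 180 degrees of body azimuth
#' (-90 to +90) and 110 degrees of elevation (-20 to +90), including a
#' straight-up target analysed in elevation only, five left, five right and
#' five central targets, and the strongly eccentric left/right pair at
#' +-90 degrees. The published studies name their targets but do not print
#' coordinates, so this roster uses systematic names at geometrically
#' plausible positions; rosters are fully user-configurable via
#' [make_roster()].
#'
#' @param layout a [room_layout()] (default 6 x 7 m room).
#' @return a `target_roster` data.frame with 15 rows.
#' @export
default_roster <- function(layout = room_layout()) {
  make_roster(
    layout,
    names = c(
      "eccentric_left", "eccentric_right",
      "corner_low_left", "corner_low_right", "floor_front",
      "wall_mid_left", "wall_mid_right", "front_center",
      "wall_high_left", "wall_high_right", "front_high",
      "ceiling_left", "ceiling_right", "ceiling_front", "zenith"
    ),
    azimuth_deg = c(-90, 90, -60, 60, 0, -45, 45, 0, -30, 30, 0, -60, 60, 0, 0),
    elevation_deg = c(0, 0, -20, -20, -20, 10, 10, 0, 40, 40, 55, 65, 65, 75, 90)
  )
}

#' Pseudorandomised target schedule
#'
#' Builds the presentation order for one condition: `repetitions` blocks in
#' which every target appears exactly once and lateral (left/right) targets
#' strictly alternate side; central targets may fall anywhere. `mode =
#' "fixed"` returns one canonical order per block, independent of the seed
#' (the behaviour of the original app, whose order was hard-coded);
#' `mode = "randomized"` draws a fresh constrained permutation per block,
#' reproducibly under `seed`.
#'
#' @param roster a `target_roster`.
#' @param repetitions number of blocks (one repetition of every target each).
#' @param mode "fixed" or "randomized".
#' @param seed integer seed used for `mode = "randomized"`.
#' @return character vector of target names, length
#'   `repetitions * nrow(roster)`.
#' @export
build_schedule <- function(roster, repetitions, mode = c("fixed", "randomized"),
                           seed = 1) {
  mode <- match.arg(mode)
  stopifnot(repetitions >= 1)
  left <- roster$name[roster$side == "left"]
  right <- roster$name[roster$side == "right"]
  center <- roster$name[roster$side == "center"]
  n_lat <- length(left) + length(right)
  if (n_lat > 0 && (length(left) == 0 || length(right) == 0)) {
    stop("alternation impossible: lateral targets on one side only")
  }
  if (abs(length(left) - length(right)) > 1) {
    stop("alternation impossible: left/right counts differ by more than 1")
  }

  ## one block: interleave laterals (alternating side) and place centers
  make_block <- function(randomize, prev_side) {
    l <- left; r <- right; ce <- center
    if (randomize) {
      l <- sample(l); r <- sample(r); ce <- sample(ce)
    } else {
      l <- sort(l); r <- sort(r); ce <- sort(ce)
    }
    start_left <- if (length(l) != length(r)) {
      length(l) > length(r)
    } else if (randomize) {
      if (!is.na(prev_side) && prev_side %in% c("left", "right")) {
        prev_side == "right"
      } else {
        stats::runif(1) < 0.5
      }
    } else {
      TRUE
    }
    lat <- character(0)
    a <- if (start_left) l else r
    b <- if (start_left) r else l
    for (i in seq_len(max(length(a), length(b)))) {
      if (i <= length(a)) lat <- c(lat, a[i])
      if (i <= length(b)) lat <- c(lat, b[i])
    }
    ## insert centers: randomized -> at random gaps; fixed -> evenly spaced
    block <- lat
    if (length(ce) > 0) {
      gaps <- if (randomize) {
        sort(sample(length(block) + 1, length(ce), replace = TRUE))
      } else {
        round(seq(1, length(block) + 1, length.out = length(ce)))
      }
      for (i in rev(seq_along(ce))) {
        block <- append(block, ce[i], after = gaps[i] - 1)
      }
    }
    block
  }

  side_of <- stats::setNames(roster$side, roster$name)
  if (mode == "randomized") set.seed(seed)
  out <- character(0)
  prev_side <- NA_character_
  for (b in seq_len(repetitions)) {
    blk <- make_block(mode == "randomized", prev_side)
    ## guard the block seam: no two same-side laterals in a row
    if (!is.na(prev_side) && length(blk) > 0 &&
        side_of[blk[1]] %in% c("left", "right") && side_of[blk[1]] == prev_side) {
      blk <- rev(blk) # reversing an alternating block flips its first side
    }
    out <- c(out, blk)
    lat_sides <- side_of[blk][side_of[blk] != "center"]
    if (length(lat_sides) > 0) prev_side <- lat_sides[length(lat_sides)]
  }
  unname(out)
}

#' Construct a pointing session
#'
#' @param participant_id participant label.
#' @param day 1 or 2.
#' @param trials data.frame with columns `index`, `day`, `condition`,
#'   `target`, `repetition`, `e`, `n`, `u`, and optionally `flags`
#'   (";"-separated quality flags, "" when none).
#' @param roster a `target_roster`.
#' @param layout a [room_layout()].
#' @param sex,birthdate optional participant metadata.
#' @param handedness,pointing_hand "left" or "right".
#' @param rotation_side side of the real rotation, "left" or "right";
#'   the mental rotation is imagined to the opposite side.
#' @param extra passthrough list of unknown fields preserved on write.
#' @return an object of class `pointing_session`.
#' @export
pointing_session <- function(participant_id, day, trials, roster,
                             layout = room_layout(), sex = NA_character_,
                             birthdate = NA_character_, handedness = "right",
                             pointing_hand = "right", rotation_side = "right",
                             extra = list()) {
  stopifnot(day %in% c(1, 2),
            handedness %in% c("left", "right"),
            pointing_hand %in% c("left", "right"),
            rotation_side %in% c("left", "right"))
  if (is.null(trials$flags)) trials$flags <- ""
  s <- structure(
    list(
      participant_id = as.character(participant_id),
      sex = sex, birthdate = birthdate,
      handedness = handedness, pointing_hand = pointing_hand,
      rotation_side = rotation_side,
      day = as.integer(day),
      roster = roster, layout = layout,
      trials = trials, extra = extra
    ),
    class = "pointing_session"
  )
  s
}

#' @export
print.pointing_session <- function(x, ...) {
  cat(sprintf(
    "Pointing session: participant %s, day %d, %d trials (%s), %d targets\n",
    x$participant_id, x$day, nrow(x$trials),
    paste(unique(x$trials$condition), collapse = "/"), nrow(x$roster)
  ))
  invisible(x)
}

#' Validate a pointing session
#'
#' Checks the session invariants: unit-norm vectors (within tolerance),
#' components within [-1, 1], conditions among EO/EC/RR/MR, target names
#' resolving against the roster, strictly increasing presentation index,
#' day in {1, 2}.
#'
#' @param session a `pointing_session`.
#' @return character vector of violation messages (empty when clean).
#' @export
validate_session <- function(session) {
  v <- character(0)
  tr <- session$trials
  if (!all(tr$condition %in% CONDITIONS)) {
    v <- c(v, sprintf("unknown condition(s): %s",
                      paste(setdiff(unique(tr$condition), CONDITIONS),
                            collapse = ", ")))
  }
  bad_target <- setdiff(unique(tr$target), session$roster$name)
  if (length(bad_target) > 0) {
    v <- c(v, sprintf("target name(s) not in roster: %s",
                      paste(bad_target, collapse = ", ")))
  }
  nrm <- sqrt(tr$e^2 + tr$n^2 + tr$u^2)
  off <- which(abs(nrm - 1) > 1e-6)
  if (length(off) > 0) {
    v <- c(v, sprintf("%d trial(s) with non-unit pointing vector (max |norm-1| = %.3g)",
                      length(off), max(abs(nrm - 1))))
  }
  if (any(abs(tr$e) > 1 + 1e-9 | abs(tr$n) > 1 + 1e-9 | abs(tr$u) > 1 + 1e-9)) {
    v <- c(v, "vector component(s) outside [-1, 1]")
  }
  if (is.unsorted(tr$index, strictly = TRUE)) {
    v <- c(v, "presentation index not strictly increasing")
  }
  if (!all(tr$day %in% c(1L, 2L))) v <- c(v, "trial day outside {1, 2}")
  v
}

## serialise one session to the dialect's list form
session_to_list <- function(session) {
  ro <- session$roster
  roster_list <- lapply(seq_len(nrow(ro)), function(i) {
    list(
      name = ro$name[i],
      position_xyz_m = c(ro$x_m[i], ro$y_m[i], ro$z_m[i]),
      azimuth_deg = ro$azimuth_deg[i],
      elevation_deg = ro$elevation_deg[i],
      side = ro$side[i],
      analyse_azimuth = ro$analyse_azimuth[i]
    )
  })
  tr <- session$trials
  trials_list <- lapply(seq_len(nrow(tr)), function(i) {
    x <- list(
      index = tr$index[i],
      day = tr$day[i],
      condition = tr$condition[i],
      target = tr$target[i],
      repetition = tr$repetition[i],
      vector = c(tr$e[i], tr$n[i], tr$u[i])
    )
    if (!is.null(tr$flags) && nzchar(tr$flags[i])) x$flags <- tr$flags[i]
    x
  })
  c(
    list(
      format_version = 1L,
      participant = list(
        id = session$participant_id,
        sex = session$sex, birthdate = session$birthdate,
        handedness = session$handedness,
        pointing_hand = session$pointing_hand,
        rotation_side = session$rotation_side
      ),
      day = session$day,
      layout = unclass(session$layout),
      roster = roster_list,
      trials = trials_list
    ),
    session$extra
  )
}

#' Write a session to the pointing-session JSON dialect
#'
#' @param session a valid `pointing_session`.
#' @param path output file path.
#' @param order "collected" (presentation order, for research) or
#'   "by_target" (repetitions of each target grouped, targets alphabetical,
#'   for diagnostic reading).
#' @return the path, invisibly.
#' @export
write_session <- function(session, path, order = c("collected", "by_target")) {
  order <- match.arg(order)
  s <- session
  if (order == "by_target") {
    tr <- s$trials
    s$trials <- tr[order(tr$target, tr$repetition, tr$index), , drop = FALSE]
  } else {
    s$trials <- s$trials[order(s$trials$index), , drop = FALSE]
  }
  ## 17 significant digits: doubles survive the round trip bit-exactly
  json <- jsonlite::toJSON(session_to_list(s), auto_unbox = TRUE,
                           digits = I(17),
                           null = "null", na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a session from the pointing-session JSON dialect
#'
#' Accepts format_version 1 (flat trial list) and is forward-tolerant of
#' unknown top-level keys, which are preserved in the session's `extra`
#' slot. Pointing vectors are re-normalised; the pre-normalisation norm is
#' recorded in the trial column `raw_norm`. In strict mode any invariant
#' violation is an error; in lenient mode violations become quality flags
#' and grossly corrupt trials (norm outside [0.5, 1.5]) are dropped with a
#' `dropped_trials` attribute.
#'
#' @param path path to a session JSON file.
#' @param strict logical (default TRUE).
#' @return a `pointing_session`.
#' @export
read_session <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  fv <- raw$format_version
  if (is.null(fv) || !(fv %in% 1)) {
    stop("unsupported format_version: ", if (is.null(fv)) "missing" else fv)
  }
  known <- c("format_version", "participant", "day", "layout", "roster", "trials")
  extra <- raw[setdiff(names(raw), known)]

  lay <- raw$layout
  layout <- room_layout(
    width_m = lay$width_m, depth_m = lay$depth_m, height_m = lay$height_m,
    observer_xy = unlist(lay$observer_xy), eye_height_m = lay$eye_height_m,
    facing_heading_deg = lay$facing_heading_deg
  )
  ro <- raw$roster
  roster <- data.frame(
    name = vapply(ro, function(t) t$name, ""),
    x_m = vapply(ro, function(t) t$position_xyz_m[[1]], 0),
    y_m = vapply(ro, function(t) t$position_xyz_m[[2]], 0),
    z_m = vapply(ro, function(t) t$position_xyz_m[[3]], 0),
    azimuth_deg = vapply(ro, function(t) t$azimuth_deg, 0),
    elevation_deg = vapply(ro, function(t) t$elevation_deg, 0),
    side = vapply(ro, function(t) t$side, ""),
    analyse_azimuth = vapply(ro, function(t) isTRUE(t$analyse_azimuth), TRUE),
    stringsAsFactors = FALSE
  )
  class(roster) <- c("target_roster", "data.frame")

  tl <- raw$trials
  trials <- data.frame(
    index = vapply(tl, function(t) as.integer(t$index), 0L),
    day = vapply(tl, function(t) as.integer(t$day), 0L),
    condition = vapply(tl, function(t) t$condition, ""),
    target = vapply(tl, function(t) t$target, ""),
    repetition = vapply(tl, function(t) as.integer(t$repetition), 0L),
    e = vapply(tl, function(t) as.numeric(t$vector[[1]]), 0),
    n = vapply(tl, function(t) as.numeric(t$vector[[2]]), 0),
    u = vapply(tl, function(t) as.numeric(t$vector[[3]]), 0),
    flags = vapply(tl, function(t) if (is.null(t$flags)) "" else t$flags, ""),
    stringsAsFactors = FALSE
  )
  ## files may be stored in by-target order; indices recover collected order
  if (!anyDuplicated(trials$index)) {
    trials <- trials[order(trials$index), , drop = FALSE]
    rownames(trials) <- NULL
  }
  nrm <- sqrt(trials$e^2 + trials$n^2 + trials$u^2)
  trials$raw_norm <- nrm
  corrupt <- nrm < 0.5 | nrm > 1.5
  dropped <- 0L
  if (any(corrupt)) {
    if (strict) {
      stop(sprintf("corrupt record(s): %d trial(s) with vector norm outside [0.5, 1.5]",
                   sum(corrupt)))
    }
    trials <- trials[!corrupt, , drop = FALSE]
    nrm <- nrm[!corrupt]
    dropped <- sum(corrupt)
  }
  ## renormalise only where needed, so already-unit vectors survive a
  ## write/read round trip bit-exactly
  renorm <- abs(nrm - 1) > 1e-12
  trials$e[renorm] <- trials$e[renorm] / nrm[renorm]
  trials$n[renorm] <- trials$n[renorm] / nrm[renorm]
  trials$u[renorm] <- trials$u[renorm] / nrm[renorm]

  p <- raw$participant
  nul2na <- function(x) if (is.null(x)) NA_character_ else x
  session <- pointing_session(
    participant_id = p$id, day = raw$day, trials = trials, roster = roster,
    layout = layout, sex = nul2na(p$sex), birthdate = nul2na(p$birthdate),
    handedness = p$handedness, pointing_hand = p$pointing_hand,
    rotation_side = p$rotation_side, extra = extra
  )
  viol <- validate_session(session)
  if (length(viol) > 0) {
    if (strict) stop("invalid session: ", paste(viol, collapse = "; "))
    session$trials$flags <- vapply(session$trials$flags, function(f) {
      paste(c(if (nzchar(f)) f, "session_invariant_violation"), collapse = ";")
    }, "")
  }
  attr(session, "dropped_trials") <- dropped
  attr(session, "violations") <- viol
  session
}

#' Read a questionnaire score table
#'
#' One row per participant, columns `participant_id`, `sbsod`,
#' `perspective_taking`, `wayfinding`, `spatial_anxiety` (extra columns kept).
#'
#' @param path CSV file path.
#' @return a data.frame.
#' @export
read_scores <- function(path) {
  sc <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(sc)) {
    stop("scores file must have a participant_id column")
  }
  sc$participant_id <- as.character(sc$participant_id)
  sc
}
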