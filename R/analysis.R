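## End-to-end scoring pipeline: eyes-open baselines, per-trial errors with
## rotation-frame handling, grouped summaries, condition effects and
## questionnaire correlations.

## Trials of one or more sessions as one data.frame with angles attached.
pool_trials <- function(sessions) {
  if (inherits(sessions, "pointing_session")) sessions <- list(sessions)
  do.call(rbind, lapply(sessions, function(s) {
    tr <- s$trials
    ang <- vector_to_angles(as.matrix(tr[, c("e", "n", "u")]),
                            s$layout$facing_heading_deg)
    data.frame(
      participant_id = s$participant_id,
      pointing_hand = s$pointing_hand,
      rotation_side = s$rotation_side,
      day = tr$day, condition = tr$condition, target = tr$target,
      repetition = tr$repetition, index = tr$index,
      e = tr$e, n = tr$n, u = tr$u,
      azimuth_deg = ang$azimuth_deg, elevation_deg = ang$elevation_deg,
      flags = tr$flags,
      stringsAsFactors = FALSE
    )
  }))
}

roster_of <- function(sessions) {
  if (inherits(sessions, "pointing_session")) return(sessions$roster)
  sessions[[1]]$roster
}

has_flag <- function(flags, what) {
  vapply(strsplit(flags, ";", fixed = TRUE), function(f) what %in% f, TRUE)
}

#' Per-target circular summaries
#'
#' For every (participant, condition, target) cell: circular mean azimuth,
#' resultant length and circular SD, plus linear mean and SD of elevation.
#' Trials flagged `sensor_flip_suspect` are excluded when
#' `exclude_flagged = TRUE`.
#'
#' @param sessions a `pointing_session` or list of them.
#' @param exclude_flagged drop flagged trials from summaries (default TRUE).
#' @return a data.frame with one row per cell: `participant_id`, `condition`,
#'   `target`, `az_mean_deg`, `az_R`, `az_sd_deg`, `el_mean_deg`, `el_sd_deg`,
#'   `n_trials`, `n_flagged`.
#' @export
target_summaries <- function(sessions, exclude_flagged = TRUE) {
  tr <- pool_trials(sessions)
  key <- interaction(tr$participant_id, tr$condition, tr$target, drop = TRUE)
  out <- lapply(split(tr, key), function(g) {
    flagged <- has_flag(g$flags, "sensor_flip_suspect")
    use <- if (exclude_flagged) g[!flagged, , drop = FALSE] else g
    if (nrow(use) == 0) use <- g # never summarise an empty cell
    cm <- circ_mean(use$azimuth_deg)
    data.frame(
      participant_id = g$participant_id[1],
      condition = g$condition[1],
      target = g$target[1],
      az_mean_deg = cm$mean_deg,
      az_R = cm$resultant_length,
      az_sd_deg = cm$circ_sd_deg,
      el_mean_deg = mean(use$elevation_deg),
      el_sd_deg = stats::sd(use$elevation_deg),
      n_trials = nrow(use),
      n_flagged = sum(flagged),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pooled per-target dispersion estimates
#'
#' The per-cell circular SD reported by [target_summaries()] is biased
#' downward at the repetition counts typical of a single session (6-8 trials
#' per cell). For estimating the underlying trial-to-trial dispersion this
#' function instead pools, per target, every participant's deviations from
#' their own cell mean and divides the summed squares by the residual
#' degrees of freedom (trials minus cells). Azimuth residuals are signed
#' circular distances; elevation residuals are linear. Targets whose roster
#' entry has `analyse_azimuth = FALSE` (straight up) are excluded from the
#' azimuth estimate.
#'
#' @param sessions a `pointing_session` or list of them.
#' @param condition condition to pool (default "EO").
#' @param exclude_flagged drop sensor-flip suspects (default TRUE).
#' @return a data.frame `target`, `az_sd_deg` (NA where azimuth is not
#'   analysable), `el_sd_deg`, `n_trials`, `n_cells`.
#' @export
pooled_target_sd <- function(sessions, condition = "EO",
                             exclude_flagged = TRUE) {
  tr <- pool_trials(sessions)
  tr <- tr[tr$condition == condition, , drop = FALSE]
  if (exclude_flagged) {
    tr <- tr[!has_flag(tr$flags, "sensor_flip_suspect"), , drop = FALSE]
  }
  if (nrow(tr) == 0) stop("no trials in condition ", condition)
  roster <- roster_of(sessions)
  az_ok <- stats::setNames(roster$analyse_azimuth, roster$name)
  out <- lapply(split(tr, tr$target), function(g) {
    cells <- split(g, g$participant_id)
    cells <- Filter(function(h) nrow(h) >= 2, cells)
    if (length(cells) == 0) {
      return(data.frame(target = g$target[1], az_sd_deg = NA_real_,
                        el_sd_deg = NA_real_, n_trials = 0L, n_cells = 0L))
    }
    res_az <- unlist(lapply(cells, function(h)
      circ_distance(h$azimuth_deg, circ_mean(h$azimuth_deg)$mean_deg)))
    res_el <- unlist(lapply(cells, function(h)
      h$elevation_deg - mean(h$elevation_deg)))
    df <- length(res_el) - length(cells)
    data.frame(
      target = g$target[1],
      az_sd_deg = if (isTRUE(az_ok[g$target[1]]))
        sqrt(sum(res_az^2) / df) else NA_real_,
      el_sd_deg = sqrt(sum(res_el^2) / df),
      n_trials = length(res_el), n_cells = length(cells),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Eyes-open baseline directions
#'
#' Pools the EO trials of one participant (across days unless `day` given)
#' and returns the per-target baseline direction: circular mean azimuth and
#' linear mean elevation. Flagged trials are excluded. Targets with fewer
#' than `min_trials` EO trials are listed in the `coverage` attribute rather
#' than raising.
#'
#' @param sessions sessions of one participant.
#' @param day optional day filter.
#' @param min_trials minimum EO trials per target (default 2).
#' @param exclude_flagged drop flagged trials (default TRUE).
#' @return a data.frame `target`, `azimuth_deg`, `elevation_deg`, `n`, with
#'   attribute `coverage` naming under-covered targets.
#' @export
compute_baseline <- function(sessions, day = NULL, min_trials = 2,
                             exclude_flagged = TRUE) {
  tr <- pool_trials(sessions)
  tr <- tr[tr$condition == "EO", , drop = FALSE]
  if (!is.null(day)) tr <- tr[tr$day %in% day, , drop = FALSE]
  if (exclude_flagged) {
    tr <- tr[!has_flag(tr$flags, "sensor_flip_suspect"), , drop = FALSE]
  }
  if (nrow(tr) == 0) stop("no EO trials: baseline unavailable")
  out <- lapply(split(tr, tr$target), function(g) {
    data.frame(
      target = g$target[1],
      azimuth_deg = circ_mean(g$azimuth_deg)$mean_deg,
      elevation_deg = mean(g$elevation_deg),
      n = nrow(g),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "coverage") <- out$target[out$n < min_trials]
  out
}

#' Expected pointing direction for a condition
#'
#' EO, EC and RR leave the world-frame target direction unchanged (a real
#' body rotation does not move the target, and the device measures in the
#' world frame). For MR with `apply_mr_transform = TRUE` the azimuth is
#' shifted by -90 degrees for an imagined rightward rotation and +90 for a
#' leftward one, so that errors measure spatial-updating accuracy; with the
#' transform off the baseline is used unchanged (paper-literal scoring, in
#' which the imagined rotation itself appears in the error). Elevation is
#' never transformed.
#'
#' @param azimuth_deg,elevation_deg baseline direction (vectors ok).
#' @param condition one of EO/EC/RR/MR (scalar).
#' @param mr_side side of the imagined rotation ("left"/"right"); for a
#'   session this is the side opposite `rotation_side`.
#' @param apply_mr_transform logical (default TRUE).
#' @return data.frame `azimuth_deg`, `elevation_deg`.
#' @export
expected_direction <- function(azimuth_deg, elevation_deg, condition,
                               mr_side = "right", apply_mr_transform = TRUE) {
  stopifnot(condition %in% CONDITIONS, mr_side %in% c("left", "right"))
  az <- azimuth_deg
  if (condition == "MR" && apply_mr_transform) {
    az <- wrap_angle(az + if (mr_side == "right") -90 else 90)
  }
  data.frame(azimuth_deg = az, elevation_deg = elevation_deg)
}

opposite_side <- function(side) ifelse(side == "left", "right", "left")

#' Per-trial pointing errors against the eyes-open baseline
#'
#' For every non-baseline-defining trial: signed azimuth error (circular
#' distance from the expected azimuth; positive = right of expected), signed
#' elevation error (positive = above expected), and the total great-circle
#' angle between the pointed and expected directions. The straight-up
#' target (roster `analyse_azimuth = FALSE`) is scored in elevation only.
#' Sensor-flip suspects are detected against the baseline and flagged;
#' `exclude_flagged` drops them from the returned records.
#'
#' @param sessions sessions of one participant (or a cohort list; baselines
#'   are computed per participant).
#' @param baselines optional precomputed baseline table (one participant
#'   only); default computes EO baselines per participant from `sessions`.
#' @param apply_mr_transform see [expected_direction()] (default TRUE).
#' @param exclude_flagged drop sensor-flip suspects (default TRUE).
#' @param conditions which conditions to score (default EC/RR/MR and EO).
#' @return a data.frame of error records: `participant_id`, `condition`,
#'   `target`, `repetition`, `day`, `azimuth_error_deg`,
#'   `elevation_error_deg`, `total_angle_error_deg`, `sensor_flip_suspect`.
#' @export
compute_errors <- function(sessions, baselines = NULL,
                           apply_mr_transform = TRUE, exclude_flagged = TRUE,
                           conditions = CONDITIONS) {
  tr <- pool_trials(sessions)
  roster <- roster_of(sessions)
  az_ok <- stats::setNames(roster$analyse_azimuth, roster$name)
  out <- lapply(split(tr, tr$participant_id), function(g) {
    bl <- if (is.null(baselines)) {
      compute_baseline(sessions_of(sessions, g$participant_id[1]))
    } else {
      baselines
    }
    g <- g[g$condition %in% conditions, , drop = FALSE]
    known <- g$target %in% bl$target
    if (any(!known)) {
      message(sum(!known), " trial(s) skipped: target absent from baseline")
      g <- g[known, , drop = FALSE]
    }
    i <- match(g$target, bl$target)
    mr_side <- opposite_side(g$rotation_side[1])
    exp_az <- bl$azimuth_deg[i]
    is_mr <- g$condition == "MR"
    if (apply_mr_transform && any(is_mr)) {
      exp_az[is_mr] <- wrap_angle(
        exp_az[is_mr] + if (mr_side == "right") -90 else 90
      )
    }
    exp_el <- bl$elevation_deg[i]
    az_err <- circ_distance(g$azimuth_deg, exp_az)
    el_err <- g$elevation_deg - exp_el
    tot <- great_circle_angle(g$azimuth_deg, g$elevation_deg, exp_az, exp_el)
    az_analysable <- az_ok[g$target]
    az_err[!az_analysable] <- NA_real_
    flip <- detect_sensor_flips(ifelse(is.na(az_err), 0, az_err),
                                g$elevation_deg)
    flip <- flip | has_flag(g$flags, "sensor_flip_suspect")
    data.frame(
      participant_id = g$participant_id,
      condition = g$condition, target = g$target,
      repetition = g$repetition, day = g$day,
      azimuth_error_deg = az_err,
      elevation_error_deg = el_err,
      total_angle_error_deg = ifelse(az_analysable, tot, abs(el_err)),
      sensor_flip_suspect = flip,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (exclude_flagged) out <- out[!out$sensor_flip_suspect, , drop = FALSE]
  out
}

## subset a session list to one participant
sessions_of <- function(sessions, id) {
  if (inherits(sessions, "pointing_session")) sessions <- list(sessions)
  Filter(function(s) s$participant_id == id, sessions)
}

#' Grouped error summaries
#'
#' Summarises error records by the given grouping keys: mean absolute error,
#' mean signed error, circular SD of the signed azimuth errors, linear SD of
#' elevation errors, and counts. Groups containing eccentric targets
#' (|true azimuth| >= 75 degrees) contralateral to the pointing hand carry a
#' laterality annotation when grouping by target.
#'
#' @param errors error records from [compute_errors()].
#' @param by character vector of grouping columns (default
#'   `c("condition")`).
#' @param roster optional roster for the laterality annotation.
#' @param pointing_hand pointing hand for the annotation (default "right").
#' @return a data.frame of grouped summaries.
#' @export
summarize_errors <- function(errors, by = "condition", roster = NULL,
                             pointing_hand = "right") {
  stopifnot(nrow(errors) > 0, all(by %in% names(errors)))
  key <- interaction(errors[, by, drop = FALSE], drop = TRUE, sep = "\r")
  out <- lapply(split(errors, key), function(g) {
    az <- g$azimuth_error_deg[!is.na(g$azimuth_error_deg)]
    res <- g[1, by, drop = FALSE]
    res$mean_abs_az_error_deg <- if (length(az)) mean(abs(az)) else NA_real_
    res$mean_az_error_deg <- if (length(az)) circ_mean(az)$mean_deg else NA_real_
    res$az_sd_deg <- if (length(az) > 1) circ_mean(az)$circ_sd_deg else NA_real_
    res$mean_abs_el_error_deg <- mean(abs(g$elevation_error_deg))
    res$el_sd_deg <- stats::sd(g$elevation_error_deg)
    res$mean_total_error_deg <- mean(g$total_angle_error_deg)
    res$n <- nrow(g)
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if ("target" %in% by && !is.null(roster)) {
    i <- match(out$target, roster$name)
    out$contralateral_eccentric <- abs(roster$azimuth_deg[i]) >= 75 &
      roster$side[i] == opposite_side(pointing_hand)
  }
  out
}

## Repeated-measures one-way F from a subjects x conditions matrix:
## F = MS_condition / MS_error after removing the subject (block) effect.
rm_anova_F <- function(m) {
  n <- nrow(m); c <- ncol(m)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- c * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- c - 1; df2 <- (c - 1) * (n - 1)
  (ss_cond / df1) / (ss_err / df2)
}

#' Repeated-measures condition effect
#'
#' One-way repeated-measures ANOVA (participant as blocking factor) on a
#' per-participant-by-condition table of scores, with a within-participant
#' label-permutation test: condition labels are permuted independently
#' within each participant and the F statistic recomputed; the permutation
#' p-value is (1 + #\{F* >= F\}) / (n_perm + 1).
#'
#' @param tab data.frame with columns `participant_id`, `condition`, `value`;
#'   complete cells required.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation draw.
#' @return a list of class `condition_effect`: `F`, `df_between`,
#'   `df_within`, `p_parametric`, `p_permutation`, `condition_means`, `n`.
#' @export
condition_effect <- function(tab, n_perm = 999, seed = 1) {
  stopifnot(all(c("participant_id", "condition", "value") %in% names(tab)))
  m <- stats::xtabs(value ~ participant_id + condition, data = tab)
  counts <- stats::xtabs(~ participant_id + condition, data = tab)
  if (any(counts != 1)) {
    stop("incomplete cells: every participant needs exactly one value per ",
         "condition (impute or exclude first)")
  }
  m <- as.matrix(unclass(m))
  n <- nrow(m); c <- ncol(m)
  if (c < 2 || n < 3) stop("need >= 2 conditions and >= 3 participants")
  Fobs <- rm_anova_F(m)
  df1 <- c - 1; df2 <- (c - 1) * (n - 1)
  p_par <- stats::pf(Fobs, df1, df2, lower.tail = FALSE)
  ## seed the permutation draw without disturbing the caller's RNG stream
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    mp <- t(apply(m, 1, sample))
    if (rm_anova_F(mp) >= Fobs) count <- count + 1L
  }
  structure(
    list(
      F = Fobs, df_between = df1, df_within = df2,
      p_parametric = p_par,
      p_permutation = (1 + count) / (n_perm + 1),
      condition_means = colMeans(m), n = n
    ),
    class = "condition_effect"
  )
}

#' @export
print.condition_effect <- function(x, ...) {
  cat(sprintf(
    "rm-ANOVA: F(%d, %d) = %.3f, parametric p = %.4g, permutation p = %.4g\n",
    x$df_between, x$df_within, x$F, x$p_parametric, x$p_permutation
  ))
  cat("condition means:",
      paste(sprintf("%s = %.2f", names(x$condition_means), x$condition_means),
            collapse = ", "), "\n")
  invisible(x)
}

#' Correlate pointing metrics with self-report questionnaire scores
#'
#' Pearson correlations between per-participant pointing metrics and
#' questionnaire scores for the requested pairs, with two-sided p-values and
#' Benjamini-Hochberg adjusted p across the pairs. Participants missing
#' either value are dropped pairwise.
#'
#' @param metrics data.frame with `participant_id` and metric columns.
#' @param scores data.frame with `participant_id` and score columns
#'   (see [read_scores()]).
#' @param pairs list of c(metric_column, score_column) pairs.
#' @return data.frame `metric`, `score`, `r`, `p`, `p_adj`, `n`,
#'   `undefined` (TRUE when a column had zero variance).
#' @export
correlate_selfreport <- function(metrics, scores, pairs) {
  merged <- merge(metrics, scores, by = "participant_id")
  rows <- lapply(pairs, function(pr) {
    x <- merged[[pr[1]]]; y <- merged[[pr[2]]]
    keep <- stats::complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n < 4) stop("need >= 4 matched participants for pair ",
                    pr[1], " x ", pr[2])
    undef <- stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12
    if (undef) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(x, y)
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(metric = pr[1], score = pr[2], r = r, p = p, n = n,
               undefined = undef, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[, c("metric", "score", "r", "p", "p_adj", "n", "undefined")]
}
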