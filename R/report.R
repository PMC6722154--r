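## Report bundle: tables, figures and a machine-readable summary for an
## analysed cohort.

#' Analyse a cohort of sessions end to end
#'
#' Convenience wrapper: per-participant EO baselines, error records, target
#' summaries, per-condition summaries, the repeated-measures condition
#' effect on mean absolute azimuth error, and (when scores are supplied)
#' questionnaire correlations.
#'
#' @param sessions list of `pointing_session` objects (a cohort).
#' @param scores optional questionnaire score table (see [read_scores()]).
#' @param apply_mr_transform see [expected_direction()].
#' @param exclude_flagged drop sensor-flip suspects (default TRUE).
#' @param n_perm permutations for the condition effect (default 999).
#' @param seed seed for the permutation draw.
#' @return a list of class `cohort_analysis` with elements `errors`,
#'   `target_summaries`, `condition_summary`, `condition_effect`,
#'   `correlations` (NULL without scores), `options`.
#' @export
analyze_cohort <- function(sessions, scores = NULL, apply_mr_transform = TRUE,
                           exclude_flagged = TRUE, n_perm = 999, seed = 1) {
  if (inherits(sessions, "pointing_session")) sessions <- list(sessions)
  errors <- compute_errors(sessions, apply_mr_transform = apply_mr_transform,
                           exclude_flagged = exclude_flagged)
  tsum <- target_summaries(sessions, exclude_flagged = exclude_flagged)
  csum <- summarize_errors(errors, by = "condition")
  test_cond <- intersect(c("EC", "RR", "MR"), unique(errors$condition))
  eff <- NULL
  per_part <- summarize_errors(errors, by = c("participant_id", "condition"))
  if (length(test_cond) >= 2 &&
      length(unique(per_part$participant_id)) >= 3) {
    tab <- per_part[per_part$condition %in% test_cond,
                    c("participant_id", "condition", "mean_abs_az_error_deg")]
    names(tab)[3] <- "value"
    complete <- !anyNA(stats::xtabs(value ~ participant_id + condition,
                                    data = tab) == 0)
    eff <- tryCatch(condition_effect(tab, n_perm = n_perm, seed = seed),
                    error = function(e) NULL)
  }
  cors <- NULL
  if (!is.null(scores)) {
    metrics <- stats::reshape(
      per_part[, c("participant_id", "condition", "mean_abs_az_error_deg")],
      idvar = "participant_id", timevar = "condition", direction = "wide"
    )
    names(metrics) <- sub("mean_abs_az_error_deg.", "az_err_", names(metrics),
                          fixed = TRUE)
    pairs <- list()
    for (cond in intersect(c("EC", "RR", "MR"),
                           unique(per_part$condition))) {
      for (sc in intersect(c("sbsod", "perspective_taking", "wayfinding",
                             "spatial_anxiety"), names(scores))) {
        pairs[[length(pairs) + 1]] <- c(paste0("az_err_", cond), sc)
      }
    }
    if (length(pairs) > 0) {
      cors <- tryCatch(correlate_selfreport(metrics, scores, pairs),
                       error = function(e) NULL)
    }
  }
  structure(
    list(
      errors = errors, target_summaries = tsum, condition_summary = csum,
      per_participant = per_part, condition_effect = eff,
      correlations = cors,
      options = list(apply_mr_transform = apply_mr_transform,
                     exclude_flagged = exclude_flagged)
    ),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("Cohort analysis:",
      length(unique(x$errors$participant_id)), "participants,",
      nrow(x$errors), "scored trials\n")
  print(x$condition_summary[, c("condition", "mean_abs_az_error_deg",
                                "az_sd_deg", "el_sd_deg", "n")])
  if (!is.null(x$condition_effect)) print(x$condition_effect)
  invisible(x)
}

#' Write a report bundle
#'
#' Emits, under `out_dir`: per-participant and cohort CSV tables, a
#' machine-readable JSON summary, polar-histogram figures of pointing angles
#' per requested target and plane, a per-target SD figure, and a manifest
#' listing every artifact (and anything skipped).
#'
#' @param analysis a `cohort_analysis` from [analyze_cohort()].
#' @param sessions the sessions the analysis was computed from (for the
#'   polar histograms).
#' @param out_dir output directory (created if needed).
#' @param figure_targets target names to draw polar histograms for
#'   (default: all targets present).
#' @param figures draw figures at all (default TRUE).
#' @return the manifest list, invisibly.
#' @export
write_report <- function(analysis, sessions, out_dir,
                         figure_targets = NULL, figures = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fig_dir <- file.path(out_dir, "figures")
  artifacts <- list()
  skipped <- character(0)

  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    artifacts[[length(artifacts) + 1]] <<- list(path = name, kind = "table")
  }
  wr(analysis$errors, "error_records.csv")
  wr(analysis$target_summaries, "target_summaries.csv")
  wr(analysis$condition_summary, "condition_summary.csv")
  wr(analysis$per_participant, "per_participant_summary.csv")
  if (!is.null(analysis$correlations)) {
    wr(analysis$correlations, "selfreport_correlations.csv")
  } else {
    skipped <- c(skipped, "selfreport_correlations (no scores supplied)")
  }

  summary_json <- list(
    n_participants = length(unique(analysis$errors$participant_id)),
    n_scored_trials = nrow(analysis$errors),
    options = analysis$options,
    condition_summary = analysis$condition_summary,
    condition_effect = if (is.null(analysis$condition_effect)) NULL else
      analysis$condition_effect[c("F", "df_between", "df_within",
                                  "p_parametric", "p_permutation")],
    skipped_conditions = setdiff(CONDITIONS,
                                 unique(analysis$errors$condition))
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  artifacts[[length(artifacts) + 1]] <- list(path = "summary.json",
                                             kind = "summary")

  if (figures) {
    dir.create(fig_dir, showWarnings = FALSE)
    tr <- pool_trials(sessions)
    if (is.null(figure_targets)) figure_targets <- unique(tr$target)
    for (tg in figure_targets) {
      g <- tr[tr$target == tg & tr$condition == "EO", , drop = FALSE]
      if (nrow(g) == 0) {
        skipped <- c(skipped, paste0("polar histogram ", tg, " (no EO trials)"))
        next
      }
      for (plane in c("azimuth", "elevation")) {
        vals <- if (plane == "azimuth") g$azimuth_deg else g$elevation_deg
        p <- ggplot2::ggplot(data.frame(angle = vals),
                             ggplot2::aes(x = angle)) +
          ggplot2::geom_histogram(binwidth = 5, boundary = 0,
                                  fill = "steelblue", colour = "grey20") +
          ggplot2::coord_polar(start = pi / 2, direction = -1) +
          ggplot2::scale_x_continuous(limits = c(-180, 180),
                                      breaks = seq(-180, 135, 45)) +
          ggplot2::labs(title = paste0(tg, " (", plane, ", EO)"),
                        x = NULL, y = "trials") +
          ggplot2::theme_minimal()
        fn <- paste0("polar_", plane, "_", gsub("[^A-Za-z0-9_]", "_", tg),
                     ".png")
        grDevices::png(file.path(fig_dir, fn), width = 640, height = 640)
        print(p)
        grDevices::dev.off()
        artifacts[[length(artifacts) + 1]] <- list(
          path = file.path("figures", fn), kind = "figure",
          target = tg, plane = plane
        )
      }
    }
    ## per-target SD figure (EO), azimuth and elevation
    ts <- analysis$target_summaries
    ts <- ts[ts$condition == "EO", , drop = FALSE]
    if (nrow(ts) > 0) {
      agg_az <- stats::aggregate(az_sd_deg ~ target, ts, mean)
      agg_el <- stats::aggregate(el_sd_deg ~ target, ts, mean)
      dd <- rbind(
        data.frame(target = agg_az$target, sd = agg_az$az_sd_deg,
                   plane = "azimuth"),
        data.frame(target = agg_el$target, sd = agg_el$el_sd_deg,
                   plane = "elevation")
      )
      p <- ggplot2::ggplot(dd, ggplot2::aes(x = target, y = sd)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::facet_wrap(~plane, ncol = 1, scales = "free_y") +
        ggplot2::labs(y = "SD of pointing (deg)", x = NULL) +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
      grDevices::png(file.path(fig_dir, "per_target_sd.png"),
                     width = 900, height = 600)
      print(p)
      grDevices::dev.off()
      artifacts[[length(artifacts) + 1]] <- list(
        path = "figures/per_target_sd.png", kind = "figure"
      )
    }
  } else {
    skipped <- c(skipped, "figures (disabled)")
  }

  manifest <- list(artifacts = artifacts, skipped = skipped,
                   generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
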