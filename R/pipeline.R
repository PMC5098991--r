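#' Experiment configuration
#'
#' Bundles every tunable of the five-condition study. Defaults are the
#' protocol values: 10 naive subjects per condition, 20-minute trials at
#' 30 fps split into 10 min habituation (excluded from analysis) and 10 min
#' observation, replica waypoints every 2.5 s, planar-control depth 7.5 cm,
#' 12 cm shoaling radius, 10 transfer-entropy bins with 175-sample minimum
#' segments, and left/right stimulus placement balanced across trials.
#'
#' @param geometry A [tank_geometry()] (the `stimulus_side` field is set
#'   per trial).
#' @param conditions Condition labels to run, subset of
#'   `c("RM", "RM2D", "R", "M", "Control")`.
#' @param trials_per_condition Number of subjects per condition.
#' @param habituation_s,observation_s Durations (s).
#' @param fps Frame rate (frames/s).
#' @param locomotion A [locomotion_params()] for the focal fish (and the
#'   program's donor fish).
#' @param waypoint_interval_s Replica waypoint spacing (s).
#' @param rm2d_depth_cm Fixed depth of the planar condition (cm).
#' @param shoaling_radius_cm Shoaling radius (cm).
#' @param te_bins,te_min_len Transfer-entropy discretization bins and
#'   minimum segment length (samples).
#' @param seed Master integer seed.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(geometry = tank_geometry(),
                              conditions = c("RM", "RM2D", "R", "M", "Control"),
                              trials_per_condition = 10,
                              habituation_s = 600, observation_s = 600,
                              fps = 30,
                              locomotion = locomotion_params(fps = fps),
                              waypoint_interval_s = 2.5,
                              rm2d_depth_cm = 7.5,
                              shoaling_radius_cm = 12,
                              te_bins = 10, te_min_len = 175,
                              seed = 1) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  stopifnot(habituation_s >= 0, observation_s > 0, fps > 0,
            trials_per_condition >= 1)
  structure(list(geometry = geometry, conditions = conditions,
                 trials_per_condition = trials_per_condition,
                 habituation_s = habituation_s, observation_s = observation_s,
                 fps = fps, locomotion = locomotion,
                 waypoint_interval_s = waypoint_interval_s,
                 rm2d_depth_cm = rm2d_depth_cm,
                 shoaling_radius_cm = shoaling_radius_cm,
                 te_bins = te_bins, te_min_len = te_min_len, seed = seed),
            class = "experiment_config")
}

# Mirror a trajectory across the tank midline (left <-> right placement).
mirror_x <- function(traj, geometry) {
  traj$x_cm <- geometry$length_cm - traj$x_cm
  traj
}

#' Generate the shared replica program of a study
#'
#' The replica trajectory is derived from one donor fish swimming in the
#' left lateral compartment for the full trial duration, downsampled to
#' 2.5 s waypoints; the same program drives the replica in every trial
#' (mirrored when the platform sits on the right).
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed for the donor simulation.
#' @return A `replica_program`.
#' @export
make_study_program <- function(config, seed = config$seed) {
  g <- config$geometry
  g$stimulus_side <- "left"
  donor <- simulate_fish(config$locomotion,
                         config$habituation_s + config$observation_s,
                         g, compartment = "left", seed = seed)
  make_replica_program(donor, config$waypoint_interval_s)
}

#' Run a single trial of one condition
#'
#' Simulates the focal fish in the central compartment, attaches the
#' stimulus dictated by the condition (RM: the 3D replica program; RM2D:
#' the program blocked at 7.5 cm depth; R: static replica at the lateral
#' compartment centre, 7.5 cm deep; M: the RM program flagged transparent;
#' Control: no physical stimulus, with the RM program attached as a
#' virtual stimulus for shoaling and transfer entropy), drops the
#' habituation window, and computes the behavioral summary and per-segment
#' transfer entropies.
#'
#' @param config An [experiment_config()].
#' @param condition One of `"RM"`, `"RM2D"`, `"R"`, `"M"`, `"Control"`.
#' @param program The shared `replica_program` from [make_study_program()].
#' @param trial_seed Integer seed for this subject.
#' @param stimulus_side `"left"` or `"right"`.
#' @return List: `condition`, `stimulus_side`, `fish`, `stimulus` (NULL for
#'   Control), `virtual_stimulus`, `summary` (one row), `te` (segment
#'   table).
#' @export
run_trial <- function(config, condition, program, trial_seed,
                      stimulus_side = "left") {
  if (!condition %in% c("RM", "RM2D", "R", "M", "Control"))
    stop("invalid condition label: ", condition)
  g <- config$geometry
  g$stimulus_side <- stimulus_side
  total_s <- config$habituation_s + config$observation_s
  fish <- simulate_fish(config$locomotion, total_s, g,
                        compartment = "central", seed = trial_seed)
  prog_traj <- program$trajectory
  if (stimulus_side == "right") prog_traj <- mirror_x(prog_traj, g)
  depth <- config$rm2d_depth_cm
  stim <- switch(condition,
    RM = prog_traj,
    M = prog_traj,
    RM2D = {
      p2 <- project_rm2d(program, depth, g$water_depth_cm)$trajectory
      if (stimulus_side == "right") mirror_x(p2, g) else p2
    },
    R = {
      xb <- compartment_bounds(g, stimulus_compartment(g))
      n <- nrow(prog_traj)
      trajectory3d(rep(mean(xb), n), rep(g$width_cm / 2, n),
                   rep(depth, n), fps = config$fps, provenance = "simulated")
    },
    Control = NULL)
  virtual <- if (condition == "Control") prog_traj else stim
  n_obs <- min(nrow(fish), nrow(virtual))
  fish_obs <- drop_habituation(fish[seq_len(n_obs), ], config$habituation_s)
  virt_obs <- drop_habituation(virtual[seq_len(n_obs), ], config$habituation_s)
  summary <- summarize_trial(fish_obs, virt_obs, g,
                             radius_cm = config$shoaling_radius_cm)
  # transfer entropy only where the (virtual) stimulus moves: a static
  # replica has a constant width coordinate and carries no information
  te <- if (condition == "R") NULL else
    te_segments(fish_obs, virt_obs, g, bins = config$te_bins,
                min_len = config$te_min_len)
  if (!is.null(te) && nrow(te)) te <- cbind(condition = condition, te)
  list(condition = condition, stimulus_side = stimulus_side,
       transparent = condition == "M",
       fish = fish, stimulus = stim, virtual_stimulus = virtual,
       summary = cbind(condition = condition,
                       stimulus_side = stimulus_side, summary),
       te = te)
}

#' Run the full multi-condition study
#'
#' Executes every condition with `trials_per_condition` subjects (stimulus
#' side balanced: half left, half right), screens subjects per condition by
#' the IQR rule on the time spent in each lateral section (a flagged fish
#' is consistently discarded from all observables), then runs the
#' statistical battery: per-condition one-sample t-tests of both preference
#' indices against chance, one-way ANOVAs across conditions with Tukey HSD
#' when significant, and per-condition direction-by-segment ANOVA of the
#' normalized transfer entropy.
#'
#' @param config An [experiment_config()].
#' @return Object of class `study_report`: list with `trials` (per-subject
#'   summary rows with exclusion flags), `t_tests`, `anova`, `tukey`,
#'   `te_long`, `te_summary`, `te_anova`, `qc` and `provenance`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  program <- make_study_program(config, seed = config$seed)
  rows <- list(); te_rows <- list(); failures <- character(0)
  idx <- 0L
  for (cond in config$conditions) {
    for (k in seq_len(config$trials_per_condition)) {
      idx <- idx + 1L
      side <- if (k <= ceiling(config$trials_per_condition / 2)) "left" else "right"
      trial_seed <- (config$seed * 20011L + idx * 7919L) %% .Machine$integer.max
      res <- tryCatch(
        run_trial(config, cond, program, trial_seed, side),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("%s trial %d: %s", cond, k,
                                        conditionMessage(res)))
        next
      }
      row <- cbind(subject = k, res$summary,
                   session = if (k <= config$trials_per_condition / 2)
                     "morning" else "afternoon")
      rows[[length(rows) + 1L]] <- row
      if (!is.null(res$te) && nrow(res$te))
        te_rows[[length(te_rows) + 1L]] <- cbind(subject = k, res$te)
    }
  }
  trials <- do.call(rbind, rows)
  # IQR screening on the time spent in each lateral section, per condition
  trials$excluded <- FALSE
  for (cond in unique(trials$condition)) {
    sel <- trials$condition == cond
    if (sum(sel) >= 4) {
      flag <- iqr_outliers(trials$T_N[sel]) | iqr_outliers(trials$T_F[sel])
      trials$excluded[sel] <- flag
    }
  }
  kept <- trials[!trials$excluded, ]
  by_cond <- split(kept, kept$condition)
  t_tests <- do.call(rbind, lapply(names(by_cond), function(cond) {
    out <- lapply(c("PI_stimulus", "PI_bottom"), function(v) {
      vals <- by_cond[[cond]][[v]]
      vals <- vals[is.finite(vals)]
      if (length(vals) < 2 || stats::sd(vals) == 0) return(NULL)
      tt <- one_sample_t(vals, mu0 = 0.5, tail = "greater")
      data.frame(condition = cond, observable = v, n = length(vals),
                 t = tt$statistic, df = tt$df, p_one_tailed = tt$p,
                 p_two_tailed = tt$p_two_sided)
    })
    do.call(rbind, out)
  }))
  observables <- c("PI_stimulus", "PI_bottom", "T_mid_len", "T_mid_depth",
                   "mean_speed", "mean_accel", "shoaling_s")
  anova_tab <- NULL; tukey_tabs <- list()
  if (length(by_cond) >= 2) {
    for (v in observables) {
      gr <- lapply(by_cond, function(d) d[[v]][is.finite(d[[v]])])
      gr <- gr[lengths(gr) >= 2]
      if (length(gr) < 2) next
      a <- tryCatch(one_way_anova(gr), error = function(e) NULL)
      if (is.null(a)) next
      anova_tab <- rbind(anova_tab,
                         data.frame(observable = v, F = a$F, df1 = a$df1,
                                    df2 = a$df2, p = a$p))
      if (a$p < 0.05) tukey_tabs[[v]] <- tukey_hsd(gr)
    }
  } else {
    message("run_study: fewer than 2 conditions, between-condition ANOVA skipped")
  }
  te_all <- if (length(te_rows)) do.call(rbind, te_rows) else NULL
  te_long <- te_summary <- te_anova <- NULL
  if (!is.null(te_all) && nrow(te_all)) {
    # segment = ordinal of the near-section visit within a trial; the same
    # replica program drives every trial, so ordinals are comparable across
    # subjects and act as the within-group factor
    da <- direction_analysis(te_all)
    te_long <- da$long; te_summary <- da$summary
    te_anova <- do.call(rbind, lapply(unique(te_long$condition), function(cond) {
      sub <- te_long[te_long$condition == cond, ]
      if (length(unique(sub$segment)) < 2) return(NULL)
      out <- tryCatch(direction_segment_anova(sub), error = function(e) NULL)
      if (is.null(out)) return(NULL)
      cbind(condition = cond, out)
    }))
  }
  structure(list(
    trials = trials, t_tests = t_tests, anova = anova_tab,
    tukey = tukey_tabs, te_long = te_long, te_summary = te_summary,
    te_anova = te_anova,
    qc = list(failures = failures,
              n_excluded = sum(trials$excluded),
              sides = table(trials$condition, trials$stimulus_side)),
    provenance = list(seed = config$seed,
                      conditions = config$conditions,
                      trials_per_condition = config$trials_per_condition,
                      fps = config$fps,
                      habituation_s = config$habituation_s,
                      observation_s = config$observation_s)),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d trials (%d excluded by IQR screening)\n",
              nrow(x$trials), x$qc$n_excluded))
  if (!is.null(x$t_tests)) {
    cat("\nOne-sample t-tests vs chance (0.5):\n")
    print(x$t_tests, digits = 3)
  }
  if (!is.null(x$anova)) {
    cat("\nBetween-condition one-way ANOVA:\n")
    print(x$anova, digits = 3)
  }
  if (!is.null(x$te_anova)) {
    cat("\nDirection x segment ANOVA of normalized transfer entropy:\n")
    print(x$te_anova, digits = 3)
  }
  invisible(x)
}
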