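#' Names of the built-in experiment presets
#'
#' @return Character vector of valid preset names.
#' @export
preset_names <- function() {
  c("b1_homog", "b1_heterog", "b2_vibration", "b3_airflow",
    "b4_posFB", "b4_negFB", "b4_control",
    "f1_pure", "f1_mixed", "f2_open_loop", "f3_closed_loop",
    "p1_target")
}

#' Build an experiment preset
#'
#' Materialises one of the in-silico protocols into a model, a clock, a
#' default replicate count and the summary settings:
#'
#' * `b1_homog`: 12 bees, both sides fixed at 28 deg C, 20 min, N = 14;
#'   analysis window minutes 8-13.
#' * `b1_heterog`: 15 bees, 32 vs 36 deg C (pre-heated), 13 min, N = 12;
#'   same window.
#' * `b2_vibration`: 12 bees, both sides at ambient, vibration
#'   `psi = 0.1` on the left for `t >= 181` s, 6 min, N = 17.
#' * `b3_airflow`: 15 bees, 36 (right) vs 32 deg C, airflow `phi_R = 0.6`
#'   switched on at a per-replicate random time in minutes 13-15, 20 min,
#'   N = 12; analysis window last 5 min.
#' * `b4_posFB` / `b4_negFB` / `b4_control`: 12 bees, 20 min, N = 14,
#'   closed-loop positive/negative temperature feedback or fixed 28/28
#'   control; analysis window last 5 min.
#' * `f1_pure`: 6 fish, no robot, 30 min, N = 8.
#' * `f1_mixed`: 3 fish + 3 robots constantly CW, 30 min, N = 8.
#' * `f2_open_loop`: 5 fish + 1 robot switching with p = 0.014 per second,
#'   30 min, N = 24.
#' * `f3_closed_loop`: 5 fish + 1 majority-following robot, 30 min, N = 22.
#' * `p1_target`: single bean shoot, binary target-tracking light, 1200 min.
#'
#' @param name One of [preset_names()].
#' @param param_overrides Named list of parameter overrides passed to the
#'   model's parameter constructor.
#' @return A list of class `bh_preset` with elements `name`, `model`,
#'   `clock`, `n_replicates` and `summary_args`.
#' @export
experiment_preset <- function(name, param_overrides = list()) {
  if (!name %in% preset_names())
    stop("unknown preset '", name, "'; valid presets: ",
         paste(preset_names(), collapse = ", "))
  bp <- function(...) do.call(bee_params, utils::modifyList(list(...), param_overrides))
  fp <- function(...) do.call(fish_params, utils::modifyList(list(...), param_overrides))
  pp <- function(...) do.call(plant_params, utils::modifyList(list(...), param_overrides))
  ps <- switch(
    name,
    b1_homog = list(
      model = bee_model(bp(B_total = 12), "fixed", 28, 28),
      clock = sim_clock(1, 1200), n_replicates = 14,
      summary_args = list(window = c(480, 780))),
    b1_heterog = list(
      model = bee_model(bp(B_total = 15), "fixed", 36, 32),
      clock = sim_clock(1, 780), n_replicates = 12,
      summary_args = list(window = c(480, 780))),
    b2_vibration = list(
      model = bee_model(bp(B_total = 12), "fixed", 28, 28,
                        psi_L = piecewise_schedule(c(0, 181), c(0, 0.1))),
      clock = sim_clock(1, 360), n_replicates = 17,
      summary_args = list(window = c(181, 360), interval = 1)),
    b3_airflow = list(
      model = bee_model(bp(B_total = 15), "fixed", 36, 32,
                        phi_R_onset = c(780, 900), phi_R_value = 0.6),
      clock = sim_clock(1, 1200), n_replicates = 12,
      summary_args = list(window = c(900, 1200))),
    b4_posFB = list(
      model = bee_model(bp(B_total = 12), "positive"),
      clock = sim_clock(1, 1200), n_replicates = 14,
      summary_args = list(window = c(900, 1200))),
    b4_negFB = list(
      model = bee_model(bp(B_total = 12), "negative"),
      clock = sim_clock(1, 1200), n_replicates = 14,
      summary_args = list(window = c(900, 1200))),
    b4_control = list(
      model = bee_model(bp(B_total = 12), "fixed", 28, 28),
      clock = sim_clock(1, 1200), n_replicates = 14,
      summary_args = list(window = c(900, 1200))),
    f1_pure = list(
      model = fish_model(fp(F_total = 6, n_robots = 0), "none"),
      clock = sim_clock(1, 1800), n_replicates = 8,
      summary_args = list()),
    f1_mixed = list(
      model = fish_model(fp(F_total = 3, n_robots = 3), "constant", R_init = 1),
      clock = sim_clock(1, 1800), n_replicates = 8,
      summary_args = list()),
    f2_open_loop = list(
      model = fish_model(fp(F_total = 5, n_robots = 1), "random_switching",
                         p_switch = 0.014),
      clock = sim_clock(1, 1800), n_replicates = 24,
      summary_args = list()),
    f3_closed_loop = list(
      model = fish_model(fp(F_total = 5, n_robots = 1), "closed_loop"),
      clock = sim_clock(1, 1800), n_replicates = 22,
      summary_args = list()),
    p1_target = list(
      model = plant_model(pp(), "binary_target"),
      clock = sim_clock(1, 1200, units = "minutes"), n_replicates = 1,
      summary_args = list())
  )
  structure(c(list(name = name), ps), class = "bh_preset")
}

#' Run an experiment preset
#'
#' @param name One of [preset_names()].
#' @param n_replicates Replicate count; `NULL` uses the protocol's default.
#' @param seed Base seed for the ensemble.
#' @param param_overrides Named list of parameter overrides.
#' @param keep_trajectories Keep full trajectories in the result.
#' @return A `bh_ensemble` (see [run_ensemble()]).
#' @examples
#' \donttest{
#' res <- run_experiment("b1_homog", n_replicates = 2, seed = 1)
#' res$summary
#' }
#' @export
run_experiment <- function(name, n_replicates = NULL, seed = 1,
                           param_overrides = list(),
                           keep_trajectories = TRUE) {
  ps <- experiment_preset(name, param_overrides)
  n <- if (is.null(n_replicates)) ps$n_replicates else n_replicates
  run_ensemble(ps$model, ps$clock, n, seed, summary_args = ps$summary_args,
               keep_trajectories = keep_trajectories)
}

#' Sweep the individual : social : noise rate ratios
#'
#' Runs an experiment preset over a grid of rate parameters (the
#' alpha / beta / sigma knobs of the preset's organism) and returns one
#' summary row of medians per grid cell.
#'
#' @param name Preset name.
#' @param grid A data.frame whose columns are parameter names (e.g.
#'   `alpha_bees`, `beta_bees`, `sigma_bees`) and whose rows are grid cells.
#' @param n_replicates Replicates per cell.
#' @param seed Base seed (each cell uses the same base seed, so cells are
#'   paired).
#' @return A data.frame: the grid columns plus the medians of the preset's
#'   summary metrics.
#' @export
run_sweep <- function(name, grid, n_replicates = 5, seed = 1) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ov <- as.list(grid[i, , drop = FALSE])
    res <- run_experiment(name, n_replicates, seed, param_overrides = ov,
                          keep_trajectories = FALSE)
    num <- vapply(res$summary, is.numeric, logical(1))
    med <- lapply(res$summary[, num & !(names(res$summary) %in%
                                          c("replicate", "seed")), drop = FALSE],
                  stats::median, na.rm = TRUE)
    rows[[i]] <- cbind(grid[i, , drop = FALSE], as.data.frame(med))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
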