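#' Sample side counts at fixed intervals
#'
#' Emulates the counting protocol: bee counts on each side read off every
#' `interval` seconds inside an analysis window, endpoints inclusive (a 5-min
#' window at 30-s intervals yields 11 samples).
#'
#' @param traj A bee `bh_trajectory`.
#' @param interval Sampling interval (s).
#' @param window Length-2 analysis window `c(from, to)` (s); must lie within
#'   the trajectory.
#' @return A data.frame with columns `time`, `B_R`, `B_L`.
#' @export
sampled_counts <- function(traj, interval = 30, window = c(480, 780)) {
  stopifnot(inherits(traj, "bh_trajectory"), traj$model_type == "bee")
  d <- traj$data
  if (window[1] < min(d$time) || window[2] > max(d$time))
    stop("analysis window extends beyond the trajectory")
  at <- seq(window[1], window[2], by = interval)
  idx <- match(at, d$time)
  if (anyNA(idx)) stop("sampling instants do not align with the time grid")
  data.frame(time = at, B_R = d$B_R[idx], B_L = d$B_L[idx])
}

#' Mean majority fraction of a count series
#'
#' The majority side is evaluated per sampling instant
#' (`max(B_R, B_L) / B_total`), then averaged — matching the per-count
#' protocol. Set `per_instant = FALSE` to instead take the majority over the
#' whole window mean.
#'
#' @param counts A data.frame from [sampled_counts()].
#' @param B_total Group size.
#' @param per_instant Evaluate the majority per sample (default) or on the
#'   window means.
#' @return Fraction in `[0.5, 1]`.
#' @export
majority_fraction <- function(counts, B_total, per_instant = TRUE) {
  if (per_instant) mean(pmax(counts$B_R, counts$B_L)) / B_total
  else max(mean(counts$B_R), mean(counts$B_L)) / B_total
}

#' Direction time budgets of a fish trajectory
#'
#' Time-averaged fraction of fish swimming CW and time-averaged robot CW
#' direction, over the applied steps.
#'
#' @param traj A fish `bh_trajectory`.
#' @return Named vector `c(fish_cw_budget, robot_cw_budget)` (robot budget is
#'   `NA` for pure fish groups).
#' @export
direction_time_budget <- function(traj) {
  stopifnot(inherits(traj, "bh_trajectory"), traj$model_type == "fish")
  d <- traj$data
  n <- nrow(d) - 1L
  c(fish_cw_budget = mean(d$F_CW[seq_len(n)]) / traj$params$F_total,
    robot_cw_budget = mean(d$R_CW[seq_len(n)]))
}

#' Robot-group direction correlation
#'
#' Pearson correlation between per-replicate robot CW budget and fish CW
#' budget across an ensemble summary.
#'
#' @param summary An ensemble summary data.frame with columns
#'   `robot_cw_budget` and `fish_cw_budget`.
#' @return Pearson correlation coefficient.
#' @export
robot_group_correlation <- function(summary) {
  stopifnot(nrow(summary) >= 3)
  stats::cor(summary$robot_cw_budget, summary$fish_cw_budget)
}

#' Count light-direction switches
#'
#' Number of changes of the realised light ratio along a plant trajectory,
#' optionally restricted to a time window.
#'
#' @param traj A plant `bh_trajectory`.
#' @param window Optional `c(from, to)` window in minutes.
#' @return Integer switch count.
#' @export
light_switch_count <- function(traj, window = NULL) {
  stopifnot(inherits(traj, "bh_trajectory"), traj$model_type == "plant")
  d <- traj$data
  lam <- d$lambda[!is.na(d$lambda)]
  tt <- d$time[!is.na(d$lambda)]
  if (!is.null(window)) {
    keep <- tt >= window[1] & tt <= window[2]
    lam <- lam[keep]
  }
  if (length(lam) < 2) return(0L)
  sum(diff(lam) != 0)
}

#' Per-replicate summary metrics
#'
#' Pure function of a trajectory; recomputation is idempotent. Columns depend
#' on the model: bees report the sampled majority/minority fractions inside
#' the analysis window plus the final state; fish report the direction time
#' budgets; plants report the final inhomogeneity and the light switch count.
#'
#' @param traj A `bh_trajectory`.
#' @param ... Model-specific arguments: bees accept `window` (default: last
#'   300 s) and `interval` (default 30 s); plants accept `switch_window`.
#' @return A one-row data.frame.
#' @export
summarise_replicate <- function(traj, ...) {
  stopifnot(inherits(traj, "bh_trajectory"))
  args <- list(...)
  d <- traj$data
  switch(traj$model_type,
         bee = {
           t_end <- max(d$time)
           window <- if (is.null(args$window)) c(t_end - 300, t_end) else args$window
           interval <- if (is.null(args$interval)) 30 else args$interval
           cnt <- sampled_counts(traj, interval, window)
           mf <- majority_fraction(cnt, traj$params$B_total)
           data.frame(majority_fraction = mf, minority_fraction = 1 - mf,
                      final_B_R = d$B_R[nrow(d)], final_B_L = d$B_L[nrow(d)],
                      final_T_R = d$T_R[nrow(d)], final_T_L = d$T_L[nrow(d)])
         },
         fish = {
           b <- direction_time_budget(traj)
           data.frame(fish_cw_budget = b[["fish_cw_budget"]],
                      robot_cw_budget = b[["robot_cw_budget"]])
         },
         plant = {
           sw <- light_switch_count(traj, args$switch_window)
           nlast <- nrow(d)
           data.frame(final_upsilon = d$upsilon[nlast],
                      mean_upsilon = mean(d$upsilon, na.rm = TRUE),
                      switch_count = sw,
                      final_mass = d$P_R[nlast] + d$P_L[nlast])
         },
         stop("unknown model type: ", traj$model_type))
}
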