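#' Zebrafish ring-corridor model parameters
#'
#' Parameters of the direction-choice model for zebrafish shoaling in a ring
#' corridor, optionally with bio-mimetic robotic conspecifics. Fish swim
#' clockwise (CW) or counter-clockwise (CCW) and switch either spontaneously
#' (only while effectively alone) or socially, by imperfectly counting the
#' fish (and robots) in sight.
#'
#' The behavioural rates and noise scales are calibration defaults; the sight
#' ratio is the area-of-view to arena-area ratio (geometry gives roughly 1/3
#' near the outer wall and 1/7 near the inner wall, averaged to 1/5).
#'
#' @param alpha_fish Spontaneous switch probability per second.
#' @param beta_fish Social switching coefficient.
#' @param sigma_fish Fish perception-noise scale in `[0, 1]`.
#' @param gamma_fish Robot acceptance coefficient in `[0, 1]`: how often a
#'   robot is taken for a conspecific.
#' @param sigma_fishRobot Tracking-software observation-noise scale.
#' @param sight_ratio Sight-area to arena-area ratio, in `(0, 1]`.
#' @param F_total Number of live fish.
#' @param n_robots Number of robotic fish; their social contribution scales
#'   as `n_robots * gamma_fish`.
#' @return A validated list of class `fish_params`.
#' @export
fish_params <- function(alpha_fish = 0.02,
                        beta_fish = 0.06,
                        sigma_fish = 0.25,
                        gamma_fish = 0.8,
                        sigma_fishRobot = 0.05,
                        sight_ratio = 0.2,
                        F_total = 6,
                        n_robots = 0) {
  p <- list(alpha_fish = alpha_fish, beta_fish = beta_fish,
            sigma_fish = sigma_fish, gamma_fish = gamma_fish,
            sigma_fishRobot = sigma_fishRobot, sight_ratio = sight_ratio,
            F_total = F_total, n_robots = n_robots)
  p <- lapply(p, function(x) if (is.numeric(x)) unname(x) else x)
  for (nm in names(p))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop("fish_params: '", nm, "' must be a single non-negative number")
  for (nm in c("sigma_fish", "gamma_fish"))
    if (p[[nm]] > 1) stop("fish_params: '", nm, "' must lie in [0, 1]")
  if (p$sight_ratio <= 0 || p$sight_ratio > 1)
    stop("fish_params: 'sight_ratio' must lie in (0, 1]")
  structure(p, class = "fish_params")
}

#' Grouping and aloneness probabilities
#'
#' Mean-field probability that a fish has at least one (apparent) conspecific
#' in sight: `p_group = min(1, (F_total + n_robots * gamma_fish) *
#' sight_ratio)`; `p_alone = 1 - p_group`. With six agents and the default
#' sight ratio no fish is ever alone.
#'
#' @param params A [fish_params()] object.
#' @return Named vector `c(p_group, p_alone)`.
#' @examples
#' grouping_probability(fish_params(F_total = 2))  # p_group = 0.4
#' @export
grouping_probability <- function(params = fish_params()) {
  pg <- min(1, (params$F_total + params$n_robots * params$gamma_fish) *
              params$sight_ratio)
  c(p_group = pg, p_alone = 1 - pg)
}

#' Individual (spontaneous) direction-switch flows
#'
#' @param F_CW,F_CCW Fish per direction.
#' @param params A [fish_params()] object.
#' @return Named vector `c(into_CW, into_CCW)` in fish per second.
#' @export
fish_individual_flows <- function(F_CW, F_CCW, params = fish_params()) {
  pa <- grouping_probability(params)[["p_alone"]]
  c(into_CW = params$alpha_fish * pa * max(F_CCW, 0),
    into_CCW = params$alpha_fish * pa * max(F_CW, 0))
}

#' Erroneous mutual perception
#'
#' Perceived per-direction counts as seen by the CW- and CCW-swimming fish,
#' including the robot contribution `n_robots * gamma_fish * R` and the
#' misclassification error terms (each scaled by an independent `U(0, 1)`
#' draw; the `-1` excludes the focal fish itself). Perceived counts are
#' floored at zero: the raw forms can turn slightly negative only when the
#' observing class holds less than one (mean-field) fish.
#'
#' @param F_CW,F_CCW Fish per direction.
#' @param R_CW Robot CW time budget in `[0, 1]` (`R_CCW = 1 - R_CW`).
#' @param params A [fish_params()] object.
#' @param X Numeric vector of four `U(0, 1)` draws, in the order
#'   `X_CW^obsCW, X_CCW^obsCW, X_CW^obsCCW, X_CCW^obsCCW` (default all 0 =
#'   noise off).
#' @return Named list with the four perceived counts `obs_CW_by_CW`,
#'   `obs_CCW_by_CW`, `obs_CW_by_CCW`, `obs_CCW_by_CCW`.
#' @export
fish_perceive <- function(F_CW, F_CCW, R_CW = 0, params = fish_params(),
                          X = c(0, 0, 0, 0)) {
  g <- params$n_robots * params$gamma_fish
  rCW <- g * R_CW
  rCCW <- g * (1 - R_CW)
  s <- params$sigma_fish
  E_CCW_by_CW <- s * (F_CW + rCW - 1) * X[1]
  E_CW_by_CW <- s * (F_CCW + rCCW) * X[2]
  E_CCW_by_CCW <- s * (F_CW + rCW) * X[3]
  E_CW_by_CCW <- s * (F_CCW + rCCW - 1) * X[4]
  list(obs_CW_by_CW = max(0, F_CW + rCW + E_CW_by_CW - E_CCW_by_CW),
       obs_CCW_by_CW = max(0, F_CCW + rCCW - E_CW_by_CW + E_CCW_by_CW),
       obs_CW_by_CCW = max(0, F_CW + rCW + E_CW_by_CCW - E_CCW_by_CCW),
       obs_CCW_by_CCW = max(0, F_CCW + rCCW - E_CW_by_CCW + E_CCW_by_CCW))
}

#' Socially induced direction-switch flows
#'
#' Mass-action alignment: the switching of the CCW group towards CW grows
#' with the count they perceive as CW-aligned and shrinks with the count they
#' perceive as CCW-aligned (`+ 1` for the focal fish itself), with the robot
#' participating both as switchable mass (via `gamma`) and as perceived
#' conspecific.
#'
#' @inheritParams fish_perceive
#' @param obs A perception list from [fish_perceive()].
#' @return Named vector `c(into_CW, into_CCW)` in fish per second.
#' @export
fish_social_flows <- function(F_CW, F_CCW, R_CW = 0, obs,
                              params = fish_params()) {
  g <- params$n_robots * params$gamma_fish
  pg <- grouping_probability(params)[["p_group"]]
  c(into_CW = params$beta_fish * pg * (max(F_CCW, 0) + g * (1 - R_CW)) *
      obs$obs_CW_by_CCW / (obs$obs_CCW_by_CCW + 1),
    into_CCW = params$beta_fish * pg * (max(F_CW, 0) + g * R_CW) *
      obs$obs_CCW_by_CW / (obs$obs_CW_by_CW + 1))
}

#' Net fish flow derivatives
#'
#' @inheritParams fish_social_flows
#' @return Named vector `c(dF_CW, dF_CCW)`, summing to zero exactly.
#' @export
fish_derivatives <- function(F_CW, F_CCW, R_CW = 0, obs,
                             params = fish_params()) {
  ind <- fish_individual_flows(F_CW, F_CCW, params)
  soc <- fish_social_flows(F_CW, F_CCW, R_CW, obs, params)
  d <- (ind[["into_CW"]] - ind[["into_CCW"]]) +
    (soc[["into_CW"]] - soc[["into_CCW"]])
  c(dF_CW = d, dF_CCW = -d)
}

#' Tracking-software direction proportions
#'
#' The overhead tracker miscounts some fish: the error added to the CW count
#' is `sigma_fishRobot * (X_CCW * F_CCW - X_CW * F_CW)` and the CCW error is
#' its negative, so the two proportions always sum to one.
#'
#' @param F_CW,F_CCW True fish counts per direction.
#' @param params A [fish_params()] object.
#' @param X_CW,X_CCW Realised `U(0, 1)` draws (default 0 = perfect tracking).
#' @return Named vector `c(prop_CW, prop_CCW)`.
#' @export
robot_track_fish <- function(F_CW, F_CCW, params = fish_params(),
                             X_CW = 0, X_CCW = 0) {
  err <- params$sigma_fishRobot * (X_CCW * F_CCW - X_CW * F_CW)
  total <- params$F_total
  stopifnot(total > 0)
  c(prop_CW = (F_CW + err) / total, prop_CCW = (F_CCW - err) / total)
}

#' Closed-loop robot direction decision
#'
#' Majority-following rule on the gliding average of tracked CW proportions:
#' above 0.5 swim CW (1), below 0.5 swim CCW (0), at exactly 0.5 choose a
#' fair-coin random direction.
#'
#' @param prop_history Numeric vector of recent CW proportions (the gliding
#'   window); empty history also triggers the random choice.
#' @param tie_draw A realised `U(0, 1)` draw used only on a tie/empty history.
#' @return 0 or 1.
#' @export
robot_decide <- function(prop_history, tie_draw = stats::runif(1)) {
  if (length(prop_history) == 0) return(as.numeric(tie_draw < 0.5))
  m <- mean(prop_history)
  if (m > 0.5) 1 else if (m < 0.5) 0 else as.numeric(tie_draw < 0.5)
}

#' Exogenous robot direction controller
#'
#' One update of the open-loop robot: in `"constant"` mode the direction is
#' held; in `"random_switching"` mode the two-state machine flips with
#' probability `p_switch` per time step.
#'
#' @param R_CW Current direction (0 or 1).
#' @param mode `"constant"` or `"random_switching"`.
#' @param p_switch Per-step switching probability in `[0, 1]`.
#' @param switch_draw A realised `U(0, 1)` draw consumed in random mode.
#' @return The direction for the current step.
#' @export
robot_exogenous <- function(R_CW, mode = c("constant", "random_switching"),
                            p_switch = 0.014, switch_draw = stats::runif(1)) {
  mode <- match.arg(mode)
  stopifnot(p_switch >= 0, p_switch <= 1)
  if (mode == "random_switching" && switch_draw < p_switch) 1 - R_CW else R_CW
}

#' Fish model specification
#'
#' @param params A [fish_params()] object.
#' @param robot_mode `"none"` (pure fish group), `"constant"`,
#'   `"random_switching"` (open loop) or `"closed_loop"`
#'   (majority-following).
#' @param R_init Initial robot direction (0 or 1); `NA` draws it randomly at
#'   the start of each replicate (the default for the open- and closed-loop
#'   modes).
#' @param p_switch Per-step switch probability for `"random_switching"`.
#' @param decision_window Gliding-average window (in steps) of the
#'   closed-loop controller; default 1 (one proportion per model second).
#' @param F_init Initial `c(F_CW, F_CCW)`; defaults to an even split.
#' @param solver `"rk4"` (default) or `"euler"`.
#' @return An object of class `fish_model`.
#' @export
fish_model <- function(params = fish_params(),
                       robot_mode = c("none", "constant", "random_switching",
                                      "closed_loop"),
                       R_init = NA, p_switch = 0.014, decision_window = 1,
                       F_init = NULL, solver = c("rk4", "euler")) {
  robot_mode <- match.arg(robot_mode)
  solver <- match.arg(solver)
  stopifnot(inherits(params, "fish_params"))
  if (robot_mode == "constant" && is.na(R_init)) R_init <- 1
  structure(list(params = params, robot_mode = robot_mode, R_init = R_init,
                 p_switch = p_switch, decision_window = decision_window,
                 F_init = F_init, solver = solver),
            class = "fish_model")
}

#' @describeIn run_replicate Zebrafish ring-corridor model (1-second grid).
#' @export
run_replicate.fish_model <- function(model, clock, seed, ...) {
  stopifnot(inherits(clock, "sim_clock"))
  if (clock$units != "seconds")
    stop("the fish model runs on a clock in seconds")
  p <- model$params
  n <- clock$n_steps
  dt <- clock$dt

  set.seed(as.integer(seed))
  init_draw <- stats::runif(1)

  F0 <- if (is.null(model$F_init)) c(p$F_total / 2, p$F_total / 2) else model$F_init
  stopifnot(abs(sum(F0) - p$F_total) < 1e-9)
  y <- c(F0[1], F0[2])
  R <- if (is.na(model$R_init)) as.numeric(init_draw < 0.5) else model$R_init

  cols <- c("time", "F_CW", "F_CCW", "R_CW", "prop_obs_CW")
  out <- matrix(NA_real_, nrow = n + 1L, ncol = length(cols),
                dimnames = list(NULL, cols))
  prop_hist <- numeric(n)
  max_corr <- 0
  w <- max(1L, as.integer(model$decision_window))

  for (i in seq_len(n)) {
    t <- (i - 1L) * dt
    Xp <- stats::runif(4)           # perception draws
    Xt <- stats::runif(2)           # tracker draws (CW, CCW)
    Xc <- stats::runif(1)           # controller draw (switch / tie-break)

    prop <- robot_track_fish(y[1], y[2], p, Xt[1], Xt[2])[["prop_CW"]]
    prop_hist[i] <- prop

    R <- switch(model$robot_mode,
                none = 0,
                constant = R,
                random_switching = robot_exogenous(R, "random_switching",
                                                   model$p_switch, Xc),
                closed_loop = robot_decide(prop_hist[max(1L, i - w + 1L):i], Xc))

    obs <- fish_perceive(y[1], y[2], R, p, Xp)
    deriv <- function(tt, s)
      fish_derivatives(s[1], s[2], R, obs, p)
    out[i, ] <- c(t, y, if (model$robot_mode == "none") NA_real_ else R, prop)
    y2 <- if (model$solver == "rk4") rk4_step(y, deriv, t, dt)
    else forward_difference_step(y, deriv(t, y), dt)
    f <- clamp_pair(y2, p$F_total)
    max_corr <- max(max_corr, attr(f, "corr"))
    y <- unname(c(f[1], f[2]))
  }
  out[n + 1L, 1:3] <- c(n * dt, y)
  if (max_corr > 1e-6 * p$F_total)
    warning(sprintf("fish run: post-step clamping moved up to %.3g fish (total %g)",
                    max_corr, p$F_total))
  new_trajectory("fish", as.data.frame(out), p, clock, seed)
}
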