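#' Honeybee aggregation model parameters
#'
#' Parameters of the two-CASU honeybee aggregation model. A group of young
#' bees splits between the left and right arena sides; bees leave a side at
#' rate `B / tau` where the resting time `tau` grows linearly with local
#' temperature (see [resting_time()]), and re-stop either spontaneously
#' (`alpha_bees`) or through mass-action social contact (`beta_bees`).
#'
#' The behavioural rates, noise scales and CASU thermal constants are
#' calibration defaults (chosen once so that the qualitative feedback regimes
#' hold; see the package vignette); the resting-time spans `tau_delta` /
#' `T_delta` and the temperature bounds are fixed model constants.
#'
#' @param alpha_bees Individual (spontaneous) stopping probability,
#'   dimensionless.
#' @param beta_bees Social-contact rate coefficient, per bee.
#' @param sigma_bees Half-width of the multiplicative flow noise
#'   `U(1 - sigma, 1 + sigma)`, in `[0, 1]`.
#' @param tau_delta Resting-time span (s) across the temperature span
#'   `T_delta`; 24 s by default so that `tau` runs from 1 s at 28 deg C to
#'   25 s at 36 deg C.
#' @param T_delta Temperature span (deg C) for the resting-time ramp.
#' @param T_min Minimum modelled temperature (deg C); the resting-time curve
#'   is undefined below it.
#' @param T_ambient Ambient arena temperature (deg C).
#' @param lambda_active_heating,lambda_active_cooling Active heating/cooling
#'   rates of a CASU (deg C per s).
#' @param lambda_passive_cooling Passive relaxation rate towards ambient
#'   (per s).
#' @param epsilon_temp Controller deadband (deg C).
#' @param delta_temp Feedback target step size (deg C).
#' @param sigma_beeCASU Scale of the one-sided (underestimating) bee-count
#'   observation noise, in `[0, 1]`.
#' @param obs_window Gliding-average window for the observed counts (s).
#' @param B_total Group size (bees).
#' @return A validated list of class `bee_params`.
#' @export
bee_params <- function(alpha_bees = 0.02,
                       beta_bees = 0.04,
                       sigma_bees = 1.0,
                       tau_delta = 24.0,
                       T_delta = 8.0,
                       T_min = 28.0,
                       T_ambient = 28.0,
                       lambda_active_heating = 0.005,
                       lambda_active_cooling = 0.1,
                       lambda_passive_cooling = 0.001,
                       epsilon_temp = 0.5,
                       delta_temp = 1.0,
                       sigma_beeCASU = 0.2,
                       obs_window = 30,
                       B_total = 12) {
  p <- list(alpha_bees = alpha_bees, beta_bees = beta_bees,
            sigma_bees = sigma_bees, tau_delta = tau_delta, T_delta = T_delta,
            T_min = T_min, T_ambient = T_ambient,
            lambda_active_heating = lambda_active_heating,
            lambda_active_cooling = lambda_active_cooling,
            lambda_passive_cooling = lambda_passive_cooling,
            epsilon_temp = epsilon_temp, delta_temp = delta_temp,
            sigma_beeCASU = sigma_beeCASU, obs_window = obs_window,
            B_total = B_total)
  p <- lapply(p, function(x) if (is.numeric(x)) unname(x) else x)
  rates <- c("alpha_bees", "beta_bees", "tau_delta", "T_delta",
             "lambda_active_heating", "lambda_active_cooling",
             "lambda_passive_cooling", "epsilon_temp", "delta_temp",
             "obs_window", "B_total")
  for (nm in rates)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop("bee_params: '", nm, "' must be a single non-negative number")
  for (nm in c("sigma_bees", "sigma_beeCASU"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop("bee_params: '", nm, "' must lie in [0, 1]")
  if (p$T_min > 36) stop("bee_params: T_min must not exceed 36 deg C")
  structure(p, class = "bee_params")
}

#' Temperature-, airflow- and vibration-dependent resting time
#'
#' Resting duration of a bee after stopping, as a linear ramp in the local
#' temperature, shortened by airflow (`phi`) and lengthened by vibration
#' (`psi`):
#' `tau = (1 + (tau_delta / T_delta) * (T - T_min) * (1 - phi)) * (1 + psi)`.
#' At the defaults this gives 1 s at 28 deg C and 25 s at 36 deg C.
#'
#' @param T_local Local temperature (deg C), must be `>= T_min`.
#' @param phi Airflow effect in `[0, 1]` (repellent; cancels the
#'   temperature-dependent part at 1).
#' @param psi Vibration effect in `[0, 1]` (stopping; doubles the resting
#'   time at 1).
#' @param params A [bee_params()] object.
#' @return Resting time in seconds (strictly positive).
#' @examples
#' resting_time(28)  # 1
#' resting_time(36)  # 25
#' @export
resting_time <- function(T_local, phi = 0, psi = 0, params = bee_params()) {
  if (any(T_local < params$T_min - 1e-8))
    stop("resting_time: temperature below T_min = ", params$T_min,
         " deg C; the model is undefined there")
  T_local <- pmax(T_local, params$T_min)
  (1 + params$tau_delta / params$T_delta * (T_local - params$T_min) *
     (1 - phi)) * (1 + psi)
}

#' Individual (spontaneous) side-switching flows
#'
#' Bees leave side X at rate `B_X / tau_X`; a fraction `alpha_bees` of the
#' leavers stops on the other side. Returns flows *into* each side, in
#' bees per second.
#'
#' @param B_R,B_L Bees on the right/left side.
#' @param tau_R,tau_L Resting times on each side (s).
#' @param params A [bee_params()] object.
#' @param X_R,X_L Realised noise factors (draw from
#'   `U(1 - sigma_bees, 1 + sigma_bees)`; default 1 = noise off).
#' @return Named vector `c(into_R, into_L)`.
#' @export
bee_individual_flows <- function(B_R, B_L, tau_R, tau_L,
                                 params = bee_params(), X_R = 1, X_L = 1) {
  c(into_R = params$alpha_bees * X_R * max(B_L, 0) / tau_L,
    into_L = params$alpha_bees * X_L * max(B_R, 0) / tau_R)
}

#' Socially induced side-switching flows
#'
#' Mass-action stopping: leavers from side X meet bees already present on the
#' other side, at a rate proportional to the product `B_R * B_L` and inversely
#' to the resting time at the origin side.
#'
#' @inheritParams bee_individual_flows
#' @return Named vector `c(into_R, into_L)`; zero whenever either side is
#'   empty.
#' @export
bee_social_flows <- function(B_R, B_L, tau_R, tau_L,
                             params = bee_params(), X_R = 1, X_L = 1) {
  prod <- max(B_R, 0) * max(B_L, 0)
  c(into_R = params$beta_bees * X_R * prod / tau_L,
    into_L = params$beta_bees * X_L * prod / tau_R)
}

#' Net bee flow derivatives
#'
#' Balances the individual and social flows; by construction
#' `dB_R/dt + dB_L/dt = 0` term by term (mass conservation).
#'
#' @inheritParams bee_individual_flows
#' @param noise Named list with elements `X_R_indiv`, `X_L_indiv`,
#'   `X_R_social`, `X_L_social` (all default 1).
#' @return Named vector `c(dB_R, dB_L)`.
#' @export
bee_derivatives <- function(B_R, B_L, tau_R, tau_L, params = bee_params(),
                            noise = list(X_R_indiv = 1, X_L_indiv = 1,
                                         X_R_social = 1, X_L_social = 1)) {
  ind <- bee_individual_flows(B_R, B_L, tau_R, tau_L, params,
                              noise$X_R_indiv, noise$X_L_indiv)
  soc <- bee_social_flows(B_R, B_L, tau_R, tau_L, params,
                          noise$X_R_social, noise$X_L_social)
  d <- (ind[["into_R"]] - ind[["into_L"]]) + (soc[["into_R"]] - soc[["into_L"]])
  c(dB_R = d, dB_L = -d)
}

#' CASU thermal derivatives
#'
#' Each CASU relaxes passively towards ambient and, outside a deadband
#' `epsilon_temp`, actively heats or cools at a fixed rate towards its target
#' temperature.
#'
#' @param T_R,T_L Current side temperatures (deg C).
#' @param target_R,target_L Target temperatures (deg C).
#' @param params A [bee_params()] object.
#' @return Named vector `c(dT_R, dT_L)` in deg C per second.
#' @export
casu_thermal_derivatives <- function(T_R, T_L, target_R, target_L,
                                     params = bee_params()) {
  one <- function(T_now, target) {
    d <- -params$lambda_passive_cooling * (T_now - params$T_ambient)
    if (target - T_now > params$epsilon_temp)
      d <- d + params$lambda_active_heating
    else if (T_now - target > params$epsilon_temp)
      d <- d - params$lambda_active_cooling
    d
  }
  c(dT_R = one(T_R, target_R), dT_L = one(T_L, target_L))
}

#' Noisy one-sided bee-count observation
#'
#' CASU infrared sensors underestimate the true local count (occlusion, blind
#' spots): `B_obs = B * (1 - sigma_beeCASU * X)` with `X ~ U(0, 1)`; there are
#' no false positives, so `0 <= B_obs <= B`.
#'
#' @param B_R,B_L True side counts.
#' @param params A [bee_params()] object.
#' @param X_R,X_L Realised uniform draws in `[0, 1]` (default 0 = perfect
#'   observation).
#' @return Named vector `c(B_obs_R, B_obs_L)`.
#' @export
observe_bees <- function(B_R, B_L, params = bee_params(), X_R = 0, X_L = 0) {
  c(B_obs_R = B_R * (1 - params$sigma_beeCASU * X_R),
    B_obs_L = B_L * (1 - params$sigma_beeCASU * X_L))
}

#' Feedback temperature-target update
#'
#' Reciprocal cross-inhibition on the gliding-average observed counts. In
#' `positive` mode the side that sensed more bees steps its target up by
#' `delta_temp` while the other steps down (amplifying aggregation); in
#' `negative` mode the comparison is inverted (suppressing aggregation). On a
#' tie both sides step down. Targets are clamped to `[28, 36]` deg C.
#'
#' @param obs_avg_R,obs_avg_L Gliding-average observed counts.
#' @param T_R,T_L Current side temperatures (deg C).
#' @param mode `"positive"` or `"negative"`.
#' @param params A [bee_params()] object.
#' @return Named vector `c(target_R, target_L)`.
#' @export
feedback_target_update <- function(obs_avg_R, obs_avg_L, T_R, T_L,
                                   mode = c("positive", "negative"),
                                   params = bee_params()) {
  mode <- match.arg(mode)
  d <- params$delta_temp
  if (mode == "positive") {
    step_R <- if (obs_avg_R > obs_avg_L) d else -d
    step_L <- if (obs_avg_R < obs_avg_L) d else -d
  } else {
    step_R <- if (obs_avg_R < obs_avg_L) d else -d
    step_L <- if (obs_avg_R > obs_avg_L) d else -d
  }
  clamp <- function(x) min(36, max(28, x))
  c(target_R = clamp(T_R + step_R), target_L = clamp(T_L + step_L))
}

#' Bee model specification
#'
#' Binds parameters, stimulus schedules, the temperature-control mode and the
#' initial condition into a runnable model (see [run_replicate()]).
#'
#' @param params A [bee_params()] object.
#' @param temp_mode `"fixed"` (targets follow the given schedules),
#'   `"positive"` or `"negative"` (closed-loop feedback on sensed bees).
#' @param T_target_R,T_target_L Target temperature schedules (constants or
#'   [piecewise_schedule()] functions); used in `"fixed"` mode.
#' @param psi_R,psi_L Vibration-effect schedules, values in `[0, 1]`.
#' @param phi_R,phi_L Airflow-effect schedules, values in `[0, 1]`.
#' @param phi_R_onset Optional airflow onset for the right side: a single time
#'   (deterministic) or a length-2 range from which the onset is drawn
#'   uniformly at the start of each replicate. Overrides `phi_R` with a step
#'   to `phi_R_value`.
#' @param phi_R_value Airflow level applied after `phi_R_onset`.
#' @param T_init Initial `c(T_R, T_L)`; defaults to the fixed targets at
#'   `t = 0` in `"fixed"` mode and to ambient otherwise.
#' @param B_init Initial `c(B_R, B_L)`; defaults to an even split.
#' @return An object of class `bee_model`.
#' @export
bee_model <- function(params = bee_params(),
                      temp_mode = c("fixed", "positive", "negative"),
                      T_target_R = 28, T_target_L = 28,
                      psi_R = 0, psi_L = 0, phi_R = 0, phi_L = 0,
                      phi_R_onset = NULL, phi_R_value = 0.6,
                      T_init = NULL, B_init = NULL) {
  temp_mode <- match.arg(temp_mode)
  stopifnot(inherits(params, "bee_params"))
  m <- list(params = params, temp_mode = temp_mode,
            T_target_R = as_schedule(T_target_R),
            T_target_L = as_schedule(T_target_L),
            psi_R = as_schedule(psi_R), psi_L = as_schedule(psi_L),
            phi_R = as_schedule(phi_R), phi_L = as_schedule(phi_L),
            phi_R_onset = phi_R_onset, phi_R_value = phi_R_value,
            T_init = T_init, B_init = B_init)
  structure(m, class = "bee_model")
}

## one draw set for one bee step; canonical order shared by the plain model
## and the lattice so that a 1x1 lattice is bit-identical to the plain run
bee_draws <- function(params) {
  s <- params$sigma_bees
  flow <- stats::runif(4, 1 - s, 1 + s)
  obs <- stats::runif(2)
  list(X_R_indiv = flow[1], X_L_indiv = flow[2],
       X_R_social = flow[3], X_L_social = flow[4],
       X_R_obs = obs[1], X_L_obs = obs[2])
}

## advance one bee unit (B_R, B_L, T_R, T_L) by one RK4 step with frozen
## inputs, then clamp the pair onto B_total; returns list(y, corr)
bee_advance <- function(y, draws, psi_R, psi_L, phi_R, phi_L,
                        target_R, target_L, params, t, dt) {
  deriv <- function(tt, s) {
    tau_R <- resting_time(max(s[3], params$T_min), phi_R, psi_R, params)
    tau_L <- resting_time(max(s[4], params$T_min), phi_L, psi_L, params)
    dB <- bee_derivatives(s[1], s[2], tau_R, tau_L, params, draws)
    dT <- casu_thermal_derivatives(s[3], s[4], target_R, target_L, params)
    c(dB[[1]], dB[[2]], dT[[1]], dT[[2]])
  }
  y2 <- rk4_step(y, deriv, t, dt)
  b <- clamp_pair(y2[1:2], params$B_total)
  list(y = c(b[1], b[2], y2[3], y2[4]), corr = attr(b, "corr"))
}

#' @describeIn run_replicate Honeybee two-CASU model (1-second grid).
#' @export
run_replicate.bee_model <- function(model, clock, seed, ...) {
  stopifnot(inherits(clock, "sim_clock"))
  if (clock$units != "seconds")
    stop("the bee model runs on a clock in seconds")
  p <- model$params
  n <- clock$n_steps
  dt <- clock$dt
  for (nm in c("T_target_R", "T_target_L", "psi_R", "psi_L", "phi_R", "phi_L"))
    check_schedule_coverage(model[[nm]], clock$t_end, nm)
  m_obs <- max(1L, as.integer(round(p$obs_window / dt)))

  set.seed(as.integer(seed))

  ## optional randomised airflow onset (one extra leading draw)
  phi_R_fun <- model$phi_R
  if (!is.null(model$phi_R_onset)) {
    onset <- if (length(model$phi_R_onset) == 2L)
      stats::runif(1, model$phi_R_onset[1], model$phi_R_onset[2])
    else model$phi_R_onset
    v <- model$phi_R_value
    phi_R_fun <- function(t) ifelse(t >= onset, v, 0)
  }

  T0 <- model$T_init
  if (is.null(T0)) {
    T0 <- if (model$temp_mode == "fixed")
      c(model$T_target_R(0), model$T_target_L(0))
    else c(p$T_ambient, p$T_ambient)
  }
  B0 <- if (is.null(model$B_init)) c(p$B_total / 2, p$B_total / 2) else model$B_init
  stopifnot(abs(sum(B0) - p$B_total) < 1e-9)
  y <- c(B0[1], B0[2], T0[1], T0[2])

  cols <- c("time", "B_R", "B_L", "T_R", "T_L", "T_target_R", "T_target_L",
            "psi_R", "psi_L", "phi_R", "phi_L", "B_obs_R", "B_obs_L",
            "obs_avg_R", "obs_avg_L")
  out <- matrix(NA_real_, nrow = n + 1L, ncol = length(cols),
                dimnames = list(NULL, cols))
  obs_hist_R <- numeric(n)
  obs_hist_L <- numeric(n)
  max_corr <- 0

  for (i in seq_len(n)) {
    t <- (i - 1L) * dt
    draws <- bee_draws(p)

    obs <- observe_bees(y[1], y[2], p, draws$X_R_obs, draws$X_L_obs)
    obs_hist_R[i] <- obs[[1]]
    obs_hist_L[i] <- obs[[2]]
    lo <- max(1L, i - m_obs + 1L)
    avg_R <- mean(obs_hist_R[lo:i])
    avg_L <- mean(obs_hist_L[lo:i])

    if (model$temp_mode == "fixed") {
      targets <- c(model$T_target_R(t), model$T_target_L(t))
    } else {
      targets <- feedback_target_update(avg_R, avg_L, y[3], y[4],
                                        model$temp_mode, p)
    }
    psi_R <- model$psi_R(t); psi_L <- model$psi_L(t)
    phi_R <- phi_R_fun(t); phi_L <- model$phi_L(t)

    out[i, ] <- c(t, y, targets[[1]], targets[[2]], psi_R, psi_L,
                  phi_R, phi_L, obs[[1]], obs[[2]], avg_R, avg_L)

    st <- bee_advance(y, draws, psi_R, psi_L, phi_R, phi_L,
                      targets[[1]], targets[[2]], p, t, dt)
    y <- st$y
    max_corr <- max(max_corr, st$corr)
  }
  out[n + 1L, c(1:5)] <- c(n * dt, y)
  if (max_corr > 1e-6 * p$B_total)
    warning(sprintf("bee run: post-step clamping moved up to %.3g bees (total %g)",
                    max_corr, p$B_total))
  new_trajectory("bee", as.data.frame(out), p, clock, seed)
}
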