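#' Bean-shoot growth model parameters
#'
#' Parameters of the growing bean-shoot model: biomass enters through a
#' central stem compartment at constant rate `rho_in`, is split evenly onto
#' the left and right flexible-mass compartments, moves laterally through
#' phototropism (`alpha_plant`, weighted by the light ratio) and
#' circumnutation (`beta_plant`, a mass-action term with multiplicative
#' Gaussian noise), and leaves by outgrowth at rate `rho_out`.
#'
#' @param rho_in Biomass influx rate (mass per minute, > 0).
#' @param rho_out Outgrowth rate (per minute, in `(0, 1)`).
#' @param alpha_plant Phototropic lateral-flow rate.
#' @param beta_plant Circumnutation (mass-action) rate.
#' @param sigma_plant S.d. of the motion noise `N(1, sigma_plant)`.
#' @param sigma_plantCASU S.d. of the light-controller detection noise
#'   `N(0, sigma_plantCASU)`.
#' @return A validated list of class `plant_params`.
#' @export
plant_params <- function(rho_in = 0.15,
                         rho_out = 0.005,
                         alpha_plant = 0.10,
                         beta_plant = 0.02,
                         sigma_plant = 0.35,
                         sigma_plantCASU = 0.02) {
  p <- list(rho_in = rho_in, rho_out = rho_out, alpha_plant = alpha_plant,
            beta_plant = beta_plant, sigma_plant = sigma_plant,
            sigma_plantCASU = sigma_plantCASU)
  p <- lapply(p, function(x) if (is.numeric(x)) unname(x) else x)
  for (nm in names(p))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop("plant_params: '", nm, "' must be a single non-negative number")
  if (p$rho_in <= 0) stop("plant_params: 'rho_in' must be > 0")
  if (p$rho_out <= 0 || p$rho_out >= 1)
    stop("plant_params: 'rho_out' must lie in (0, 1)")
  structure(p, class = "plant_params")
}

#' One forward-difference step of the plant model
#'
#' Advances `(P_stem, P_Rflex, P_Lflex)` by one 1-minute step. Per step the
#' stem receives `rho_in` and empties completely into the two sides (half
#' each); lateral switch flows are phototropic (`alpha * X * P_source *
#' light`) and circumnutatory (`beta * X * P_L * P_R`); each side loses
#' `rho_out` of its mass.
#'
#' Switch flows are floored at zero and the total switch outflow of a side is
#' capped at `(1 - rho_out)` of its mass (negative-mass protection). Because
#' every (possibly capped) switch term enters the two side equations with
#' opposite signs, the per-step mass balance
#' `Delta(total) = rho_in - rho_out * (P_R + P_L)` holds exactly.
#'
#' @param state Named numeric vector `c(P_stem, P_R, P_L)`.
#' @param light Light ratio `Lambda` in `[0, 1]` (0 = all light left).
#' @param params A [plant_params()] object.
#' @param noise Named list with `X_R_indiv`, `X_L_indiv`, `X_R_social`,
#'   `X_L_social` (default all 1 = noise off).
#' @param dt Step size in minutes (default 1).
#' @return Updated state vector.
#' @examples
#' plant_step(c(P_stem = 0, P_R = 0, P_L = 0), 0.5)  # stem fills to rho_in
#' @export
plant_step <- function(state, light, params = plant_params(),
                       noise = list(X_R_indiv = 1, X_L_indiv = 1,
                                    X_R_social = 1, X_L_social = 1),
                       dt = 1) {
  stopifnot(light >= 0, light <= 1)
  P_stem <- state[[1]]; P_R <- state[[2]]; P_L <- state[[3]]

  growth_R <- P_stem / 2
  growth_L <- P_stem / 2
  sw_R_ind <- max(0, params$alpha_plant * noise$X_R_indiv * P_L * light)
  sw_L_ind <- max(0, params$alpha_plant * noise$X_L_indiv * P_R * (1 - light))
  sw_R_soc <- max(0, params$beta_plant * noise$X_R_social * P_L * P_R)
  sw_L_soc <- max(0, params$beta_plant * noise$X_L_social * P_L * P_R)

  ## negative-mass protection: total switch outflow of a side may not exceed
  ## (1 - rho_out) of the source mass in one step
  cap_from_L <- (1 - params$rho_out) * P_L
  s_from_L <- sw_R_ind + sw_R_soc
  if (s_from_L > cap_from_L && s_from_L > 0) {
    f <- cap_from_L / s_from_L
    sw_R_ind <- sw_R_ind * f; sw_R_soc <- sw_R_soc * f
  }
  cap_from_R <- (1 - params$rho_out) * P_R
  s_from_R <- sw_L_ind + sw_L_soc
  if (s_from_R > cap_from_R && s_from_R > 0) {
    f <- cap_from_R / s_from_R
    sw_L_ind <- sw_L_ind * f; sw_L_soc <- sw_L_soc * f
  }

  delta <- c(params$rho_in - growth_R - growth_L,
             growth_R + sw_R_ind + sw_R_soc - sw_L_ind - sw_L_soc -
               params$rho_out * P_R,
             growth_L + sw_L_ind + sw_L_soc - sw_R_ind - sw_R_soc -
               params$rho_out * P_L)
  out <- forward_difference_step(c(P_stem, P_R, P_L), delta, dt)
  names(out) <- c("P_stem", "P_R", "P_L")
  pmax(out, 0)
}

#' Plant-tip inhomogeneity metric
#'
#' Normalised left-right imbalance of flexible plant mass, a proxy for the
#' horizontal tip position:
#' `Upsilon = 0.5 * ((P_R - P_L) / (P_R + P_L + 1) + 1)`.
#' Equals 0.5 at exact symmetry (including the empty state) and, thanks to
#' the `+ 1` in the denominator, never attains 0 or 1; small total mass keeps
#' the value near the centre (short shoots cannot reach far sideways).
#'
#' @param P_R,P_L Flexible mass on each side (>= 0).
#' @return Value in the open interval `(0, 1)`.
#' @examples
#' inhomogeneity(3, 1)  # 0.7
#' @export
inhomogeneity <- function(P_R, P_L) {
  0.5 * ((P_R - P_L) / (P_R + P_L + 1) + 1)
}

#' Positive-feedback light controller
#'
#' More detected plant mass on a side draws the light there:
#' `Lambda = Upsilon + X_detect`, clamped to `[0, 1]`.
#'
#' @param upsilon Current inhomogeneity.
#' @param x_detect Realised detection-noise draw
#'   (`N(0, sigma_plantCASU)`; default 0).
#' @return Light ratio in `[0, 1]`.
#' @export
light_posFB <- function(upsilon, x_detect = 0) {
  min(1, max(0, upsilon + x_detect))
}

#' Negative-feedback light controller
#'
#' Detected plant mass repels the light: `Lambda = 1 - Upsilon + X_detect`,
#' clamped to `[0, 1]`; drives the mass distribution back towards balance.
#'
#' @inheritParams light_posFB
#' @return Light ratio in `[0, 1]`.
#' @export
light_negFB <- function(upsilon, x_detect = 0) {
  min(1, max(0, 1 - upsilon + x_detect))
}

#' Binary target-tracking light controller
#'
#' Distilled rule of the evolved tip-guiding controller: if the tip
#' (`Upsilon`) is left of the target (`Gamma`) switch the right light on
#' (`Lambda = 1`), otherwise the left one (`Lambda = 0`). The tie
#' `Upsilon == Gamma` falls to the else-branch. No detection noise is
#' applied (tip detection by image processing is treated as exact).
#'
#' @param upsilon Current inhomogeneity.
#' @param gamma_t Current target position in `(0, 1)`.
#' @return 0 or 1.
#' @export
light_binary_target <- function(upsilon, gamma_t) {
  if (upsilon < gamma_t) 1 else 0
}

#' Plant model specification
#'
#' @param params A [plant_params()] object.
#' @param light_mode `"fixed"`, `"posFB"`, `"negFB"` or `"binary_target"`.
#' @param Lambda_fixed Light-ratio constant or schedule for `"fixed"` mode.
#' @param Gamma Target schedule in `(0, 1)` for `"binary_target"` mode;
#'   defaults to the three-phase guidance schedule (0.85 up to t = 640,
#'   0.2 up to t = 880, then 0.5).
#' @param init Initial `c(P_stem, P_R, P_L)`; defaults to the empty state.
#' @return An object of class `plant_model`.
#' @export
plant_model <- function(params = plant_params(),
                        light_mode = c("fixed", "posFB", "negFB",
                                       "binary_target"),
                        Lambda_fixed = 0.5,
                        Gamma = plant_target_schedule(),
                        init = c(0, 0, 0)) {
  light_mode <- match.arg(light_mode)
  stopifnot(inherits(params, "plant_params"))
  structure(list(params = params, light_mode = light_mode,
                 Lambda_fixed = as_schedule(Lambda_fixed),
                 Gamma = as_schedule(Gamma), init = init),
            class = "plant_model")
}

#' Three-phase tip-guidance target schedule
#'
#' The piecewise-constant target used in the guided-growth run: 0.85 (far
#' right) while `0 <= t <= 640`, 0.2 (left) while `641 <= t <= 880`, 0.5
#' (centre) while `881 <= t <= 1200`, with `t` in minutes.
#'
#' @return A [piecewise_schedule()] function.
#' @export
plant_target_schedule <- function() {
  piecewise_schedule(c(0, 641, 881), c(0.85, 0.2, 0.5))
}

#' @describeIn run_replicate Bean-shoot model (1-minute grid, forward
#'   differences).
#' @export
run_replicate.plant_model <- function(model, clock, seed, ...) {
  stopifnot(inherits(clock, "sim_clock"))
  if (clock$units != "minutes")
    stop("the plant model runs on a clock in minutes")
  p <- model$params
  n <- clock$n_steps
  dt <- clock$dt
  if (model$light_mode == "fixed")
    check_schedule_coverage(model$Lambda_fixed, clock$t_end, "Lambda_fixed")
  if (model$light_mode == "binary_target")
    check_schedule_coverage(model$Gamma, clock$t_end, "Gamma")

  set.seed(as.integer(seed))
  y <- model$init

  cols <- c("time", "P_stem", "P_R", "P_L", "upsilon", "lambda", "gamma")
  out <- matrix(NA_real_, nrow = n + 1L, ncol = length(cols),
                dimnames = list(NULL, cols))

  for (i in seq_len(n)) {
    t <- (i - 1L) * dt
    Xm <- stats::rnorm(4, mean = 1, sd = p$sigma_plant)
    Xd <- stats::rnorm(1, mean = 0, sd = p$sigma_plantCASU)
    ups <- inhomogeneity(y[[2]], y[[3]])
    gam <- NA_real_
    lam <- switch(model$light_mode,
                  fixed = min(1, max(0, model$Lambda_fixed(t))),
                  posFB = light_posFB(ups, Xd),
                  negFB = light_negFB(ups, Xd),
                  binary_target = {
                    gam <- model$Gamma(t)
                    light_binary_target(ups, gam)
                  })
    out[i, ] <- c(t, y[[1]], y[[2]], y[[3]], ups, lam, gam)
    y <- plant_step(y, lam, p,
                    noise = list(X_R_indiv = Xm[1], X_L_indiv = Xm[2],
                                 X_R_social = Xm[3], X_L_social = Xm[4]),
                    dt = dt)
  }
  out[n + 1L, 1:5] <- c(n * dt, y[[1]], y[[2]], y[[3]],
                        inhomogeneity(y[[2]], y[[3]]))
  new_trajectory("plant", as.data.frame(out), p, clock, seed)
}

#' Run the three-phase tip-guidance experiment
#'
#' Convenience wrapper: starts from the empty state and runs the
#' binary-target light controller against [plant_target_schedule()] for
#' 1200 one-minute steps.
#'
#' @param params A [plant_params()] object.
#' @param schedule Target schedule (default [plant_target_schedule()]).
#' @param seed Integer seed.
#' @param t_end Duration in minutes (default 1200).
#' @return A `bh_trajectory` with 1201 samples.
#' @export
run_target_tracking <- function(params = plant_params(),
                                schedule = plant_target_schedule(),
                                seed = 1, t_end = 1200) {
  model <- plant_model(params, light_mode = "binary_target", Gamma = schedule)
  run_replicate(model, sim_clock(1, t_end, units = "minutes"), seed)
}
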