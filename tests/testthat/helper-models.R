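## noise-free parameter sets used across tests
quiet_bee_params <- function(...) {
  bee_params(sigma_bees = 0, sigma_beeCASU = 0, ...)
}

quiet_fish_params <- function(...) {
  fish_params(sigma_fish = 0, sigma_fishRobot = 0, ...)
}

quiet_plant_params <- function(...) {
  plant_params(sigma_plant = 0, sigma_plantCASU = 0, ...)
}

## brute-force algebraic fixed point of the zero-noise bee flow system:
## solves alpha*(B_L/tau_L - B_R/tau_R) + beta*B_R*B_L*(1/tau_L - 1/tau_R) = 0
## on (0, B_total) by root bracketing
bee_equilibrium_oracle <- function(params, tau_R, tau_L) {
  B <- params$B_total
  f <- function(B_R) {
    B_L <- B - B_R
    params$alpha_bees * (B_L / tau_L - B_R / tau_R) +
      params$beta_bees * B_R * B_L * (1 / tau_L - 1 / tau_R)
  }
  stats::uniroot(f, c(1e-9, B - 1e-9), tol = 1e-12)$root
}

## independent transcription of the robot-free perception and social-flow
## equations (no robot terms anywhere), used as the reduction oracle
robot_free_fish_oracle <- function(F_CW, F_CCW, X, params) {
  s <- params$sigma_fish
  E_CCW_by_CW <- s * (F_CW - 1) * X[1]
  E_CW_by_CW <- s * F_CCW * X[2]
  E_CCW_by_CCW <- s * F_CW * X[3]
  E_CW_by_CCW <- s * (F_CCW - 1) * X[4]
  obs <- list(obs_CW_by_CW = F_CW + E_CW_by_CW - E_CCW_by_CW,
              obs_CCW_by_CW = F_CCW - E_CW_by_CW + E_CCW_by_CW,
              obs_CW_by_CCW = F_CW + E_CW_by_CCW - E_CCW_by_CCW,
              obs_CCW_by_CCW = F_CCW - E_CW_by_CCW + E_CCW_by_CCW)
  pg <- min(1, params$F_total * params$sight_ratio)
  flows <- c(into_CW = params$beta_fish * pg * F_CCW *
               obs$obs_CW_by_CCW / (obs$obs_CCW_by_CCW + 1),
             into_CCW = params$beta_fish * pg * F_CW *
               obs$obs_CCW_by_CW / (obs$obs_CW_by_CW + 1))
  list(obs = obs, flows = flows)
}
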