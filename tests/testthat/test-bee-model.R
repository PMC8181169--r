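test_that("resting time follows the linear temperature ramp with stimulus modulation", {
  expect_equal(resting_time(28.0), 1.0)
  expect_equal(resting_time(36.0), 25.0)
  expect_equal(resting_time(32.0), 13.0)          # 1 + 3 * (32 - 28)
  expect_equal(resting_time(36.0, phi = 1.0), 1.0)  # airflow cancels the ramp
  expect_equal(resting_time(36.0, psi = 1.0), 50.0) # vibration doubles it
  expect_error(resting_time(27.0), "below T_min")
})

test_that("individual and social flows match direct arithmetic", {
  p <- bee_params(alpha_bees = 0.25, beta_bees = 0.02)
  ind <- bee_individual_flows(B_R = 4, B_L = 8, tau_R = 2, tau_L = 4, p)
  expect_equal(ind[["into_R"]], 0.25 * 8 / 4)  # 0.5
  expect_equal(ind[["into_L"]], 0.25 * 4 / 2)
  soc <- bee_social_flows(B_R = 6, B_L = 6, tau_R = 2, tau_L = 4, p)
  expect_equal(soc[["into_R"]], 0.02 * 36 / 4)  # 0.18
  # mass action vanishes on an empty side
  expect_equal(unname(bee_social_flows(5, 0, 2, 4, p)), c(0, 0))
  # alpha = 0 silences the individual channel
  p0 <- bee_params(alpha_bees = 0)
  expect_equal(unname(bee_individual_flows(4, 8, 2, 4, p0)), c(0, 0))
  # a shorter contralateral resting time feeds the ipsilateral side faster
  s <- bee_social_flows(6, 6, tau_R = 10, tau_L = 2, p)
  expect_gt(s[["into_R"]], s[["into_L"]])
})

test_that("bee derivatives conserve the group exactly and break toward warmth", {
  p <- bee_params()
  set.seed(5)
  for (i in 1:25) {
    B_R <- runif(1, 0, 12); tau_R <- runif(1, 1, 25); tau_L <- runif(1, 1, 25)
    noise <- as.list(stats::setNames(runif(4, 0, 2),
                                     c("X_R_indiv", "X_L_indiv",
                                       "X_R_social", "X_L_social")))
    d <- bee_derivatives(B_R, 12 - B_R, tau_R, tau_L, p, noise)
    expect_identical(d[["dB_R"]] + d[["dB_L"]], 0)
  }
  # warm right side (longer tau_R) attracts at the symmetric state
  d <- bee_derivatives(6, 6, tau_R = 13, tau_L = 1, p)
  expect_gt(d[["dB_R"]], 0)
  # with everyone on the right, the only drain is the individual flow out
  d <- bee_derivatives(12, 0, tau_R = 13, tau_L = 1, p)
  expect_lte(d[["dB_R"]], 0)
})

test_that("CASU thermal law applies passive relaxation plus deadbanded action", {
  p <- bee_params(lambda_passive_cooling = 0.01, lambda_active_heating = 0.1,
                  lambda_active_cooling = 0.1, epsilon_temp = 0.5)
  expect_equal(casu_thermal_derivatives(28, 28, 28, 28, p),
               c(dT_R = 0, dT_L = 0))
  expect_equal(casu_thermal_derivatives(30, 28, 36, 28, p)[["dT_R"]],
               -0.01 * 2 + 0.1)   # 0.08
  expect_equal(casu_thermal_derivatives(36, 28, 28, 28, p)[["dT_R"]],
               -0.01 * 8 - 0.1)   # -0.18
})

test_that("bee observation underestimates one-sidedly", {
  p <- bee_params(sigma_beeCASU = 0.5)
  expect_equal(observe_bees(12, 7, bee_params(sigma_beeCASU = 0)),
               c(B_obs_R = 12, B_obs_L = 7))
  expect_equal(observe_bees(12, 0, p, X_R = 1)[["B_obs_R"]], 6)
  set.seed(2)
  for (i in 1:50) {
    x <- runif(2)
    o <- observe_bees(9, 3, p, x[1], x[2])
    expect_true(all(o >= 0) && o[["B_obs_R"]] <= 9 && o[["B_obs_L"]] <= 3)
  }
})

test_that("feedback target update cross-inhibits and clamps", {
  p <- bee_params(delta_temp = 1)
  up <- feedback_target_update(8, 3, T_R = 30, T_L = 30, "positive", p)
  expect_equal(up, c(target_R = 31, target_L = 29))
  dn <- feedback_target_update(8, 3, T_R = 30, T_L = 30, "negative", p)
  expect_equal(dn, c(target_R = 29, target_L = 31))
  # clamped at the working range boundaries
  expect_equal(feedback_target_update(8, 3, 36, 28, "positive", p),
               c(target_R = 36, target_L = 28))
  expect_error(feedback_target_update(1, 1, 30, 30, "sideways", p))
})

test_that("zero-noise symmetric runs stay symmetric to machine precision", {
  m <- bee_model(quiet_bee_params(), "fixed", 28, 28)
  tr <- run_replicate(m, sim_clock(1, 600), 3)
  expect_lt(max(abs(tr$data$B_R - tr$data$B_L)), 1e-9)
  expect_lt(max(abs(tr$data$B_R + tr$data$B_L - 12)), 1e-9)
})

test_that("zero-noise equilibrium matches the algebraic fixed point", {
  p <- quiet_bee_params(lambda_passive_cooling = 0)
  m <- bee_model(p, "fixed", 34, 30)    # pre-heated, frozen temperatures
  tr <- run_replicate(m, sim_clock(1, 4000), 1)
  tau_R <- resting_time(34, params = p)
  tau_L <- resting_time(30, params = p)
  oracle <- bee_equilibrium_oracle(p, tau_R, tau_L)
  expect_equal(tr$data$B_R[nrow(tr$data)], oracle, tolerance = 1e-6)
})

test_that("equilibrium share responds monotonically to each stimulus", {
  share_after <- function(...) {
    m <- bee_model(quiet_bee_params(lambda_passive_cooling = 0), "fixed", ...)
    tr <- run_replicate(m, sim_clock(1, 1500), 1)
    tr$data$B_R[1501] / 12
  }
  base <- share_after(30, 30)
  expect_gt(share_after(34, 30), base)                       # warmer right
  expect_lt(share_after(30, 30, phi_R = 0.5), base)          # airflow repels
  expect_gt(share_after(30, 30, psi_R = 0.5), base)          # vibration holds
})

test_that("parameter validation rejects out-of-range noise scales", {
  expect_error(bee_params(sigma_bees = 1.5), "\\[0, 1\\]")
  expect_error(bee_params(alpha_bees = -1), "non-negative")
})
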