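test_that("grouping probability saturates with apparent group size", {
  expect_equal(grouping_probability(fish_params(F_total = 6)),
               c(p_group = 1, p_alone = 0))
  expect_equal(grouping_probability(fish_params(F_total = 2))[["p_group"]], 0.4)
  expect_equal(grouping_probability(
    fish_params(F_total = 5, n_robots = 1, gamma_fish = 1))[["p_group"]], 1)
})

test_that("individual switch flows scale with aloneness", {
  p <- fish_params(alpha_fish = 0.01, F_total = 2.5)   # p_alone = 0.5
  f <- fish_individual_flows(F_CW = 1, F_CCW = 4, p)
  expect_equal(f[["into_CW"]], 0.01 * 0.5 * 4)  # 0.02
  # crowded arena: nobody is ever alone, no spontaneous switching
  p6 <- fish_params(F_total = 6)
  expect_equal(unname(fish_individual_flows(3, 3, p6)), c(0, 0))
  f <- fish_individual_flows(3, 3, p)
  expect_equal(f[["into_CW"]], f[["into_CCW"]])
})

test_that("noise-free perception returns true counts plus the robot share", {
  p <- fish_params(sigma_fish = 0, gamma_fish = 0.8, n_robots = 1, F_total = 5)
  obs <- fish_perceive(4, 1, R_CW = 1, p)
  expect_equal(obs$obs_CW_by_CW, 4 + 0.8)
  expect_equal(obs$obs_CCW_by_CW, 1)
  expect_equal(obs$obs_CW_by_CCW, 4 + 0.8)
  expect_equal(obs$obs_CCW_by_CCW, 1)
})

test_that("perceived counts are non-negative for every draw", {
  set.seed(9)
  for (i in 1:200) {
    p <- fish_params(sigma_fish = runif(1), gamma_fish = runif(1),
                     F_total = 5, n_robots = sample(0:3, 1))
    F_CW <- runif(1, 0, 5)
    obs <- fish_perceive(F_CW, 5 - F_CW, runif(1), p, runif(4))
    expect_true(all(unlist(obs) >= 0))
  }
  # with at least one fish in the observing class the raw bound already holds
  p <- fish_params(sigma_fish = 1, F_total = 5)
  obs <- fish_perceive(5, 0, 0, p, c(1, 1, 1, 1))
  expect_gte(obs$obs_CCW_by_CW, 0)
})

test_that("social switch flows match direct arithmetic", {
  p <- fish_params(beta_fish = 0.05, F_total = 5, n_robots = 0)  # p_group = 1
  obs <- list(obs_CW_by_CCW = 4, obs_CCW_by_CCW = 1,
              obs_CCW_by_CW = 1, obs_CW_by_CW = 4)
  f <- fish_social_flows(3, 2, 0, obs, p)
  expect_equal(f[["into_CW"]], 0.05 * 1 * 2 * 4 / (1 + 1))  # 0.2
  # consensus with no robot is a fixed point of the social flow
  p0 <- fish_params(sigma_fish = 0, n_robots = 0, F_total = 6)
  obs0 <- fish_perceive(6, 0, 0, p0)
  f0 <- fish_social_flows(6, 0, 0, obs0, p0)
  expect_equal(f0[["into_CW"]], 0)
  d0 <- fish_derivatives(6, 0, 0, obs0, p0)
  expect_identical(unname(d0), c(0, 0))
  # a lone opposing robot re-opens the consensus
  pr <- fish_params(sigma_fish = 0, gamma_fish = 1, n_robots = 1, F_total = 5)
  obsr <- fish_perceive(5, 0, R_CW = 0, pr)
  fr <- fish_social_flows(5, 0, R_CW = 0, obsr, pr)
  expect_gt(fr[["into_CCW"]], 0)
})

test_that("fish derivatives conserve the school and follow the robots", {
  p <- fish_params(F_total = 5, n_robots = 1)
  set.seed(4)
  for (i in 1:25) {
    F_CW <- runif(1, 0, 5)
    obs <- fish_perceive(F_CW, 5 - F_CW, runif(1), p, runif(4))
    d <- fish_derivatives(F_CW, 5 - F_CW, runif(1), obs, p)
    expect_identical(d[["dF_CW"]] + d[["dF_CCW"]], 0)
  }
  # constant-CW robots bias a 50:50 school toward CW (no perception noise)
  p0 <- fish_params(sigma_fish = 0, gamma_fish = 0.8, n_robots = 3, F_total = 3)
  obs <- fish_perceive(1.5, 1.5, R_CW = 1, p0)
  d <- fish_derivatives(1.5, 1.5, R_CW = 1, obs, p0)
  expect_gt(d[["dF_CW"]], 0)
})

test_that("gamma = 0 with no robots reduces to the robot-free equations", {
  p <- fish_params(sigma_fish = 0.7, gamma_fish = 0, n_robots = 0, F_total = 5)
  set.seed(17)
  for (F_CW in c(1, 2.5, 4)) {
    X <- runif(4)
    obs <- fish_perceive(F_CW, 5 - F_CW, R_CW = 1, p, X)
    oracle <- robot_free_fish_oracle(F_CW, 5 - F_CW, X, p)
    expect_identical(unlist(obs), unlist(oracle$obs))
    expect_identical(fish_social_flows(F_CW, 5 - F_CW, 1, obs, p),
                     oracle$flows)
  }
})

test_that("tracking proportions carry an antisymmetric error", {
  p <- fish_params(sigma_fishRobot = 0.1, F_total = 5)
  expect_equal(robot_track_fish(4, 1, fish_params(sigma_fishRobot = 0, F_total = 5)),
               c(prop_CW = 0.8, prop_CCW = 0.2))
  pr <- robot_track_fish(4, 1, p, X_CW = 0, X_CCW = 1)
  expect_equal(pr[["prop_CW"]], 0.82)
  set.seed(3)
  for (i in 1:50) {
    F_CW <- runif(1, 0, 5)
    pr <- robot_track_fish(F_CW, 5 - F_CW, p, runif(1), runif(1))
    expect_equal(pr[["prop_CW"]] + pr[["prop_CCW"]], 1)
  }
})

test_that("the closed-loop decision rule is majority-following with fair ties", {
  expect_equal(robot_decide(0.7), 1)
  expect_equal(robot_decide(0.3), 0)
  expect_equal(robot_decide(0.5, tie_draw = 0.2), 1)
  expect_equal(robot_decide(0.5, tie_draw = 0.9), 0)
  expect_equal(robot_decide(numeric(0), tie_draw = 0.2), 1)
})

test_that("the exogenous two-state machine switches at its configured rate", {
  expect_equal(robot_exogenous(1, "random_switching", 0, switch_draw = 0.5), 1)
  r <- 0
  for (i in 1:6) r[i + 1] <- robot_exogenous(r[i], "random_switching", 1,
                                             switch_draw = 0.3)
  expect_equal(r, c(0, 1, 0, 1, 0, 1, 0))
  expect_equal(robot_exogenous(1, "constant"), 1)
})

test_that("conservation holds along full fish trajectories", {
  m <- fish_model(fish_params(F_total = 5, n_robots = 1), "closed_loop")
  tr <- suppressWarnings(run_replicate(m, sim_clock(1, 400), 11))
  expect_lt(max(abs(tr$data$F_CW + tr$data$F_CCW - 5)), 1e-9)
  expect_true(all(tr$data$R_CW[1:400] %in% c(0, 1)))
})
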