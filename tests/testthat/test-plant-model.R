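## parameter set matching the worked fixed-point arithmetic
ref_plant <- function(...) quiet_plant_params(rho_in = 0.4, rho_out = 0.1, ...)

test_that("the stem fills to the influx rate after one step and stays there", {
  p <- ref_plant()
  s1 <- plant_step(c(0, 0, 0), 0.5, p)
  expect_equal(unname(s1), c(0.4, 0, 0))
  s2 <- plant_step(s1, 0.5, p)
  expect_equal(s2[["P_stem"]], 0.4)
  s3 <- plant_step(s2, 0.5, p)
  expect_equal(s3[["P_stem"]], 0.4)
})

test_that("per-step mass balance is exact under arbitrary noise", {
  p <- plant_params()
  set.seed(12)
  s <- c(P_stem = 0.3, P_R = 5, P_L = 2)
  for (i in 1:200) {
    noise <- as.list(stats::setNames(rnorm(4, 1, p$sigma_plant),
                                     c("X_R_indiv", "X_L_indiv",
                                       "X_R_social", "X_L_social")))
    lam <- runif(1)
    s2 <- plant_step(s, lam, p, noise)
    expect_equal(sum(s2) - sum(s),
                 p$rho_in - p$rho_out * (s[["P_R"]] + s[["P_L"]]),
                 tolerance = 1e-12)
    expect_true(all(s2 >= 0))
    s <- s2
  }
})

test_that("balanced light drives the flexible mass to its fixed point", {
  p <- ref_plant()
  s <- c(0, 0, 0)
  for (i in 1:400) s <- plant_step(s, 0.5, p)
  expect_equal(s[["P_R"]], 0.4 / (2 * 0.1), tolerance = 1e-6)
  expect_equal(s[["P_L"]], s[["P_R"]], tolerance = 1e-9)
})

test_that("full right light moves mass rightward whenever the left holds any", {
  p <- ref_plant()
  s <- c(P_stem = 0.4, P_R = 1, P_L = 1)
  s2 <- plant_step(s, 1, p)
  # no leftward phototropic flow at Lambda = 1
  expect_gt(s2[["P_R"]] - s2[["P_L"]], 0)
})

test_that("the inhomogeneity metric is centred, bounded and open", {
  expect_equal(inhomogeneity(0, 0), 0.5)
  expect_equal(inhomogeneity(2.3, 2.3), 0.5)
  expect_equal(inhomogeneity(3, 1), 0.7)
  expect_lt(inhomogeneity(1000, 0), 1)
  expect_gt(inhomogeneity(0, 1000), 0)
  # short shoots stay near the centre
  expect_lt(abs(inhomogeneity(0.02, 0) - 0.5), 0.01)
})

test_that("light controllers implement their feedback laws with clamping", {
  expect_equal(light_posFB(0.5), 0.5)
  expect_equal(light_posFB(0.98, x_detect = 0.4), 1)
  expect_equal(light_negFB(0.7), 0.3)
  expect_equal(light_negFB(0.5), 0.5)
  expect_equal(light_negFB(0.1, x_detect = -0.5), 0.4)
  expect_equal(light_binary_target(0.7, 0.85), 1)
  expect_equal(light_binary_target(0.9, 0.85), 0)
  expect_equal(light_binary_target(0.85, 0.85), 0)  # tie falls to the else-branch
})

test_that("the guidance target schedule has its three phases", {
  g <- plant_target_schedule()
  expect_equal(g(c(0, 640, 641, 880, 881, 1200)),
               c(0.85, 0.85, 0.2, 0.2, 0.5, 0.5))
})

test_that("target tracking runs the full guidance protocol", {
  tr <- run_target_tracking(seed = 5)
  d <- tr$data
  expect_equal(nrow(d), 1201L)
  # stem pins to the influx rate from the first step onward
  expect_equal(d$P_stem[-1], rep(plant_params()$rho_in, 1200), tolerance = 1e-12)
  expect_true(all(d$lambda[1:1200] %in% c(0, 1)))
  # late phase I: pushed toward, but bounded by, the far target
  late1 <- d$upsilon[d$time >= 400 & d$time <= 640]
  expect_gt(mean(late1), 0.5)
  expect_lt(mean(late1), 0.85)
  # the central target needs far more light switching than the lateral one
  sw1 <- light_switch_count(tr, c(400, 640)) / 240
  sw3 <- light_switch_count(tr, c(881, 1200)) / 320
  expect_gt(sw3, sw1)
})

test_that("plant parameter validation enforces the rate ranges", {
  expect_error(plant_params(rho_in = 0), "> 0")
  expect_error(plant_params(rho_out = 1.2), "\\(0, 1\\)")
})
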