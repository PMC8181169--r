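test_that("RK4 step reproduces hand-expanded and closed-form solutions", {
  # zero field
  expect_identical(rk4_step(0, function(t, y) 0 * y, 0, 1), 0)
  # constant field is exact
  expect_equal(rk4_step(2, function(t, y) 3, 0, 0.5), 3.5)
  # f = -y, dt = 1: the RK4 polynomial 1 - 1 + 1/2 - 1/6 + 1/24 = 0.375
  expect_equal(rk4_step(1, function(t, y) -y, 0, 1), 0.375, tolerance = 1e-12)
  # f = -y at dt = 0.01 tracks exp(-t) to 1e-6 relative error over [0, 5]
  y <- 1
  for (i in 1:500) y <- rk4_step(y, function(t, yy) -yy, (i - 1) * 0.01, 0.01)
  expect_equal(y, exp(-5), tolerance = 1e-6)
})

test_that("non-finite derivatives abort with the offending component named", {
  expect_error(
    rk4_step(c(a = 1, b = 1), function(t, y) c(0, Inf), 0, 1),
    "b")
  expect_error(forward_difference_step(c(x = 1), NaN), "x")
})

test_that("forward difference performs a plain explicit update", {
  expect_equal(forward_difference_step(0, 0.4 - 0, dt = 1), 0.4)
  expect_identical(forward_difference_step(c(1, 2), c(0, 0)), c(1, 2))
})

test_that("simulation clock validates its grid", {
  cl <- sim_clock(1, 1800)
  expect_equal(cl$n_steps, 1800L)
  expect_equal(cl$units, "seconds")
  expect_error(sim_clock(0.7, 10), "integer multiple")
  expect_error(sim_clock(-1, 10))
})

test_that("replicate seeds are deterministic, distinct and leave the RNG alone", {
  s1 <- replicate_seeds(42, 20)
  s2 <- replicate_seeds(42, 20)
  expect_identical(s1, s2)
  expect_equal(anyDuplicated(s1), 0L)
  set.seed(1); before <- runif(1)
  set.seed(1); replicate_seeds(99, 5); after <- runif(1)
  expect_identical(before, after)
})

test_that("a replicate is a pure function of (config, seed)", {
  m <- fish_model(fish_params(F_total = 5, n_robots = 1), "random_switching")
  cl <- sim_clock(1, 120)
  t1 <- suppressWarnings(run_replicate(m, cl, 7))
  t2 <- suppressWarnings(run_replicate(m, cl, 7))
  expect_identical(t1$data, t2$data)
  t3 <- suppressWarnings(run_replicate(m, cl, 8))
  expect_false(identical(t1$data, t3$data))
  # length contract: n_steps + 1 samples
  expect_equal(nrow(suppressWarnings(run_replicate(m, sim_clock(1, 1800), 1))$data),
               1801L)
})

test_that("with all noise scales at zero, different seeds give identical runs", {
  mb <- bee_model(quiet_bee_params(), "fixed", 30, 28)
  cl <- sim_clock(1, 200)
  expect_identical(run_replicate(mb, cl, 1)$data, run_replicate(mb, cl, 999)$data)
  mf <- fish_model(quiet_fish_params(F_total = 5, n_robots = 1), "constant",
                   R_init = 1)
  expect_identical(run_replicate(mf, cl, 1)$data, run_replicate(mf, cl, 999)$data)
  mp <- plant_model(quiet_plant_params(), "fixed", Lambda_fixed = 0.7)
  clm <- sim_clock(1, 200, units = "minutes")
  expect_identical(run_replicate(mp, clm, 1)$data, run_replicate(mp, clm, 999)$data)
})

test_that("disjoint base seeds give exchangeable replicate metrics", {
  a <- suppressWarnings(run_experiment("b1_homog", 15, 1001,
                                       keep_trajectories = FALSE))$summary
  b <- suppressWarnings(run_experiment("b1_homog", 15, 2002,
                                       keep_trajectories = FALSE))$summary
  ks <- suppressWarnings(stats::ks.test(a$majority_fraction, b$majority_fraction))
  expect_gt(ks$p.value, 0.01)
})

test_that("a schedule shorter than the run is rejected before integration", {
  short <- piecewise_schedule(c(0, 50), c(0, 0.1), t_max = 100)
  m <- bee_model(bee_params(), "fixed", 28, 28, psi_L = short)
  expect_error(run_replicate(m, sim_clock(1, 300), 1), "defined up to")
})

test_that("model and clock units must agree", {
  expect_error(run_replicate(bee_model(), sim_clock(1, 10, units = "minutes"), 1),
               "seconds")
  expect_error(run_replicate(plant_model(), sim_clock(1, 10), 1), "minutes")
})
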