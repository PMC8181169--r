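#!/usr/bin/env Rscript
## Calibration of the behavioural-rate and noise defaults.
##
## The shipped defaults of bee_params(), fish_params() and plant_params()
## were chosen once with this script so that the qualitative feedback
## regimes hold at the protocol settings:
##   bees   - median majority fraction ordered positive > control > negative,
##            strong decisions in the 32/36 C heterogeneous arena;
##   fish   - mixed groups with constantly-CW robots biased above 0.5,
##            robot-fish budget correlation tighter closed-loop than open-loop;
##   plants - positive light feedback committing to one side
##            (median |Upsilon - 0.5| >= 0.3 at t = 1200), negative feedback
##            holding the distribution balanced (<= 0.1).
##
## Run time is dominated by the replicate ensembles; with the reduced
## replicate counts below a full sweep takes tens of minutes. This script is
## exploratory tooling, not part of the test suite.

suppressPackageStartupMessages(library(biohybrid))

n_rep <- 14
seed <- 11

bee_cell <- function(alpha, beta, sigma, lh, lc) {
  ov <- list(alpha_bees = alpha, beta_bees = beta, sigma_bees = sigma,
             lambda_active_heating = lh, lambda_active_cooling = lc,
             lambda_passive_cooling = lh / 5)
  med <- function(name)
    median(suppressWarnings(
      run_experiment(name, n_rep, seed, ov, keep_trajectories = FALSE)
    )$summary$majority_fraction)
  data.frame(alpha = alpha, beta = beta, sigma = sigma, lh = lh,
             pos = med("b4_posFB"), ctl = med("b4_control"),
             neg = med("b4_negFB"), het = med("b1_heterog"))
}

fish_cell <- function(beta, sigma, gamma) {
  ov <- list(beta_fish = beta, sigma_fish = sigma, gamma_fish = gamma)
  s1 <- suppressWarnings(run_experiment("f1_mixed", n_rep, seed, ov,
                                        keep_trajectories = FALSE))$summary
  s2 <- suppressWarnings(run_experiment("f2_open_loop", n_rep, seed, ov,
                                        keep_trajectories = FALSE))$summary
  s3 <- suppressWarnings(run_experiment("f3_closed_loop", n_rep, seed, ov,
                                        keep_trajectories = FALSE))$summary
  data.frame(beta = beta, sigma = sigma, gamma = gamma,
             f1_cw = mean(s1$fish_cw_budget),
             corr_f2 = robot_group_correlation(s2),
             corr_f3 = robot_group_correlation(s3))
}

plant_cell <- function(rin, rout, alpha, beta, sp, sc) {
  pp <- plant_params(rho_in = rin, rho_out = rout, alpha_plant = alpha,
                     beta_plant = beta, sigma_plant = sp, sigma_plantCASU = sc)
  dev <- function(mode) {
    m <- plant_model(pp, mode)
    s <- run_ensemble(m, sim_clock(1, 1200, units = "minutes"), n_rep, seed,
                      keep_trajectories = FALSE)$summary
    median(abs(s$final_upsilon - 0.5))
  }
  data.frame(rin = rin, rout = rout, alpha = alpha, beta = beta, sp = sp,
             sc = sc, pos = dev("posFB"), neg = dev("negFB"))
}

message("bees (the shipped default is the first row):")
print(rbind(bee_cell(0.02, 0.04, 1.0, 0.005, 0.1),
            bee_cell(0.02, 0.04, 1.0, 0.1, 0.1),    # fast heating: neg > ctl
            bee_cell(0.06, 0.025, 0.6, 0.005, 0.1)))

message("fish (the shipped default is the first row):")
print(rbind(fish_cell(0.06, 0.25, 0.8),
            fish_cell(0.06, 0.50, 0.8)))            # excessive noise: anti-alignment

message("plants (the shipped default is the first row):")
print(rbind(plant_cell(0.15, 0.005, 0.10, 0.02, 0.35, 0.02),
            plant_cell(0.40, 0.100, 0.50, 0.030, 0.10, 0.05)))  # strong leak: no commitment
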