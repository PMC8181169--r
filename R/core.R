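#' Fixed-step simulation clock
#'
#' Defines the integration grid shared by a model and its schedules. The bee
#' and fish models run on a 1-second grid, the plant model on a 1-minute grid;
#' the unit is stored explicitly and never converted implicitly.
#'
#' @param dt Time step (> 0), in `units`.
#' @param t_end Total duration; must be an integer multiple of `dt`.
#' @param units Time unit label, `"seconds"` or `"minutes"`.
#' @return An object of class `sim_clock` with fields `dt`, `t_end`,
#'   `n_steps` and `units`.
#' @examples
#' sim_clock(1, 1200)
#' @export
sim_clock <- function(dt = 1, t_end = 1200, units = c("seconds", "minutes")) {
  units <- match.arg(units)
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(t_end), length(t_end) == 1L, t_end > 0)
  n <- t_end / dt
  if (abs(n - round(n)) > 1e-9)
    stop("t_end must be an integer multiple of dt")
  structure(list(dt = dt, t_end = t_end, n_steps = as.integer(round(n)),
                 units = units),
            class = "sim_clock")
}

#' @export
print.sim_clock <- function(x, ...) {
  cat(sprintf("<sim_clock> dt = %g %s, t_end = %g (%d steps)\n",
              x$dt, x$units, x$t_end, x$n_steps))
  invisible(x)
}

#' Classical fourth-order Runge-Kutta step
#'
#' Advances a state vector by one step of the classical RK4 scheme. All
#' stochastic inputs (noise draws, stimuli, controller outputs) must already be
#' frozen inside `deriv`: the same realised values are seen by all four stages,
#' so within a step the field is deterministic.
#'
#' @param state Numeric state vector (named components are used in error
#'   diagnostics).
#' @param deriv Function `(t, state) -> dstate/dt` returning a vector of the
#'   same length.
#' @param t Current time.
#' @param dt Step size.
#' @return Updated state vector.
#' @examples
#' rk4_step(1, function(t, y) -y, 0, 1)  # 0.375, the RK4 polynomial for f = -y
#' @export
rk4_step <- function(state, deriv, t, dt) {
  k1 <- deriv(t, state)
  k2 <- deriv(t + dt / 2, state + dt / 2 * k1)
  k3 <- deriv(t + dt / 2, state + dt / 2 * k2)
  k4 <- deriv(t + dt, state + dt * k3)
  out <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(!is.finite(out))) {
    bad <- which(!is.finite(out))
    nm <- names(state)
    lab <- if (is.null(nm)) as.character(bad) else nm[bad]
    stop("non-finite derivative update for state component(s): ",
         paste(lab, collapse = ", "))
  }
  out
}

#' Forward-difference step
#'
#' One explicit Euler / forward-difference update `state + dt * delta`, used by
#' the plant model, which is formulated as difference equations rather than
#' ODEs.
#'
#' @param state Numeric state vector.
#' @param delta Per-step change (already evaluated at the current state).
#' @param dt Step size (default 1).
#' @return Updated state vector.
#' @export
forward_difference_step <- function(state, delta, dt = 1) {
  out <- state + dt * delta
  if (any(!is.finite(out))) {
    bad <- which(!is.finite(out))
    nm <- names(state)
    lab <- if (is.null(nm)) as.character(bad) else nm[bad]
    stop("non-finite update for state component(s): ",
         paste(lab, collapse = ", "))
  }
  out
}

#' Derive replicate seeds from a base seed
#'
#' Splittable seed-sequence scheme: the base seed seeds R's generator once and
#' `n` distinct replicate seeds are sampled without replacement from
#' `1 .. 2^31 - 2`. Identical `(base_seed, n)` always yields the same seeds;
#' seeds within one ensemble cannot collide.
#'
#' @param base_seed Integer base seed.
#' @param n Number of replicate seeds.
#' @return Integer vector of length `n`.
#' @export
replicate_seeds <- function(base_seed, n) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(base_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a single seeded replicate
#'
#' Dispatches on the model object (`bee_model`, `fish_model`, `plant_model`).
#' Each step draws the model's named noise variates once, senses, applies the
#' configured controller, integrates with frozen inputs and clamps the
#' compartments back onto the conserved total.
#'
#' @param model A model specification object.
#' @param clock A [sim_clock()]; its unit must match the model's native unit.
#' @param seed Integer seed; identical `(model, clock, seed)` gives an
#'   identical trajectory.
#' @param ... Passed to methods.
#' @return A `bh_trajectory` object: a list with `model_type`, `data` (a
#'   data.frame of `n_steps + 1` rows), `params`, `clock` and `seed`.
#' @export
run_replicate <- function(model, clock, seed, ...) {
  UseMethod("run_replicate")
}

#' @export
run_replicate.default <- function(model, clock, seed, ...) {
  stop("no run_replicate method for class ", paste(class(model), collapse = "/"))
}

new_trajectory <- function(model_type, data, params, clock, seed) {
  structure(list(model_type = model_type, data = data, params = params,
                 clock = clock, seed = seed),
            class = "bh_trajectory")
}

#' @export
print.bh_trajectory <- function(x, ...) {
  cat(sprintf("<bh_trajectory> %s model, %d samples (dt = %g %s), seed = %s\n",
              x$model_type, nrow(x$data), x$clock$dt, x$clock$units,
              format(x$seed)))
  invisible(x)
}

#' Run a seeded ensemble of replicates
#'
#' Replicate `k` uses the `k`-th seed from [replicate_seeds()]. A per-replicate
#' summary row is computed with [summarise_replicate()].
#'
#' @param model A model specification object.
#' @param clock A [sim_clock()].
#' @param n_replicates Number of replicates (>= 1).
#' @param base_seed Integer base seed.
#' @param summary_args Named list of extra arguments for
#'   [summarise_replicate()] (e.g. the bee analysis `window`).
#' @param keep_trajectories Keep the full trajectories (default `TRUE`); set
#'   `FALSE` to retain summaries only for large sweeps.
#' @return A list of class `bh_ensemble` with `trajectories` (possibly `NULL`)
#'   and `summary`, a data.frame with one row per replicate.
#' @export
run_ensemble <- function(model, clock, n_replicates, base_seed,
                         summary_args = list(), keep_trajectories = TRUE) {
  stopifnot(n_replicates >= 1)
  seeds <- replicate_seeds(base_seed, n_replicates)
  trajs <- vector("list", n_replicates)
  rows <- vector("list", n_replicates)
  for (k in seq_len(n_replicates)) {
    tr <- run_replicate(model, clock, seeds[k])
    s <- do.call(summarise_replicate, c(list(tr), summary_args))
    rows[[k]] <- cbind(data.frame(replicate = k, seed = seeds[k]), s)
    if (keep_trajectories) trajs[[k]] <- tr
  }
  structure(list(trajectories = if (keep_trajectories) trajs else NULL,
                 summary = do.call(rbind, rows)),
            class = "bh_ensemble")
}

#' @export
print.bh_ensemble <- function(x, ...) {
  cat(sprintf("<bh_ensemble> %d replicates\n", nrow(x$summary)))
  print(utils::head(x$summary))
  invisible(x)
}

## shared helper: clamp a two-compartment pair onto its conserved total.
## Returns the corrected pair with the absolute correction in attr "corr";
## callers aggregate corrections and warn once per run.
clamp_pair <- function(pair, total) {
  p <- pmax(pair, 0)
  s <- p[1] + p[2]
  out <- if (s > 0) p * (total / s) else c(total / 2, total / 2)
  attr(out, "corr") <- sum(abs(out - pair))
  out
}

## piecewise-constant schedule closure: value[i] applies on [at[i], at[i+1]).
## t_max marks the last time the schedule is defined for (Inf = always).

#' Piecewise-constant stimulus schedule
#'
#' Builds a function of time returning `value[i]` for
#' `t` in `[at[i], at[i+1])`; the last value extends to `t_max`.
#'
#' @param at Increasing vector of onset times, starting at 0.
#' @param value Values, same length as `at`.
#' @param t_max Last time the schedule is valid for (default `Inf`).
#' @return A function `t -> value` with attribute `t_max`.
#' @examples
#' psi <- piecewise_schedule(c(0, 180), c(0, 0.1))
#' psi(100); psi(200)
#' @export
piecewise_schedule <- function(at, value, t_max = Inf) {
  stopifnot(length(at) == length(value), at[1] == 0, !is.unsorted(at, strictly = TRUE))
  force(at); force(value)
  f <- function(t) value[findInterval(t, at)]
  attr(f, "t_max") <- t_max
  f
}

## coerce a constant or schedule function to a schedule; validate coverage
as_schedule <- function(x, name = deparse(substitute(x))) {
  if (is.function(x)) return(x)
  stopifnot(is.numeric(x), length(x) == 1L)
  f <- function(t) rep.int(x, length(t))
  attr(f, "t_max") <- Inf
  f
}

check_schedule_coverage <- function(f, t_end, name) {
  tm <- attr(f, "t_max")
  if (!is.null(tm) && tm < t_end)
    stop(sprintf("schedule '%s' is defined up to t = %g but the run lasts until t = %g",
                 name, tm, t_end))
  invisible(TRUE)
}
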