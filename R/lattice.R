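#' Lattice scale-up configuration
#'
#' A grid of two-compartment bee units coupled to their von Neumann
#' neighbours by diffusion flows of non-resting bees. Each node runs the
#' plain bee dynamics with fixed temperature targets; after each internal
#' step, every node sends `d_coupling * dt * (B_R/tau_R + B_L/tau_L) /
#' degree` bees to each neighbour (taken from its sides in proportion to
#' their mobile fraction, deposited half-half on the receiver's sides).
#' Boundaries are reflecting (edge nodes simply have fewer neighbours). The
#' flow law is an extrapolation of the lattice concept, documented in the
#' vignette.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param d_coupling Inter-node diffusion rate (per second, >= 0).
#' @param params A [bee_params()] object shared by all nodes; `B_total` is
#'   the initial population per node.
#' @param T_target_R,T_target_L Fixed target temperatures: scalars or
#'   `n_rows x n_cols` matrices.
#' @return An object of class `lattice_config`.
#' @export
lattice_config <- function(n_rows = 1, n_cols = 1, d_coupling = 0.01,
                           params = bee_params(),
                           T_target_R = 28, T_target_L = 28) {
  stopifnot(n_rows >= 1, n_cols >= 1, d_coupling >= 0,
            inherits(params, "bee_params"))
  expand <- function(x) {
    if (length(x) == 1L) matrix(x, n_rows, n_cols)
    else {stopifnot(all(dim(x) == c(n_rows, n_cols))); x}
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, d_coupling = d_coupling,
                 params = params, T_target_R = expand(T_target_R),
                 T_target_L = expand(T_target_L)),
            class = "lattice_config")
}

#' Run a coupled bee lattice
#'
#' Each node owns an independent noise stream: node 1 is seeded with `seed`
#' itself and nodes 2..n with seeds derived via [replicate_seeds()]. A 1x1
#' lattice therefore reproduces a plain fixed-target [bee_model()] run bit
#' for bit, and with `d_coupling = 0` every node evolves exactly as an
#' isolated run under its own seed. Nodes are advanced in row-major order
#' each step; the diffusion exchange is applied afterwards from a frozen
#' post-step snapshot. The global bee total is conserved exactly.
#'
#' @param config A [lattice_config()].
#' @param clock A [sim_clock()] in seconds.
#' @param seed Integer seed.
#' @return A list of class `bh_lattice` with `times` and arrays `B_R`, `B_L`,
#'   `T_R`, `T_L` of dimension `(n_steps + 1) x n_nodes` (nodes in row-major
#'   order), plus `total`, the global population per step.
#' @export
run_lattice <- function(config, clock, seed) {
  stopifnot(inherits(config, "lattice_config"), inherits(clock, "sim_clock"))
  if (clock$units != "seconds") stop("the lattice runs on a clock in seconds")
  p <- config$params
  nr <- config$n_rows; nc <- config$n_cols
  n_nodes <- nr * nc
  n <- clock$n_steps
  dt <- clock$dt

  ## row-major node index and von Neumann neighbour lists
  idx <- function(r, c) (r - 1L) * nc + c
  nbrs <- vector("list", n_nodes)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    v <- integer(0)
    if (r > 1) v <- c(v, idx(r - 1L, c))
    if (r < nr) v <- c(v, idx(r + 1L, c))
    if (c > 1) v <- c(v, idx(r, c - 1L))
    if (c < nc) v <- c(v, idx(r, c + 1L))
    nbrs[[idx(r, c)]] <- v
  }
  deg <- lengths(nbrs)

  tR_target <- as.vector(t(config$T_target_R))
  tL_target <- as.vector(t(config$T_target_L))

  ## one RNG substream per node (node 1 = the run seed itself)
  node_seeds <- c(as.integer(seed),
                  if (n_nodes > 1L) replicate_seeds(seed, n_nodes - 1L))
  rng_states <- vector("list", n_nodes)
  for (k in seq_len(n_nodes)) {
    set.seed(node_seeds[k])
    rng_states[[k]] <- get(".Random.seed", envir = globalenv())
  }

  B_R <- rep(p$B_total / 2, n_nodes)
  B_L <- rep(p$B_total / 2, n_nodes)
  T_R <- tR_target
  T_L <- tL_target
  ## per-node conserved totals, updated only by the coupling flows, so the
  ## within-node clamp normalises against the exact invariant
  node_total <- rep(p$B_total, n_nodes)

  arr <- function() matrix(NA_real_, n + 1L, n_nodes)
  out <- list(B_R = arr(), B_L = arr(), T_R = arr(), T_L = arr())
  save_row <- function(i) {
    out$B_R[i, ] <<- B_R; out$B_L[i, ] <<- B_L
    out$T_R[i, ] <<- T_R; out$T_L[i, ] <<- T_L
  }
  save_row(1L)

  for (i in seq_len(n)) {
    t <- (i - 1L) * dt
    ## internal bee dynamics, node by node in row-major order
    for (k in seq_len(n_nodes)) {
      assign(".Random.seed", rng_states[[k]], envir = globalenv())
      draws <- bee_draws(p)
      rng_states[[k]] <- get(".Random.seed", envir = globalenv())
      if (node_total[k] > 0) {
        pk <- p; pk$B_total <- node_total[k]
        st <- bee_advance(c(B_R[k], B_L[k], T_R[k], T_L[k]), draws,
                          0, 0, 0, 0, tR_target[k], tL_target[k], pk, t, dt)
        B_R[k] <- st$y[1]; B_L[k] <- st$y[2]
        T_R[k] <- st$y[3]; T_L[k] <- st$y[4]
      }
    }
    ## diffusion exchange from a frozen snapshot
    if (config$d_coupling > 0 && n_nodes > 1L) {
      sBR <- B_R; sBL <- B_L
      for (k in seq_len(n_nodes)) {
        tau_R <- resting_time(T_R[k], 0, 0, p)
        tau_L <- resting_time(T_L[k], 0, 0, p)
        mob_R <- sBR[k] / tau_R
        mob_L <- sBL[k] / tau_L
        mob <- mob_R + mob_L
        if (mob <= 0) next
        q <- min(config$d_coupling * dt * mob, 0.5 * (sBR[k] + sBL[k]))
        per_nb <- q / deg[k]
        for (j in nbrs[[k]]) {
          B_R[j] <- B_R[j] + per_nb / 2
          B_L[j] <- B_L[j] + per_nb / 2
        }
        B_R[k] <- B_R[k] - q * mob_R / mob
        B_L[k] <- B_L[k] - q * mob_L / mob
        node_total[k] <- node_total[k] - q
        for (j in nbrs[[k]]) node_total[j] <- node_total[j] + per_nb
      }
    }
    save_row(i + 1L)
  }
  structure(list(times = seq(0, n * dt, by = dt), B_R = out$B_R,
                 B_L = out$B_L, T_R = out$T_R, T_L = out$T_L,
                 total = rowSums(out$B_R) + rowSums(out$B_L),
                 config = config, clock = clock, seed = seed),
            class = "bh_lattice")
}

#' @export
print.bh_lattice <- function(x, ...) {
  cat(sprintf("<bh_lattice> %d x %d nodes, %d samples, total = %.6g bees\n",
              x$config$n_rows, x$config$n_cols, length(x$times),
              x$total[length(x$total)]))
  invisible(x)
}
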