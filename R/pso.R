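#' Particle swarm optimizer settings
#'
#' Defaults follow common practice for SVM hyperparameter tuning with this
#' optimizer: a cognitive factor below the social factor (c1 = 1.6,
#' c2 = 2.0) so particles are not trapped in purely local search, and a
#' swarm/iteration budget of 300/300. The inertia weight decays linearly
#' from 0.9 to 0.5 over the run (see [pso_inertia()]).
#'
#' @param bounds 2-row matrix (or 2-column matrix, coerced) of per-dimension
#'   `low`/`high` box bounds; one column per search dimension.
#' @param swarm_size Number of particles, >= 2.
#' @param t_max Iteration cap, >= 1.
#' @param c1,c2 Cognitive and social acceleration factors, > 0. A notice is
#'   logged when c1 > c2 (biases particles toward local search).
#' @param tol Absolute improvement in the global best over `patience`
#'   iterations below which the run stops early.
#' @param patience Convergence window, iterations.
#' @param seed Integer seed for initialization and the stochastic updates.
#' @return A `pso_config` list.
#' @export
pso_config <- function(bounds, swarm_size = 300L, t_max = 300L,
                       c1 = 1.6, c2 = 2.0, tol = 1e-8, patience = 20L,
                       seed = 1L) {
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2L && ncol(bounds) == 2L) bounds <- t(bounds)
  if (nrow(bounds) != 2L) stopf("bounds must give low/high per dimension")
  if (any(bounds[2, ] <= bounds[1, ])) stopf("bounds require low < high")
  if (!is_count(swarm_size) || swarm_size < 2) stopf("swarm_size must be >= 2")
  if (!is_count(t_max)) stopf("t_max must be >= 1")
  if (c1 <= 0 || c2 <= 0) stopf("c1 and c2 must be positive")
  if (c1 > c2) {
    wq_note("pso", sprintf(
      "c1 (%.3g) > c2 (%.3g): particles may be trapped in local search", c1, c2))
  }
  rownames(bounds) <- c("low", "high")
  structure(list(bounds = bounds, swarm_size = as.integer(swarm_size),
                 t_max = as.integer(t_max), c1 = c1, c2 = c2, tol = tol,
                 patience = as.integer(patience), seed = seed),
            class = "pso_config")
}

#' Linearly decreasing inertia weight
#'
#' `omega(t) = 0.9 - 0.4 * t / t_max`: strong global exploration early
#' (0.9) decaying to strong convergence late (0.5).
#'
#' @param t Current iteration, 0 <= t <= t_max.
#' @param t_max Iteration cap.
#' @return Inertia weight.
#' @export
#' @examples
#' pso_inertia(0, 300)    # 0.9
#' pso_inertia(300, 300)  # 0.5
pso_inertia <- function(t, t_max) {
  if (any(t < 0) || any(t > t_max)) stopf("t must lie in [0, t_max]")
  0.9 - 0.4 * t / t_max
}

# Evaluate the objective for every particle; error on non-finite values.
eval_swarm <- function(objective, z) {
  f <- apply(z, 1L, objective)
  if (!is.numeric(f) || any(!is.finite(f))) {
    bad <- which(!is.finite(f))[1]
    stopf("optimization error: non-finite objective at position (%s)",
          paste(signif(z[bad, ], 6), collapse = ", "))
  }
  f
}

pso_init <- function(objective, cfg) {
  d <- ncol(cfg$bounds)
  lo <- cfg$bounds[1, ]
  hi <- cfg$bounds[2, ]
  width <- hi - lo
  z <- matrix(runif(cfg$swarm_size * d), cfg$swarm_size, d)
  z <- sweep(sweep(z, 2L, width, "*"), 2L, lo, "+")
  v <- matrix(runif(cfg$swarm_size * d, -1, 1), cfg$swarm_size, d)
  v <- sweep(v, 2L, 0.1 * width, "*")
  f <- eval_swarm(objective, z)
  best <- which.min(f)
  structure(list(z = z, v = v, pbest = z, pbest_f = f,
                 gbest = z[best, ], gbest_f = f[best], t = 0L),
            class = "swarm_state")
}

#' One particle swarm iteration
#'
#' Velocity update `v <- omega v + c1 r1 (pbest - z) + c2 r2 (gbest - z)`
#' with fresh uniform draws `r1`, `r2` per particle and dimension, followed
#' by the position update `z <- z + v`. Velocities are clamped to half the
#' box width; positions are clipped to the bounds with the offending
#' velocity component zeroed. Personal and global bests are refreshed under
#' the minimization convention and the iteration counter advances.
#'
#' Uses the current R random stream; seed via [pso_optimize()] or
#' `set.seed()` for reproducibility.
#'
#' @param state A `swarm_state` (from a previous step or [pso_optimize()]'s
#'   internals).
#' @param objective Function mapping a position vector to a finite scalar.
#' @param cfg A [pso_config()].
#' @return Updated `swarm_state`.
#' @export
pso_step <- function(state, objective, cfg) {
  d <- ncol(cfg$bounds)
  np <- cfg$swarm_size
  lo <- matrix(cfg$bounds[1, ], np, d, byrow = TRUE)
  hi <- matrix(cfg$bounds[2, ], np, d, byrow = TRUE)
  vmax <- 0.5 * (hi - lo)
  w <- pso_inertia(state$t, cfg$t_max)
  r1 <- matrix(runif(np * d), np, d)
  r2 <- matrix(runif(np * d), np, d)
  gb <- matrix(state$gbest, np, d, byrow = TRUE)
  v <- w * state$v + cfg$c1 * r1 * (state$pbest - state$z) +
    cfg$c2 * r2 * (gb - state$z)
  v <- pmin(pmax(v, -vmax), vmax)
  z <- state$z + v
  out_lo <- z < lo
  out_hi <- z > hi
  v[out_lo | out_hi] <- 0
  z <- pmin(pmax(z, lo), hi)
  f <- eval_swarm(objective, z)
  improved <- f < state$pbest_f
  state$pbest[improved, ] <- z[improved, ]
  state$pbest_f[improved] <- f[improved]
  best <- which.min(state$pbest_f)
  if (state$pbest_f[best] < state$gbest_f) {
    state$gbest_f <- state$pbest_f[best]
    state$gbest <- state$pbest[best, ]
  }
  state$z <- z
  state$v <- v
  state$t <- state$t + 1L
  state
}

#' Run the particle swarm optimizer
#'
#' Initializes positions uniformly in the box (velocities at a tenth of the
#' box width), iterates [pso_step()] and stops when the iteration cap is
#' reached or the global best has improved by less than `cfg$tol` over the
#' last `cfg$patience` iterations.
#'
#' @param objective Function position -> finite scalar; minimized. Negate
#'   the objective to maximize.
#' @param cfg A [pso_config()].
#' @return List with `par` (best position), `value` (best fitness),
#'   `iterations` used, and `history` of the global best per iteration
#'   (element 1 = after initialization).
#' @export
#' @examples
#' sphere <- function(z) sum(z^2)
#' cfg <- pso_config(rbind(c(-5, -5), c(5, 5)), swarm_size = 40, t_max = 100)
#' fit <- pso_optimize(sphere, cfg)
#' fit$value
pso_optimize <- function(objective, cfg) {
  stopifnot(inherits(cfg, "pso_config"))
  with_seed(cfg$seed, {
    state <- pso_init(objective, cfg)
    history <- numeric(cfg$t_max + 1L)
    history[1L] <- state$gbest_f
    while (state$t < cfg$t_max) {
      state <- pso_step(state, objective, cfg)
      history[state$t + 1L] <- state$gbest_f
      t <- state$t
      if (t >= cfg$patience) {
        if (history[t + 1L - cfg$patience] - history[t + 1L] < cfg$tol) break
      }
    }
    list(par = state$gbest, value = state$gbest_f, iterations = state$t,
         history = history[seq_len(state$t + 1L)])
  })
}
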