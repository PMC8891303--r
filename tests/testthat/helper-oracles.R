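# Shared fixtures and independent oracles.

# Explicit-Euler time stepping of the same spatial discretization, with
# trapezoidal quadrature of the boundary flux. Independent of the spectral
# propagation / closed-form flux integrals it cross-checks.
euler_released_mass <- function(mat, sched, grid, dt_factor = 10) {
  genR <- build_generator(grid, mat$D, "R")
  genP <- build_generator(grid, mat$D, "P")
  state <- sqrt(grid$widths)
  flux_coef <- mat$D / grid$widths[1]^1.5
  dt_max <- min(grid$widths)^2 / (dt_factor * mat$D)
  m <- 0
  for (p in seq_along(sched$kind)) {
    M <- if (sched$kind[p] == "R") genR$matrix else genP$matrix
    tau <- sched$duration[p]
    nstep <- ceiling(tau / dt_max)
    dt <- tau / nstep
    for (k in seq_len(nstep)) {
      f0 <- flux_coef * state[1]
      state <- state - dt * drop(M %*% state)
      if (sched$kind[p] == "R") {
        m <- m + dt * (f0 + flux_coef * state[1]) / 2
      }
    }
  }
  list(m = m, state = state)
}

# A tiny finite slab whose 5-interval grid keeps the Euler oracle cheap.
tiny_material <- function() material(D = 1e-10, b = 1e-4)
tiny_settings <- function() solver_settings(N1 = 5, N2 = 2)
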