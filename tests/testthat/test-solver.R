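test_that("grid construction handles all three thickness branches", {
  st <- solver_settings(N1 = 2, N2 = 1, grid_factor = 50)
  g <- build_grid(material(D = 1e-10), 10800, st)
  expect_equal(g$L_turn, 1.4697e-3, tolerance = 1e-4)
  expect_equal(g$L, 7.3485e-2, tolerance = 1e-4)
  expect_equal(sum(g$widths), g$L)
  expect_equal(g$delta0, g$widths[1])

  # finite slab thinner than the turning depth: single uniform sector
  gf <- build_grid(material(D = 1e-10, b = 7e-4), 10800, solver_settings(N1 = 10))
  expect_equal(length(gf$widths), 10)
  expect_true(all(abs(gf$widths - 7e-5) < 1e-18))
  expect_equal(sum(gf$widths), 7e-4)

  # finite slab thicker than the turning depth: two sectors up to b
  gt <- build_grid(material(D = 1e-10, b = 5e-3), 10800,
                   solver_settings(N1 = 4, N2 = 3))
  expect_equal(length(gt$widths), 7)
  expect_equal(sum(gt$widths), 5e-3)
  expect_equal(sum(gt$widths[1:4]), gt$L_turn, tolerance = 1e-12)
})

test_that("phase generators reproduce the uniform-grid stencil", {
  D <- 1e-10
  g <- build_grid(material(D = D, b = 5e-4), 3600, solver_settings(N1 = 5))
  dl <- g$widths[1]
  R <- build_generator(g, D, "R")
  P <- build_generator(g, D, "P")
  base <- D / dl^2
  expR <- base * (diag(c(2, 2, 2, 2, 1)) +
                    rbind(cbind(0, diag(-1, 4)), 0) +
                    cbind(rbind(0, diag(-1, 4)), 0))
  expP <- expR; expP[1, 1] <- base
  expect_equal(R$matrix, expR, tolerance = 1e-12)
  expect_equal(P$matrix, expP, tolerance = 1e-12)
})

test_that("pause generator conserves mass, release generator dissipates", {
  # deliberately non-uniform grid
  g <- build_grid(material(D = 1e-11), 7200, solver_settings(N1 = 3, N2 = 2))
  P <- build_generator(g, 1e-11, "P")
  R <- build_generator(g, 1e-11, "R")
  v <- sqrt(g$widths)
  expect_lt(max(abs(P$matrix %*% v)), 1e-12 * max(abs(P$matrix)))
  expect_lt(abs(min(P$values)) / max(P$values), 1e-12)
  expect_gt(min(R$values), 0)
  expect_true(all(R$matrix[cbind(1:4, 2:5)] < 0))
})

test_that("spectral propagation matches identity, null vector, and Euler", {
  mat <- tiny_material()
  g <- build_grid(mat, 180, tiny_settings())
  R <- build_generator(g, mat$D, "R")
  P <- build_generator(g, mat$D, "P")
  state <- sqrt(g$widths) * stats::runif(g$n_int, 0.5, 1.5)
  expect_equal(propagate(state, R, 0), state, tolerance = 1e-12)
  # a flat profile is invariant under any pause
  flat <- sqrt(g$widths)
  expect_equal(propagate(flat, P, 1e5), flat, tolerance = 1e-9)
  # explicit-Euler oracle on the same small grid
  sched <- make_schedule(c(60, 60), 60)
  eu <- euler_released_mass(mat, sched, g)
  st <- flat
  for (p in 1:3) {
    st <- propagate(st, if (p == 2) P else R, sched$duration[p])
  }
  expect_equal(st, eu$state, tolerance = 1e-3)
})

test_that("released mass matches the Euler oracle over a 3-phase schedule", {
  mat <- tiny_material()
  sched <- make_schedule(c(60, 60), 60)
  res <- released_mass(mat, sched, tiny_settings(), samples_per_phase = 0)
  eu <- euler_released_mass(mat, sched,
                            build_grid(mat, total_time(sched), tiny_settings()))
  expect_equal(res$m_final_norm, eu$m, tolerance = 1e-3)
})

test_that("single release reproduces K sqrt(t) within the profile tolerance", {
  mat <- material(D = 1e-10)
  K_norm <- 2 * sqrt(mat$D / pi)
  for (prof in c("ensemble", "survey")) {
    st <- solver_settings(prof)
    res <- released_mass(mat, make_schedule(10800), st, samples_per_phase = 0)
    dev <- 100 * abs(res$m_final_norm - K_norm * sqrt(10800)) /
      (K_norm * sqrt(10800))
    expect_lt(dev, st$eps2)
  }
})

test_that("released mass is monotone, flat in pauses, and conservative", {
  mat <- material(D = 1e-11, b = 2e-4)
  sched <- random_schedule(4, 7200, seed = 3)
  res <- released_mass(mat, sched, solver_settings(N1 = 40), snapshots = TRUE)
  expect_true(all(diff(res$m_ext_norm) > -1e-15))
  # exactly constant across every pause phase
  for (p in which(sched$kind == "P")) {
    vals <- res$m_ext_norm[res$phase_index == p]
    expect_equal(max(vals) - min(vals), 0)
    expect_equal(res$per_phase_release[p], 0)
  }
  expect_lt(res$mass_balance_residual, 1e-8)
  # the slab can never release more than it holds
  expect_lt(res$m_final_norm, mat$b)
  # pause ends are flatter than the preceding release ends
  for (p in which(sched$kind == "P")) {
    spread_R <- diff(range(res$snapshots[[p - 1]]))
    spread_P <- diff(range(res$snapshots[[p]]))
    expect_lt(spread_P, spread_R)
  }
})

test_that("numerical mass is strictly inside the a priori bounds (N = 2)", {
  mat <- material(D = 1e-10)
  sched <- make_schedule(c(600, 600), 600)
  res <- released_mass(mat, sched, solver_settings("ensemble"),
                       samples_per_phase = 0)
  K <- 2 * sqrt(mat$D / pi)
  expect_gt(res$m_final_norm, K * sqrt(2) * sqrt(600))
  expect_lt(res$m_final_norm, K * 2 * sqrt(600))
  expect_gt(res$m_final_norm, K * sqrt(1200))  # beats the no-pause release
})

test_that("convergence criteria pass on a fine grid and fail without buffer", {
  mat <- material(D = 1e-10)
  sched <- random_schedule(10, 10800, seed = 21)
  res <- released_mass(mat, sched, solver_settings("reference"),
                       samples_per_phase = 5)
  conv <- check_convergence(res)
  expect_true(conv$crit1_pass)
  expect_true(conv$crit2_pass)

  # truncating the domain at L_turn makes the wall felt: criterion 1 fails
  res0 <- released_mass(mat, make_schedule(10800),
                        solver_settings(N1 = 50, grid_factor = 1),
                        samples_per_phase = 20)
  conv0 <- check_convergence(res0)
  expect_false(conv0$crit1_pass)

  # finite slab: criteria skipped with an explanatory note
  resf <- released_mass(material(D = 1e-10, b = 1e-4),
                        make_schedule(600), solver_settings(N1 = 20))
  convf <- check_convergence(resf)
  expect_false(convf$applicable)
  expect_match(convf$note, "physical")
})
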