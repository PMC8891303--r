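test_that("release prefactor K = 2 A c0 sqrt(D/pi) and its scaling", {
  expect_equal(release_prefactor(material(D = 1e-10)), 1.12838e-5,
               tolerance = 1e-5)
  expect_equal(release_prefactor(material(D = 1e-13)), 3.56825e-7,
               tolerance = 1e-5)
  # quadrupling D doubles K; A and c0 enter linearly
  expect_equal(release_prefactor(material(D = 4e-10)),
               2 * release_prefactor(material(D = 1e-10)))
  expect_equal(release_prefactor(material(D = 1e-10, A = 3, c0 = 2)),
               6 * release_prefactor(material(D = 1e-10)))
})

test_that("single-release mass follows K sqrt(t)", {
  K <- release_prefactor(material(D = 1e-10))
  expect_equal(single_release_mass(K, 10800), 1.1727e-3, tolerance = 1e-4)
  expect_equal(single_release_mass(K, 0), 0)
  expect_equal(single_release_mass(K, 4 * 567), 2 * single_release_mass(K, 567))
})

test_that("erf profile obeys boundary conditions and mass conservation", {
  D <- 1e-10; t <- 3600
  expect_equal(erf_profile(0, t, D), 0)
  expect_equal(erf_profile(1, t, D), 1, tolerance = 1e-12)
  expect_equal(erf_profile(sqrt(4 * D * t), t, D), 0.84270, tolerance = 1e-5)
  # the depleted mass under the profile equals the single-release K sqrt(t)
  dep <- stats::integrate(function(x) 1 - erf_profile(x, t, D), 0, Inf,
                          rel.tol = 1e-10)$value
  expect_equal(dep, 2 * sqrt(D / pi) * sqrt(t), tolerance = 1e-6)
})

test_that("a priori bounds bracket correctly", {
  K <- release_prefactor(material(D = 1e-13))
  expect_equal(lower_bound_mass(K, 10, 1800), 4.787e-5, tolerance = 1e-3)
  expect_equal(lower_bound_mass(K, 1, 1800), single_release_mass(K, 1800))
  ub <- upper_bound_mass(K, make_schedule(rep(1800, 10), rep(2000, 9)))
  expect_equal(ub$apriori, 1.51388e-4, tolerance = 1e-5)
  expect_equal(ub$schedule, ub$apriori)  # Jensen equality for equal releases
  # unequal releases: schedule-specific bound is strictly tighter
  ub2 <- upper_bound_mass(1, make_schedule(c(100, 400), 50))
  expect_equal(ub2$schedule, 30)
  expect_equal(ub2$apriori, 2 * sqrt(250))
  expect_lt(ub2$schedule, ub2$apriori)
  # lower bound trails the a priori upper bound by exactly sqrt(N)
  expect_equal(lower_bound_mass(K, 10, 1800) * sqrt(10), ub$apriori)
})

test_that("f(z) matches its defining values and is monotone with a hard cut", {
  expect_equal(f_of_z(0), 1)
  expect_equal(round(f_of_z(5 / 4.5), 2), 0.68)
  expect_equal(f_of_z(39.4), 0)
  expect_equal(f_of_z(10), 0.2 + 0.8 / 7, tolerance = 1e-12)  # 0.31429
  expect_equal(f_of_z(10 + 1e-12), 0)
  z <- seq(0, 10, by = 0.01)
  expect_true(all(diff(f_of_z(z)) < 0))
  expect_true(all(f_of_z(z) >= 0 & f_of_z(z) <= 1))
  expect_error(f_of_z(-0.1), ">= 0")
})

test_that("empirical estimator respects its limits and the worked value", {
  K <- release_prefactor(material(D = 1e-13))
  # N = 1 reduces exactly to the single-release solution, z never evaluated
  expect_equal(approx_released_mass(K, 1, 1800, 1800), K * sqrt(1800))
  expect_equal(approx_released_mass(K, 10, 1800, 36000), 6.128e-5,
               tolerance = 1e-3)
  # infinitely long pauses (z > 10, f = 0): estimator hits the a priori bound
  expect_equal(approx_released_mass(K, 10, 60, 1e9), K * 10 * sqrt(60))
  expect_error(approx_released_mass(K, 10, 1800, 1000), "infeasible")
})

test_that("estimator is sandwiched by the a priori bounds", {
  K <- 1
  set.seed(7)
  for (i in 1:200) {
    N <- sample(1:50, 1)
    tau_bar <- stats::runif(1, 1, 5000)
    t_tot <- N * tau_bar * stats::runif(1, 1, 60)
    m_app <- approx_released_mass(K, N, tau_bar, t_tot)
    expect_gte(m_app, lower_bound_mass(K, N, tau_bar) * (1 - 1e-12))
    expect_lte(m_app, K * N * sqrt(tau_bar) * (1 + 1e-12))
    g <- gamma_factor(N, tau_bar, t_tot)
    expect_gte(g, 1 / N - 1e-12)
    expect_lte(g, 1 + 1e-12)
  }
  # all three coincide at N = 1
  expect_equal(lower_bound_mass(K, 1, 900), approx_released_mass(K, 1, 900, 900))
})

test_that("finite-thickness formulas reproduce the worked quantities", {
  expect_equal(sigma_thickness(1e-4, 1e-13, 18000), 1.667, tolerance = 1e-3)
  expect_identical(sigma_thickness(Inf, 1e-13, 18000), Inf)
  expect_identical(sigma_thickness(1e-4, 1e-13, 0), Inf)
  expect_equal(u_of_sigma(0.4), 0.50133, tolerance = 1e-4)
  expect_equal(u_of_sigma(5), 1)
  expect_equal(u_of_sigma(0), 0)
  expect_equal(u_of_sigma(Inf), 1)
  expect_error(u_of_sigma(-1), ">= 0")
  # t* = pi b^2 / (4 D): about 22 h for a 0.1 mm slab at D = 1e-13
  expect_equal(t_star(1e-4, 1e-13) / 3600, 21.817, tolerance = 1e-4)
  expect_equal(t_star(1e-3, 1e-12), 7.854e5, tolerance = 1e-4)
  expect_equal(t_star(0, 1e-13), 0)
  expect_identical(t_star(Inf, 1e-13), Inf)
  # gamma for the three worked schedules
  expect_equal(round(gamma_factor(10, 1800, 36000), 2), 0.61)
  expect_equal(round(gamma_factor(30, 1800, 108000), 2), 0.56)
  expect_equal(gamma_factor(100, 9, 36000), 0.01)  # f(z) = 0 -> 1/N
})

test_that("assess_scenario classifies the three worked scenarios", {
  mat <- material(D = 1e-13, b = 1e-4)
  r1 <- assess_scenario(mat, 10, 1800, 36000)
  expect_identical(r1$classification, "NON_TRIVIAL")
  expect_equal(round(r1$finite_bound_coeff, 2), 0.61)
  r2 <- assess_scenario(mat, 30, 1800, 108000)
  expect_identical(r2$classification, "TRIVIAL")
  expect_equal(round(r2$raw_bound_coeff, 3), 1.106)
  expect_equal(r2$finite_bound_coeff, 1)
  r3 <- assess_scenario(mat, 100, 9, 9000)
  expect_identical(r3$classification, "NON_TRIVIAL")
  expect_equal(round(r3$finite_bound_coeff, 2), 0.27)
  r3b <- assess_scenario(mat, 100, 9, 36000)
  expect_identical(r3b$classification, "TRIVIAL")
  rInf <- assess_scenario(material(D = 1e-13), 10, 1800, 36000)
  expect_identical(rInf$classification, "INFINITE_THICKNESS")
  expect_true(is.na(rInf$finite_bound_coeff))
})

test_that("dimensionless fields are invariant under D->lD, t->t/l, fixed b", {
  # speeding up diffusion while shrinking all times by the same factor
  # leaves sigma, z, f, gamma, the bound coefficient and the
  # classification unchanged
  base <- assess_scenario(material(D = 1e-13, b = 1e-4), 10, 1800, 36000)
  for (l in c(10, 0.3)) {
    sc <- assess_scenario(material(D = 1e-13 * l, b = 1e-4),
                          10, 1800 / l, 36000 / l)
    for (f in c("z", "f_z", "gamma", "sigma", "raw_bound_coeff",
                "finite_bound_coeff")) {
      expect_equal(sc[[f]], base[[f]], tolerance = 1e-12, label = f)
    }
    expect_identical(sc$classification, base$classification)
  }
})
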