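## The closed-form mean-reaction-time solutions are checked against the
## finite-volume boundary-value solver (the module's independent oracle) and
## against their printed asymptotic expansions in the regime where those
## hold; the analytic potency-switch signature is asserted over the full
## diffusivity range.

kcat3 <- convert_catalytic_3d(0.1)
kcat2 <- convert_catalytic_2d((1 / 3) * 1e6)

test_that("equal-measure radius maps squares and cubes to discs and spheres", {
  expect_equal(equal_measure_radius(300, 2), 300 / sqrt(pi))
  expect_equal(equal_measure_radius(300, 3), 300 * (3 / (4 * pi))^(1 / 3))
  expect_equal(equal_measure_radius(600, 2), 2 * equal_measure_radius(300, 2))
  expect_error(equal_measure_radius(-1, 2), "side")
})

test_that("exact disc/sphere solutions agree with the finite-volume oracle", {
  R2 <- equal_measure_radius(300, 2)
  R3 <- equal_measure_radius(300, 3)
  for (Dum in c(1.25e-6, 1.25e-3, 0.1)) {
    for (L in c(1, 8.5, 70)) {
      cal <- calibrate_doi(reach_kernel(L, kcat3))
      p2 <- doi_problem(2, R2, Dum * 1e6, cal$epsilon, cal$lam)
      expect_lt(abs(solve_mrt_numeric(p2)$T_mean / mrt_exact(p2) - 1), 1e-6)
      p3 <- doi_problem(3, R3, Dum * 1e6, cal$epsilon, cal$lam)
      expect_lt(abs(solve_mrt_numeric(p3)$T_mean / mrt_exact(p3) - 1), 2e-6)
    }
  }
})

test_that("numeric profile satisfies the boundary conditions and rho > 1 is uniform", {
  cal <- calibrate_doi(reach_kernel(8.5, kcat3))
  p <- doi_problem(2, equal_measure_radius(300, 2), 1e5, cal$epsilon, cal$lam)
  s <- solve_mrt_numeric(p)
  n <- length(s$r)
  expect_true(all(s$w > 0))
  ## no-flux at R: one-sided slope small relative to the interior scale
  slope_R <- (s$w[n] - s$w[n - 1]) / (s$r[n] - s$r[n - 1])
  slope_mid <- max(abs(diff(s$w) / diff(s$r)))
  expect_lt(abs(slope_R), 1e-3 * slope_mid)
  ## reaction zone covering the domain: w = 1/lambda everywhere
  p_big <- doi_problem(2, 50, 1e5, 60, 2.5)
  expect_equal(mrt_exact(p_big), 1 / 2.5)
  s_big <- solve_mrt_numeric(p_big)
  expect_lt(max(abs(s_big$w - 1 / 2.5)) / (1 / 2.5), 1e-8)
})

test_that("well-mixed MRT is monotone decreasing in D and lambda", {
  R2 <- equal_measure_radius(300, 2)
  cal <- calibrate_doi(reach_kernel(8.5, kcat3))
  Ts_D <- sapply(10^seq(0, 5, 1), function(Dnm)
    mrt_exact(doi_problem(2, R2, Dnm, cal$epsilon, cal$lam)))
  expect_true(all(diff(Ts_D) < 0))
  Ts_lam <- sapply(10^seq(-2, 4, 1), function(lam)
    mrt_exact(doi_problem(2, R2, 1e4, cal$epsilon, lam)))
  expect_true(all(diff(Ts_lam) < 0))
})

test_that("asymptotic expansions match the exact solution in their validity regime", {
  ## the printed expansions assume the reaction-influenced regime
  ## (Rhat * rho small); at fast diffusion and small rho they agree closely
  for (model in c("2.5D", "2D", "3D")) {
    kc <- if (model == "2D") kcat2 else kcat3
    for (L in c(1, 2, 4)) {
      ex <- mrt_wellmixed(model, kc, L, D = 0.1, method = "exact")
      as <- mrt_wellmixed(model, kc, L, D = 0.1, method = "asymptotic")
      expect_lt(abs(as$T / ex$T - 1), 0.02)
      expect_true(as$valid)
    }
  }
  ## validity flag trips for large rho
  expect_false(mrt_wellmixed("2.5D", kcat3, 50, 0.1,
                             method = "asymptotic")$valid)
})

test_that("reaction-/diffusion-limited decomposition identities hold", {
  R2 <- equal_measure_radius(300, 2)
  R3 <- equal_measure_radius(300, 3)
  for (L in c(1, 8.5, 70)) {
    d25 <- mrt_decompose("2.5D", kcat3, L, 1e5, R2)
    ## planar integral of the 3D kernel: k_RL = kcat sqrt(3/(2 pi))/L,
    ## checked against quadrature
    k_RL_quad <- kcat3 * integrate(function(r) sigma3d(r, L) * 2 * pi * r,
                                   0, Inf, rel.tol = 1e-12)$value
    expect_lt(abs(d25$k_RL / k_RL_quad - 1), 1e-10)
    ## (32/(9 pi)) T_RL equals the leading asymptotic reaction term
    expect_lt(abs((32 / (9 * pi)) * d25$T_RL /
                    ((4 / 3) * pi * R2^2 * doi_alpha() * L / kcat3) - 1), 1e-10)
    ## reconstruction reproduces the asymptotic expansion
    expect_equal(d25$T_reconstructed,
                 mrt_asymptotic("2.5D", kcat3, L, 1e5, R2)$T)
    d3 <- mrt_decompose("3D", kcat3, L, 1e5, R3)
    expect_lt(abs((6 / 5) * d3$T_DL /
                    (2 * R3^3 / (5 * 1e5 * doi_alpha() * L)) - 1), 1e-12)
    expect_equal(d3$T_reconstructed,
                 mrt_asymptotic("3D", kcat3, L, 1e5, R3)$T)
    d2 <- mrt_decompose("2D", kcat2, L, 1e5, R2)
    expect_equal(d2$T_RL, pi * R2^2 / kcat2)  # independent of L
    expect_equal(d2$T_reconstructed,
                 mrt_asymptotic("2D", kcat2, L, 1e5, R2)$T)
  }
  ## T_RL in 2.5D is proportional to L; in 2D and 3D it is L-independent
  T_RL_25 <- sapply(c(1, 10, 70), function(L)
    mrt_decompose("2.5D", kcat3, L, 1e5, R2)$T_RL)
  expect_equal(T_RL_25 / c(1, 10, 70), rep(T_RL_25[1], 3))
})

test_that("large-reach branch is continuous at the domain-covering point", {
  ## when alpha L exceeds R the mean reaction time is 1/lambda =
  ## (4/3) pi (alpha L)^3 / kcat; approaching from below, the exact branch
  ## tends to the same value at fast diffusion
  R2 <- equal_measure_radius(300, 2)
  L_star <- R2 / doi_alpha()
  above <- mrt_wellmixed("2.5D", kcat3, L_star * 1.001, D = 1)
  expect_equal(above$T, (4 / 3) * pi * (doi_alpha() * L_star * 1.001)^3 / kcat3)
  below <- mrt_wellmixed("2.5D", kcat3, L_star * 0.999, D = 1)
  expect_lt(abs(below$T / above$T - 1), 0.05)
})

test_that("analytic switch: reach helps at slow diffusion only in the 2.5D model", {
  Ds <- c(1.25e-6, 1.25e-5, 1.25e-4, 1.25e-3, 1.25e-2, 0.1)
  Ls <- c(1, 2, 5, 8.5, 20, 70)
  ## 2.5D: ordering of T(L=70) vs T(L=1) inverts across the D range
  expect_lt(mrt_wellmixed("2.5D", kcat3, 70, 1.25e-6)$T,
            mrt_wellmixed("2.5D", kcat3, 1, 1.25e-6)$T)
  expect_gt(mrt_wellmixed("2.5D", kcat3, 70, 0.1)$T,
            mrt_wellmixed("2.5D", kcat3, 1, 0.1)$T)
  ## 2D and 3D: T never increases with L at any of the six diffusivities
  for (model in c("2D", "3D")) {
    kc <- if (model == "2D") kcat2 else kcat3
    for (Dum in Ds) {
      Ts <- sapply(Ls, function(L) mrt_wellmixed(model, kc, L, Dum)$T)
      expect_true(all(diff(Ts) <= 1e-9 * Ts[-1]))
    }
  }
  ## the switch direction is preserved when the domain is halved
  expect_lt(mrt_wellmixed("2.5D", kcat3, 40, 1.25e-6, side = 150)$T,
            mrt_wellmixed("2.5D", kcat3, 1, 1.25e-6, side = 150)$T)
  expect_gt(mrt_wellmixed("2.5D", kcat3, 40, 0.1, side = 150)$T,
            mrt_wellmixed("2.5D", kcat3, 1, 0.1, side = 150)$T)
})
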