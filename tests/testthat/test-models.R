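test_that("model constructors apply the published parameter-table defaults", {
  m <- pd1_model(pd1 = 5e-4)
  sp <- m$network$species
  names(sp) <- m$network$species_names
  expect_equal(sp$CD28$concentration, 1e-4)
  expect_equal(m$args$lambda, 1.0)
  expect_equal(m$args$kcat, 0.1)
  expect_equal(m$domain$side, 300)
  expect_equal(m$domain$boundary, "periodic")
  expect_equal(m$network$unimolecular[[1]]$rate, 1.0)

  pp <- pushpull_model(E = 500)
  spp <- pp$network$species
  names(spp) <- pp$network$species_names
  expect_equal(spp$S$concentration, 100e-6)
  expect_equal(spp$F$concentration, 112e-6)
  expect_equal(spp$F$diffusivity, 6.25e-4)
  expect_equal(pp$kernel_f$reach, 15)
  expect_equal(pp$args$kcat_e, 0.04)
  expect_equal(pp$args$kcat_f, 0.01)
  ## idealized 2D variant picks up the published converted area-rates
  pp2 <- pushpull_model(E = 500, kernel_dim = 2)
  expect_equal(round(pp2$kernel$catalytic_efficiency, 4), 221.3736)
  expect_equal(round(pp2$kernel_f$catalytic_efficiency, 4), 55.3434)
})

test_that("degenerate limits pin the steady-state fraction", {
  ## no phosphatase activity: everything ends up modified
  m1 <- pd1_model(pd1 = 0, D = 0.1, voxels_per_axis = 32)
  s1 <- steady_state_fraction(m1, n_trajectories = 20, base_seed = 1)
  expect_equal(s1$fraction, 1)
  ## no kinase activity: nothing gets modified
  m2 <- pd1_model(pd1 = 5e-4, lambda = 0, D = 0.1, voxels_per_axis = 32)
  s2 <- steady_state_fraction(m2, n_trajectories = 20, base_seed = 1)
  expect_equal(s2$fraction, 0)
  ## push-pull: no kinase -> 0; no phosphatase -> 1
  s3 <- steady_state_fraction(pushpull_model(E = 0, voxels_per_axis = 32),
                              n_trajectories = 20, base_seed = 1)
  expect_equal(s3$fraction, 0)
  s4 <- steady_state_fraction(pushpull_model(E = 500, F = 0, voxels_per_axis = 32),
                              n_trajectories = 20, base_seed = 1)
  expect_equal(s4$fraction, 1)
})

test_that("steady-state policy: warm start at fast diffusion, cold when quenched", {
  fast <- steady_state_fraction(pd1_model(pd1 = 5e-4, D = 0.1,
                                          voxels_per_axis = 32),
                                n_trajectories = 5, base_seed = 1)
  expect_true(fast$policy$warm_start)
  slow <- steady_state_fraction(pd1_model(pd1 = 5e-4, D = 1.25e-6,
                                          voxels_per_axis = 32),
                                n_trajectories = 5, base_seed = 1, t_floor = 20)
  expect_false(slow$policy$warm_start)
})

test_that("fast-diffusion steady state approaches the mean-field balance", {
  ## well-mixed control: fraction ~ lambda/(lambda + k_RL [PD-1]) when
  ## diffusion is fast; allow a modest spatial-correlation margin
  m <- pd1_model(pd1 = 5.56e-4, D = 0.1, L = 8.5, voxels_per_axis = 64)
  ss <- steady_state_fraction(m, n_trajectories = 150, base_seed = 3)
  k_RL <- convert_catalytic_3d(0.1) * sqrt(3 / (2 * pi)) / 8.5
  p_mf <- 1 / (1 + k_RL * 50 / 300^2)
  expect_lt(abs(ss$fraction - p_mf), 0.1 * p_mf + 3 * ss$se)
  expect_true(ss$converged)
  ## doubling the burn-in does not move the answer (policy robustness)
  ss2 <- steady_state_fraction(m, n_trajectories = 150, base_seed = 3,
                               burn = 3)
  expect_lt(abs(ss2$fraction - ss$fraction),
            3 * sqrt(ss$se^2 + ss2$se^2) + 0.01)
})

test_that("PD-1 potency: fraction decreases with [PD-1] under common random numbers", {
  fr <- sapply(c(1e-4, 5e-4, 2.5e-3), function(conc) {
    steady_state_fraction(pd1_model(pd1 = conc, D = 0.1, voxels_per_axis = 32),
                          n_trajectories = 40, base_seed = 17)$fraction
  })
  expect_true(all(diff(fr) < 0))
})

test_that("refinement stability: doubling the mesh leaves the fraction unchanged", {
  ## resolved kernel (L = 15 nm): halving h changes the steady state by
  ## less than the ensemble error (convergence to the volume-reactivity
  ## model)
  f <- lapply(c(32, 64), function(nv) {
    steady_state_fraction(pushpull_model(E = 556, D_S = 0.1, D_E = 0.1,
                                         L_e = 15, voxels_per_axis = nv),
                          n_trajectories = 80, base_seed = 5)
  })
  expect_lt(abs(f[[1]]$fraction - f[[2]]$fraction),
            3 * sqrt(f[[1]]$se^2 + f[[2]]$se^2) + 0.01)
})

test_that("half-maximal extraction: exact on clean curves, symmetric for activators", {
  c0 <- 10
  conc <- 10^seq(log10(c0 / 30), log10(c0 * 30), length.out = 9)
  dec <- extract_ic50(conc, 1 / (1 + conc / c0))
  expect_equal(dec$direction, "decreasing")
  expect_lt(abs(dec$ic50 / c0 - 1), 0.02)
  inc <- extract_ic50(conc, 1 - 1 / (1 + conc / c0))
  expect_equal(inc$direction, "increasing")
  expect_lt(abs(inc$ic50 / c0 - 1), 0.02)
  ## Hill cross-check agrees on clean data
  expect_lt(abs(dec$hill / c0 - 1), 0.02)
  ## curve that never crosses the level: NA with a bracketing bound
  flat <- extract_ic50(conc, 0.9 - 0.001 * seq_along(conc), level = 0.5)
  expect_true(is.na(flat$ic50))
  expect_false(is.null(flat$bracket))
  expect_error(extract_ic50(conc[1:3], c(1, 0.5, 0)), "at least 4")
})

test_that("dose-response sweep recovers a finite potency on a micro model", {
  m <- pd1_model(pd1 = 1e-4, D = 0.1, voxels_per_axis = 32)
  sweep <- 10^seq(-4.6, -2.6, length.out = 5)
  ## lowest grid point rounds 2.26 -> 2 molecules; the rounding notice is
  ## asserted elsewhere
  dr <- suppressWarnings(dose_response(m, sweep, n_trajectories = 40, base_seed = 2))
  expect_true(is.finite(dr$ic50$ic50))
  expect_equal(dr$ic50$direction, "decreasing")
  expect_true(dr$monotone)
  ## mean-field scale of the potency: lambda / k_RL as an area density
  k_RL <- convert_catalytic_3d(0.1) * sqrt(3 / (2 * pi)) / 8.5
  ic_mf <- 1 / k_RL
  expect_gt(dr$ic50$ic50, ic_mf / 4)
  expect_lt(dr$ic50$ic50, ic_mf * 4)
  ## tidy serialization round-trips exactly
  path <- tempfile(fileext = ".csv")
  write_results(dr, path)
  back <- utils::read.csv(path)
  expect_identical(back$value[back$statistic == "fraction"],
                   unname(dr$fraction))
})

test_that("potency surface collects half-maximal concentrations over a grid", {
  m <- pd1_model(pd1 = 1e-4, D = 0.1, voxels_per_axis = 32)
  sweep <- 10^seq(-4.6, -2.6, length.out = 4)
  ps <- suppressWarnings(potency_surface(m, reach_grid = c(8.5, 40),
                                         diffusivity_grid = 0.1, sweep = sweep,
                                         n_trajectories = 15, base_seed = 4))
  expect_equal(dim(ps$ic50), c(2, 1))
  expect_true(all(is.finite(ps$ic50)))
  ## fast diffusion, 3D kernel: potency worsens (IC50 grows) with reach
  expect_gt(ps$ic50[2, 1], ps$ic50[1, 1])
})
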