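test_that("static tethered pair reacts with the exact exponential clock", {
  fx <- generate_fixture("static-pair", seed = 1)
  set.seed(42)
  ts <- replicate(1500, simulate_world(fx$world, t_end = Inf,
                                       stop_on_first_pair = TRUE)$stop_time)
  ## mean within 3 standard errors of 1/(kcat sigma(r))
  se <- sd(ts) / sqrt(length(ts))
  expect_lt(abs(mean(ts) - fx$expected$mean_time), 3 * se)
  ## exponential shape: sd ~ mean
  expect_lt(abs(sd(ts) / mean(ts) - 1), 0.1)
})

test_that("first-order reactions follow their exponential kinetics", {
  dom <- lattice_domain(2, 300, 32)
  lam <- 2
  net <- reaction_network(list(species_def("C", 0, 0), species_def("Cp", 0, 0)),
                          unimolecular = list(unimolecular_rule("C", "Cp", lam)))
  set.seed(3)
  t_obs <- 0.4
  n0 <- 6
  left <- replicate(400, {
    w <- build_world(dom, net, counts = c(C = n0, Cp = 0))
    simulate_world(w, t_end = t_obs, sample_times = t_obs)$counts["C", 1]
  })
  expected <- n0 * exp(-lam * t_obs)
  se <- sd(left) / sqrt(length(left))
  expect_lt(abs(mean(left) - expected), 3 * se)
})

test_that("modification cycles conserve molecule totals along trajectories", {
  fx <- generate_fixture("pushpull-micro", seed = 2)
  m <- fx$model
  set.seed(7)
  w <- build_world(m$domain, m$network)
  tr <- simulate_world(w, t_end = 3, sample_times = seq(0.1, 3, by = 0.1))
  tot_S <- colSums(tr$counts[c("S", "Sp"), , drop = FALSE])
  expect_true(all(tot_S == tot_S[1]))
  expect_true(all(tr$counts["E", ] == tr$counts["E", 1]))
  expect_true(all(tr$counts["F", ] == tr$counts["F", 1]))
  expect_true(all(tr$counts >= 0))
  expect_gt(sum(tr$pair_events), 0)
})

test_that("simulation is reproducible bit-for-bit under a fixed seed", {
  fx <- generate_fixture("pushpull-micro", seed = 1)
  m <- fx$model
  run <- function() {
    set.seed(11)
    w <- build_world(m$domain, m$network)
    simulate_world(w, t_end = 1, sample_times = c(0.5, 1), avg_start = 0.5)
  }
  a <- run(); b <- run()
  expect_identical(a$counts, b$counts)
  expect_identical(a$avg, b$avg)
  expect_identical(a$events, b$events)
  ## ensembles: identical base seed, identical summary
  e1 <- run_ensemble(m$domain, m$network, t_end = 0.5, n_trajectories = 5,
                     base_seed = 9, avg_start = 0.25)
  e2 <- run_ensemble(m$domain, m$network, t_end = 0.5, n_trajectories = 5,
                     base_seed = 9, avg_start = 0.25)
  expect_identical(e1$avg, e2$avg)
})

test_that("time-averaged counts match the analytic relaxation average", {
  ## C -> Cp at rate lam from n0 copies: E[C](t) = n0 exp(-lam t), so the
  ## window average over [a, b] is n0 (exp(-lam a) - exp(-lam b))/(lam (b-a))
  dom <- lattice_domain(2, 300, 32)
  lam <- 1.5; n0 <- 8; a <- 0.2; b <- 1.2
  net <- reaction_network(list(species_def("C", 0, 0), species_def("Cp", 0, 0)),
                          unimolecular = list(unimolecular_rule("C", "Cp", lam)))
  set.seed(5)
  avgs <- replicate(300, {
    w <- build_world(dom, net, counts = c(C = n0, Cp = 0))
    simulate_world(w, t_end = b, avg_start = a)$avg["C"]
  })
  expected <- n0 * (exp(-lam * a) - exp(-lam * b)) / (lam * (b - a))
  se <- sd(avgs) / sqrt(length(avgs))
  expect_lt(abs(mean(avgs) - expected), 3 * se)
})

test_that("free diffusion: mean-squared displacement grows as 2 d D t", {
  dom <- lattice_domain(2, 3000, 256)  # large box so wrapping is irrelevant
  Dum <- 0.1
  net <- reaction_network(list(species_def("A", Dum, 0)))
  times <- c(0.5, 1, 2)
  set.seed(8)
  disp2 <- matrix(0, 150, length(times))
  for (k in 1:150) {
    w <- build_world(dom, net, counts = c(A = 1))
    tr <- simulate_world(w, t_end = max(times), sample_times = times,
                         track_molecule = 1)
    disp <- sweep(tr$track, 2, w$pos[1, ]) * dom$spacing
    disp2[k, ] <- rowSums(disp^2)
  }
  msd <- colMeans(disp2)
  expected <- 4 * Dum * 1e6 * times
  ## chi-squared-ish spread: SE of MSD ~ sqrt(2/n) * MSD
  for (j in seq_along(times)) {
    expect_lt(abs(msd[j] / expected[j] - 1), 3 * sqrt(2 / 150))
  }
})

test_that("3D cubic domains: conservation and agreement with the sphere theory", {
  m <- pd1_model(pd1 = 2e-6, cd28 = 1e-6, D = 0.1, L = 8.5, dimension = 3,
                 voxels_per_axis = 32)
  set.seed(1)
  w <- build_world(m$domain, m$network)
  tr <- simulate_world(w, t_end = 1, sample_times = c(0.5, 1))
  expect_true(all(colSums(tr$counts[c("CD28", "CD28p"), ]) ==
                    sum(tr$counts[c("CD28", "CD28p"), 1])))
  ## fixed + diffusing pair in a reflecting cube vs the equal-volume sphere
  kcat3 <- convert_catalytic_3d(0.1)
  cal <- calibrate_doi(reach_kernel(20, kcat3))
  dom <- lattice_domain(3, 300, 64, boundary = "reflecting")
  net <- reaction_network(
    list(species_def("A", 0, 0), species_def("B", 0.1, 0),
         species_def("X", 0, 0)),
    pairwise = list(pairwise_rule("A", "B", "A", "X", cal)))
  ts <- vapply(1:120, function(k) {
    set.seed(900 + k)
    w2 <- build_world(dom, net, counts = c(A = 1, B = 1, X = 0),
                      positions = list(A = matrix(c(32, 32, 32), 1)))
    simulate_world(w2, t_end = Inf, stop_on_first_pair = TRUE)$stop_time
  }, numeric(1))
  T_th <- mrt_wellmixed("3D", kcat3, 20, 0.1)$T
  expect_lt(abs(mean(ts) - T_th), 3 * sd(ts) / sqrt(120))
})

test_that("immobile, ruleless worlds terminate cleanly as stalled", {
  dom <- lattice_domain(2, 300, 16)
  net <- reaction_network(list(species_def("A", 0, 0)))
  w <- build_world(dom, net, seed = 1, counts = c(A = 3))
  tr <- simulate_world(w, t_end = 5, sample_times = c(1, 5))
  expect_equal(tr$status, "stalled")
  expect_equal(tr$t_final, 5)
  expect_true(all(tr$counts["A", ] == 3))
})

test_that("reflecting boundaries confine molecules; periodic boundaries wrap", {
  net <- reaction_network(list(species_def("A", 1, 0)))
  for (bc in c("reflecting", "periodic")) {
    dom <- lattice_domain(2, 300, 8, boundary = bc)
    set.seed(2)
    w <- build_world(dom, net, counts = c(A = 2))
    tr <- simulate_world(w, t_end = 0.5)
    expect_true(all(tr$final_pos >= 0 & tr$final_pos <= 7))
  }
})
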