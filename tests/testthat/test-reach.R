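test_that("worm-like chain arithmetic reproduces receptor tail reaches", {
  expect_equal(contour_length(11, 0.4), 4.4)
  expect_equal(contour_length(0, 0.4), 0)
  expect_equal(contour_length(56, 0.4), 22.4)
  expect_error(contour_length(-1), "residue_count")

  expect_equal(round(wlc_reach(0.4, 4.4), 1), 1.3)   # CD28 tail
  expect_equal(round(wlc_reach(0.4, 22.4), 1), 3.0)  # PD-1 tail
  expect_equal(wlc_reach(0, 5), 0)
  expect_error(wlc_reach(-0.1, 1), ">= 0")

  comp <- wlc_component(11)
  expect_equal(comp$contour_length, 4.4)
  expect_equal(round(comp$reach, 1), 1.3)
})

test_that("component reaches combine in quadrature", {
  expect_equal(round(combined_reach(c(3.0, 7.9, 1.3)), 1), 8.5)
  expect_equal(combined_reach(c(3, 4)), 5)
  expect_equal(combined_reach(7.7), 7.7)
  expect_error(combined_reach(numeric(0)), "non-empty")
  ## permutation invariance and dominance over the largest component
  set.seed(1)
  for (i in 1:20) {
    v <- runif(sample(2:5, 1), 0, 20)
    expect_equal(combined_reach(v), combined_reach(sample(v)))
    expect_gte(combined_reach(v), max(v))
  }
  ## accepts wlc_component lists
  expect_equal(combined_reach(list(wlc_component(11), 7.9, wlc_component(56))),
               combined_reach(c(wlc_component(11)$reach, 7.9,
                                wlc_component(56)$reach)))
})

test_that("Gaussian kernels are normalized and monotone over the reach range", {
  for (L in c(0.5, 1, 8.5, 70, 100)) {
    i3 <- integrate(function(r) sigma3d(r, L) * 4 * pi * r^2, 0, Inf,
                    rel.tol = 1e-10)
    expect_lt(abs(i3$value - 1), 1e-8)
    i2 <- integrate(function(r) sigma2d(r, L) * 2 * pi * r, 0, Inf,
                    rel.tol = 1e-10)
    expect_lt(abs(i2$value - 1), 1e-8)
    r <- seq(0, 5 * L, length.out = 100)
    expect_true(all(diff(sigma3d(r, L)) <= 0))
    expect_true(all(diff(sigma2d(r, L)) <= 0))
  }
  expect_equal(sigma3d(0, 2), (3 / (2 * pi * 4))^1.5)
  expect_equal(sigma2d(0, 2), 3 / (2 * pi * 4))
  expect_equal(sigma3d(3, 3) / sigma3d(0, 3), exp(-1.5))
  expect_equal(sigma2d(3, 3) / sigma2d(0, 3), exp(-1.5))
  expect_error(sigma3d(1, 0), "L must be")
})

test_that("catalytic efficiency conversions use the documented Avogadro convention", {
  expect_equal(convert_catalytic_3d(0.1), 1e29 / 6.023e23)
  expect_equal(convert_catalytic_3d(0), 0)
  ## 2D rates are the 3D conversion divided by one metre in nm
  ks <- c(0.02, 1, 37.5)
  expect_equal(convert_catalytic_2d(ks) / convert_catalytic_3d(ks),
               rep(1e-9, 3))
  expect_error(convert_catalytic_3d(1, avogadro = 0), "avogadro")
})

test_that("Doi calibration matches kernel moments and scales with reach", {
  k3 <- reach_kernel(8.5, convert_catalytic_3d(0.1), dimension = 3)
  cal3 <- calibrate_doi(k3)
  ## volume condition is exact by construction
  expect_equal(cal3$lam * (4 / 3) * pi * cal3$epsilon^3,
               k3$catalytic_efficiency)
  k2 <- reach_kernel(8.5, convert_catalytic_2d((4 / 3) * 1e5), dimension = 2)
  cal2 <- calibrate_doi(k2)
  expect_equal(cal2$lam * pi * cal2$epsilon^2, k2$catalytic_efficiency)
  ## exact scaling: epsilon ~ L, lambda ~ L^-3 (3D) or L^-2 (2D)
  for (cfac in c(0.3, 2, 11)) {
    c3b <- calibrate_doi(reach_kernel(8.5 * cfac, k3$catalytic_efficiency))
    expect_equal(c3b$epsilon, cal3$epsilon * cfac)
    expect_equal(c3b$lam, cal3$lam / cfac^3)
    c2b <- calibrate_doi(reach_kernel(8.5 * cfac, k2$catalytic_efficiency,
                                      dimension = 2))
    expect_equal(c2b$epsilon, cal2$epsilon * cfac)
    expect_equal(c2b$lam, cal2$lam / cfac^2)
  }
})

test_that("kernel propensity dispatches over Gaussian and indicator kernels", {
  k <- reach_kernel(8.5, convert_catalytic_3d(0.1))
  expect_equal(kernel_propensity(k, 0),
               convert_catalytic_3d(0.1) * sigma3d(0, 8.5))
  ## the published contact propensity for the PD-1 reaction parameters
  expect_equal(round(kernel_propensity(k, 0)), 89)
  cal <- calibrate_doi(k)
  expect_equal(kernel_propensity(cal, cal$epsilon * 0.99), cal$lam)
  expect_equal(kernel_propensity(cal, cal$epsilon * 1.01), 0)
})
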