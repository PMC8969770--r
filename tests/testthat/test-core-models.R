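# Core equations: coherent field, depletion-corrected Langmuir coverage,
# observation model, exponential decay, thermodynamics.

test_that("coherent field is the population difference times E^2, sign preserved", {
  expect_equal(coherent_field(interface_populations(5, 5, 1)), 0)
  expect_equal(coherent_field(interface_populations(3, 0, 2)), 12)
  expect_equal(coherent_field(interface_populations(2, 3, 1)), -1)
  # antisymmetry under swapping leaflets
  for (case in list(c(2, 7), c(0.3, 0.1), c(4, 4))) {
    expect_equal(coherent_field(interface_populations(case[1], case[2], 1.3)),
                 -coherent_field(interface_populations(case[2], case[1], 1.3)))
  }
  expect_error(interface_populations(NaN, 1, 1), "finite")
  expect_error(interface_populations(-1, 1, 1), ">= 0")
})

test_that("detected intensity is the square of the field", {
  expect_equal(shg_intensity(0), 0)
  expect_equal(shg_intensity(-4), 16)
  expect_equal(shg_intensity(3), 9)
  expect_error(shg_intensity(Inf), "finite")
})

test_that("coverage solver handles the trivial and saturating limits", {
  expect_equal(langmuir_coverage(0, 2.9, 5e7)$N_adsorbed, 0)
  # infinite-affinity limit saturates all sites
  expect_equal(langmuir_coverage(10, 2.9, 1e15)$N_adsorbed, 2.9,
               tolerance = 1e-6)
  expect_error(langmuir_coverage(-1, 2.9, 5e7), ">= 0")
  expect_error(langmuir_coverage(1, -2.9, 5e7), "> 0")
})

test_that("closed-form coverage matches the frozen bisection oracle value", {
  # frozen from langmuir_coverage_oracle(6, 2.9, 5e7, tol = 1e-13)
  expect_equal(langmuir_coverage(6, 2.9, 5e7)$N_adsorbed, 2.23913214343,
               tolerance = 1e-9)
  expect_equal(langmuir_coverage_oracle(0, 2.9, 5e7), 0)
  N <- langmuir_coverage_oracle(1, 3.6, 9e7)
  expect_lt(N, 1)
  expect_gt(N, 0)
})

test_that("coverage solver and bisection oracle agree on random inputs", {
  set.seed(11)
  for (i in 1:1000) {
    C <- runif(1, 0, 20); Nmax <- runif(1, 0.5, 10)
    K <- 10^runif(1, 5, 10)
    closed <- langmuir_coverage(C, Nmax, K)$N_adsorbed
    expect_lt(abs(closed - langmuir_coverage_oracle(C, Nmax, K, tol = 1e-12)),
              1e-9 * Nmax)
    # equilibrium relation residual
    W <- shg_constants$water_uM
    expect_lt(abs(closed * W - K * (C - closed) * (Nmax - closed)),
              1e-9 * max(1, K * C * Nmax))
  }
})

test_that("coverage is bounded, mass-balanced, and strictly monotone", {
  Cs <- seq(0.1, 15, length.out = 40)
  for (K in c(1e6, 5e7, 1e9)) {
    cov <- langmuir_coverage(Cs, 2.9, K)
    expect_true(all(cov$N_adsorbed >= 0))
    expect_true(all(cov$N_adsorbed <= pmin(Cs, 2.9)))
    expect_true(all(abs(cov$N_adsorbed + cov$M_free - Cs) <= 1e-9 * Cs))
    expect_true(all(diff(cov$N_adsorbed) > 0))         # increasing in C
  }
  Ks <- 10^seq(5, 10, length.out = 30)
  expect_true(all(diff(vapply(Ks, function(K)
    langmuir_coverage(4, 2.9, K)$N_adsorbed, numeric(1))) > 0))
  Ns <- seq(0.5, 10, length.out = 30)
  expect_true(all(diff(vapply(Ns, function(Nm)
    langmuir_coverage(4, Nm, 5e7)$N_adsorbed, numeric(1))) > 0))
})

test_that("dilute limit reduces to the unmodified Langmuir slope", {
  # K*C/W = 1e-4, C << Nmax, depletion fraction Nmax*K/W = 1e-3
  W <- shg_constants$water_uM
  C <- 1e-4; Nmax <- 1e-3; K <- 1e-4 * W / C
  N <- langmuir_coverage(C, Nmax, K)$N_adsorbed
  expect_equal(N / (Nmax * K * C / W), 1, tolerance = 0.01)
})

test_that("observation model has the right baseline, limits, and composition", {
  p <- langmuir_params(A = 174, Nmax = 2.9, K = 5e7, alpha = 3, B = 7)
  expect_equal(isotherm_intensity(0, p), 7)
  # coherent term approaches A at saturation
  p0 <- langmuir_params(A = 174, Nmax = 2.9, K = 5e7, alpha = 0, B = 0)
  expect_equal(isotherm_intensity(1e6, p0), 174, tolerance = 1e-3)
  # frozen composition with the oracle coverage at C = 6
  expect_equal(isotherm_intensity(6, p0), 103.73198805, tolerance = 1e-8)
  # non-decreasing in C
  I <- isotherm_intensity(seq(0, 20, length.out = 50), p)
  expect_true(all(diff(I) > -1e-12))
  # hrs_mode = "total" adds alpha * N more than "free"
  N6 <- langmuir_coverage(6, 2.9, 5e7)$N_adsorbed
  expect_equal(isotherm_intensity(6, p, hrs_mode = "total") -
                 isotherm_intensity(6, p, hrs_mode = "free"), 3 * N6)
})

test_that("field decay has the stated endpoints and errors", {
  expect_equal(field_decay(0, 2, 3, 100), 5)
  expect_equal(field_decay(1e9, 2, 3, 100), 2)
  expect_equal(field_decay(50, 0, 1, 50), exp(-1))
  expect_error(field_decay(1, 2, 3, -1), "tau")
  ts <- seq(0, 500, by = 10)
  expect_true(all(diff(field_decay(ts, 2, 3, 100)) < 0))
})

test_that("free energy is -RT ln K and scales as the identity demands", {
  expect_equal(adsorption_free_energy(1, 293)$delta_g, 0)
  # strictly decreasing in K at fixed T
  dgs <- vapply(10^seq(2, 10, 1), function(K)
    adsorption_free_energy(K, 293)$delta_g, numeric(1))
  expect_true(all(diff(dgs) < 0))
  # delta_g / T independent of T at fixed K
  r1 <- adsorption_free_energy(5e7, 280)
  r2 <- adsorption_free_energy(5e7, 320)
  expect_equal(r1$delta_g / r1$T, r2$delta_g / r2$T)
  expect_error(adsorption_free_energy(0, 293), "> 0")
})

test_that("derived coverage ratios compute and guard their domains", {
  expect_equal(lipids_per_site(10, 10), 1)
  expect_equal(signal_per_coverage(100, 10), 1)
  expect_error(lipids_per_site(75, 0), "> 0")
  expect_error(signal_per_coverage(100, 0), "> 0")
})
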