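# Field-domain transport kinetics: intensity/field transform, exponential
# fitting, time-zero extrapolation, transport tables.

test_that("intensity-to-field transform is sqrt with defined clamping", {
  tr <- shg_trace(0:3, c(0, 1, 4, 9), C_total = 1, sample = shg_sample(75))
  fd <- intensity_to_field(tr)
  expect_equal(fd$field, c(0, 1, 2, 3))
  expect_equal(fd$n_clamped, 0)

  tr2 <- shg_trace(1:6, c(-0.5, 1, 1, 1, 1, 1), C_total = 1,
                   sample = shg_sample(75))
  fd2 <- intensity_to_field(tr2)
  expect_equal(fd2$field[1], 0)
  expect_equal(fd2$n_clamped, 1)

  # exact inverse of squaring on a model trace
  tr3 <- decay_trace(A0 = 5, A1 = 10, tau = 300)
  fd3 <- intensity_to_field(tr3)
  expect_equal(fd3$field, 5 + 10 * exp(-tr3$time / 300))
})

test_that("noiseless transport fits are exact round trips across tau scales", {
  for (tau in c(10, 300, 1e4)) {
    tr <- decay_trace(A0 = 5, A1 = 10, tau = tau,
                      t = seq(0, 5 * tau, length.out = 200))
    fit <- fit_transport(tr)
    expect_equal(fit$A0, 5, tolerance = 1e-6)
    expect_equal(fit$A1, 10, tolerance = 1e-6)
    expect_equal(fit$tau, tau, tolerance = 1e-6)
    expect_false(fit$unresolved)
  }
})

test_that("transport fit is scale-equivariant and time-shift consistent", {
  tr <- decay_trace(A0 = 5, A1 = 10, tau = 300)
  base <- fit_transport(tr)
  # intensities * c^2 -> fields * c, tau unchanged
  c2 <- 5.7
  tr2 <- shg_trace(tr$time, tr$intensity * c2^2, tr$C_total, tr$sample)
  fit2 <- fit_transport(tr2)
  expect_equal(fit2$A0, c2 * base$A0, tolerance = 1e-8)
  expect_equal(fit2$A1, c2 * base$A1, tolerance = 1e-8)
  expect_equal(fit2$tau, base$tau, tolerance = 1e-8)

  # dropping the first k points barely moves tau on noiseless data
  k <- 10
  tr3 <- shg_trace(tr$time[-(1:k)], tr$intensity[-(1:k)], tr$C_total, tr$sample)
  fit3 <- fit_transport(tr3)
  expect_lt(abs(fit3$tau - base$tau), max(base$stderr[3], 1e-4))
})

test_that("degenerate traces are handled as defined", {
  flat <- shg_trace(seq(0, 100, 10), rep(25, 11), C_total = 1,
                    sample = shg_sample(75))
  fit <- fit_transport(flat)
  expect_equal(fit$A1, 0)
  expect_true(fit$unresolved)
  expect_error(fit_transport(shg_trace(1:5, (1:5)^2, 1, shg_sample(75))),
               ">= 6 points")
})

test_that("time-zero intensity extrapolates (A0+A1)^2 plus background", {
  mk <- function(A0, A1, bg = 0) {
    f <- fit_transport(decay_trace(A0 = A0, A1 = A1, tau = 300))
    f$background <- bg
    f
  }
  expect_equal(time_zero_intensity(mk(5, 10))$I0, 225, tolerance = 1e-6)
  f0 <- fit_transport(shg_trace(seq(0, 100, 10), rep(25, 11), 1, shg_sample(75)))
  expect_equal(time_zero_intensity(f0)$I0, 25, tolerance = 1e-8)
  expect_equal(time_zero_intensity(mk(5, 10, bg = 7))$I0, 232, tolerance = 1e-6)
})

test_that("noisy-replicate tau recovery: median within 5%, CI coverage sane", {
  set.seed(202)
  tau_true <- 300
  fits <- replicate(100, {
    tr <- decay_trace(A0 = 5, A1 = 10, tau = tau_true, mult_noise = 0.05)
    f <- fit_transport(tr)
    c(f$tau, f$stderr[3])
  })
  expect_lt(abs(median(fits[1, ]) - tau_true) / tau_true, 0.05)
  covered <- abs(fits[1, ] - tau_true) <= 1.96 * fits[2, ]
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("transport table groups, sorts, aggregates duplicates", {
  expect_equal(nrow(transport_table(list())), 0)

  pure <- shg_sample(75, 0, "pure"); apap <- shg_sample(75, 25, "apap")
  t1 <- decay_trace(A0 = 4, A1 = 8, tau = 200, C_total = 4, sample = pure)
  t2 <- decay_trace(A0 = 4, A1 = 8, tau = 320, C_total = 4, sample = apap)
  tab <- transport_table(list(t2, t1))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$sample, c("apap", "pure"))
  expect_equal(tab$tau, c(320, 200), tolerance = 1e-6)

  expect_message(
    tab2 <- transport_table(list(t1, t1,
      decay_trace(A0 = 4, A1 = 8, tau = 200, C_total = 2, sample = pure))),
    "duplicate")
  expect_equal(nrow(tab2), 2)
  expect_equal(tab2$n, c(1L, 2L))
})

test_that("synthetic tau ordering (slower with APAP above threshold) survives the table", {
  truth <- noiseless_truth()
  traces <- list()
  for (sk in c("pure", "apap"))
    for (C in c(1, 2, 3.5, 6))
      traces[[paste(sk, C)]] <- simulate_trace(C, sk, truth, noise = FALSE)
  # subtract the known constant background so the field model is exact
  bgs <- vapply(traces, function(tr) {
    p <- if (tr$sample$apap_uM > 0) truth$samples$apap else truth$samples$pure
    truth$alpha * langmuir_coverage(tr$C_total, p$Nmax, p$K)$M_free + truth$B
  }, numeric(1))
  tab <- transport_table(traces, backgrounds = bgs)
  wide <- reshape(as.data.frame(tab)[, c("sample", "C_total", "tau")],
                  idvar = "C_total", timevar = "sample", direction = "wide")
  expect_true(all(wide$tau.dopc_apap[wide$C_total >= 3.5] >
                    wide$`tau.pure_dopc`[wide$C_total >= 3.5]))
  expect_equal(wide$tau.dopc_apap[wide$C_total < 3],
               wide$`tau.pure_dopc`[wide$C_total < 3], tolerance = 1e-4)
})

test_that("trace CSV round trip preserves data and sample tags", {
  tr <- decay_trace(C_total = 3.5, sample = shg_sample(75, 25, "apap_sample"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  tr2 <- read_trace(path)
  expect_equal(tr2$intensity, tr$intensity)
  expect_equal(tr2$time, tr$time)
  expect_equal(tr2$C_total, 3.5)
  expect_equal(tr2$sample$label, "apap_sample")
  expect_equal(tr2$sample$apap_uM, 25)
})
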