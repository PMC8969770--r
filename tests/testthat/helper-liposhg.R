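# Shared fixtures, all built in code.

# Gaussian spectrum on a regular grid (no noise unless sd > 0)
gaussian_spectrum <- function(amp = 100, center = 400, fwhm = 4.7,
                              baseline = 0, grid = seq(380, 420, by = 0.1),
                              noise_sd = 0) {
  y <- baseline + amp * exp(-4 * log(2) * (grid - center)^2 / fwhm^2)
  if (noise_sd > 0) y <- y * (1 + noise_sd * stats::rnorm(length(grid)))
  shg_spectrum(grid, y)
}

# Noiseless exponential-decay trace with intensity I = (A0 + A1 e^{-t/tau})^2
decay_trace <- function(A0 = 5, A1 = 10, tau = 300,
                        t = seq(0, 2000, length.out = 200),
                        C_total = 6, sample = shg_sample(75),
                        mult_noise = 0) {
  E <- A0 + A1 * exp(-t / tau)
  I <- E^2
  if (mult_noise > 0) I <- I * (1 + mult_noise * stats::rnorm(length(I)))
  shg_trace(t, I, C_total = C_total, sample = sample)
}

# Default truth with the noise switched off (the generator's zero-noise world)
noiseless_truth <- function(seed = 1) {
  tr <- default_truth(seed)
  tr$noise[] <- 0
  tr
}
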