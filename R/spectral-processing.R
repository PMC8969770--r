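#' Baseline-subtracted peak integral of a spectrum
#'
#' Scalar readout of an SHG emission spectrum: the trapezoidal integral of
#' counts over `[center - half_window, center + half_window]`, minus a flat
#' baseline estimated as the median of counts outside the window multiplied
#' by the window width. The median of the out-of-window region is robust to
#' the tails of the peak itself.
#'
#' @param s An [shg_spectrum()].
#' @param center Window center (nm), default 400 (the 2-omega peak).
#' @param half_window Half width of the integration window (nm), default 10.
#' @param baseline `"median"` (default) or `"none"` to disable baseline
#'   subtraction (used e.g. when asserting linearity).
#' @return Integrated intensity (counts, window-width weighted).
#' @export
integrate_peak <- function(s, center = 400, half_window = 10,
                           baseline = c("median", "none")) {
  stopifnot(inherits(s, "shg_spectrum"))
  baseline <- match.arg(baseline)
  lo <- center - half_window; hi <- center + half_window
  wl <- s$wavelength
  if (lo < min(wl) || hi > max(wl))
    stop("range error: integration window outside the wavelength grid", call. = FALSE)
  inside <- wl >= lo & wl <= hi
  x <- wl[inside]; y <- s$counts[inside]
  area <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  if (baseline == "median" && any(!inside)) {
    base <- stats::median(s$counts[!inside])
    area <- area - base * (max(x) - min(x))
  }
  area
}

#' Fit a Gaussian line shape to an SHG emission peak
#'
#' Least-squares fit of
#' `counts = baseline + amplitude * exp(-4 ln2 (lambda - center)^2 / fwhm^2)`.
#' Initial values are taken from the data (location of the maximum, half-max
#' crossings); the fit is exact on noiseless model spectra.
#'
#' @param s An [shg_spectrum()] with at least 8 points spanning the peak.
#' @return An object of class `peak_fit`: list with `amplitude`, `center`,
#'   `fwhm`, `baseline`, `cov` (4x4 covariance), `stderr`, `rss`.
#' @export
fit_gaussian_peak <- function(s) {
  stopifnot(inherits(s, "shg_spectrum"))
  wl <- s$wavelength; y <- s$counts
  if (length(wl) < 8)
    stop("invalid input: need >= 8 points to fit a peak", call. = FALSE)
  b0 <- stats::median(y)
  a0 <- max(y) - b0
  if (a0 <= 0 || a0 < 1e-10 * max(abs(y) + 1))
    stop("flat-spectrum error: no peak above the baseline", call. = FALSE)
  c0 <- wl[which.max(y)]
  # FWHM guess from half-max crossings around the maximum
  half <- b0 + a0 / 2
  above <- which(y >= half)
  w0 <- if (length(above) >= 2) max(wl[above]) - min(wl[above]) else diff(range(wl)) / 4
  if (w0 <= 0) w0 <- diff(range(wl)) / 4
  dat <- data.frame(wl = wl, y = y)
  fit <- tryCatch(
    stats::nls(y ~ b + a * exp(-4 * log(2) * (wl - cen)^2 / w^2),
               data = dat,
               start = list(b = b0, a = a0, cen = c0, w = w0),
               control = stats::nls.control(maxiter = 500, minFactor = 1e-10,
                                            scaleOffset = 1)),
    error = function(e) stop("fit error: Gaussian peak fit failed to converge (",
                             conditionMessage(e), ")", call. = FALSE))
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 4, 4))
  structure(list(amplitude = unname(cf["a"]), center = unname(cf["cen"]),
                 fwhm = abs(unname(cf["w"])), baseline = unname(cf["b"]),
                 cov = vc,
                 stderr = sqrt(pmax(diag(vc), 0)),
                 rss = sum(stats::resid(fit)^2)),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("Gaussian peak: amplitude %.4g, center %.2f nm, FWHM %.3g nm, baseline %.4g\n",
              x$amplitude, x$center, x$fwhm, x$baseline))
  invisible(x)
}

#' Hyper-Rayleigh scattering calibration
#'
#' Ordinary least-squares line through (dye concentration, integrated
#' intensity) points of a dye-only control series. The slope is the HRS
#' coefficient `alpha` used by the isotherm observation model; HRS from
#' free dye in bulk solution is incoherent and linear in concentration.
#'
#' @param conc_uM Dye concentrations (uM), >= 3 distinct values.
#' @param spectra List of [shg_spectrum()] of the same length, or a numeric
#'   vector of already-integrated intensities.
#' @param center,half_window Passed to [integrate_peak()].
#' @return List of class `hrs_calibration`: `alpha` (counts/uM),
#'   `intercept` (counts), `r_squared`, `alpha_stderr`.
#' @export
hrs_calibration <- function(conc_uM, spectra, center = 400, half_window = 10) {
  check_nonneg(conc_uM, "conc_uM")
  if (length(unique(conc_uM)) < 3)
    stop("insufficient data: need >= 3 distinct concentrations", call. = FALSE)
  intensity <- if (is.numeric(spectra)) spectra
               else vapply(spectra, integrate_peak, numeric(1),
                           center = center, half_window = half_window)
  if (length(intensity) != length(conc_uM))
    stop("invalid input: lengths of conc_uM and spectra differ", call. = FALSE)
  fit <- stats::lm(intensity ~ conc_uM)
  alpha <- unname(stats::coef(fit)[2])
  if (is.finite(alpha) && alpha < 0)
    warning("HRS calibration slope is negative; check the control series")
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((intensity - mean(intensity))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else 1
  # direct OLS slope stderr (vcov.lm warns on numerically perfect fits)
  sxx <- sum((conc_uM - mean(conc_uM))^2)
  se <- sqrt(rss / (length(conc_uM) - 2) / sxx)
  structure(list(alpha = alpha,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 alpha_stderr = se),
            class = "hrs_calibration")
}

#' Baseline offset from dye-free liposome spectra
#'
#' The baseline `B` of the observation model is the SHG signal from
#' liposomes in water before any dye is added; it is the mean integrated
#' intensity over the dye-free control spectra, clamped at zero (the signal
#' is physically non-negative).
#'
#' @param spectra Non-empty list of dye-free [shg_spectrum()] objects.
#' @param center,half_window Passed to [integrate_peak()].
#' @return Baseline B (counts), >= 0.
#' @export
baseline_offset <- function(spectra, center = 400, half_window = 10) {
  if (length(spectra) == 0)
    stop("insufficient data: need >= 1 dye-free spectrum", call. = FALSE)
  vals <- vapply(spectra, integrate_peak, numeric(1),
                 center = center, half_window = half_window)
  B <- mean(vals)
  if (B < 0) {
    warning("mean dye-free intensity is negative; clamping baseline at 0")
    B <- 0
  }
  B
}
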