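#' Adsorption isotherm container
#'
#' Time-zero SHG intensities versus total dye concentration for one sample
#' composition, with the calibrated HRS slope `alpha` and baseline `B`
#' carried as fixed values (the isotherm itself is fit with only three free
#' parameters: A, Nmax, K).
#'
#' @param C_total Total dye concentrations (uM), > 0, >= 4 distinct.
#' @param I0 Time-zero intensities (counts).
#' @param I0_sigma Propagated uncertainties (counts), >= 0; optional.
#' @param sample An [shg_sample()].
#' @param alpha Fixed HRS slope (counts/uM).
#' @param B Fixed baseline offset (counts).
#' @return Object of class `adsorption_isotherm`.
#' @export
adsorption_isotherm <- function(C_total, I0, I0_sigma = NULL, sample,
                                alpha = 0, B = 0) {
  check_pos(C_total, "C_total"); check_finite(I0, "I0")
  stopifnot(inherits(sample, "shg_sample"))
  check_nonneg(alpha, "alpha"); check_nonneg(B, "B")
  if (is.null(I0_sigma)) I0_sigma <- rep(0, length(C_total))
  check_nonneg(I0_sigma, "I0_sigma")
  if (length(unique(C_total)) < 4)
    stop("insufficient data: need >= 4 distinct concentrations", call. = FALSE)
  ord <- order(C_total)
  structure(list(C_total = C_total[ord], I0 = I0[ord],
                 I0_sigma = I0_sigma[ord], sample = sample,
                 alpha = alpha, B = B),
            class = "adsorption_isotherm")
}

#' @export
print.adsorption_isotherm <- function(x, ...) {
  cat(sprintf("Adsorption isotherm: %d points, C = %g-%g uM, sample '%s' (alpha = %.4g, B = %.4g fixed)\n",
              length(x$C_total), min(x$C_total), max(x$C_total),
              x$sample$label, x$alpha, x$B))
  invisible(x)
}

#' Assemble an adsorption isotherm from transport fits
#'
#' Builds isotherm points from per-trace [time_zero_intensity()]
#' extrapolations, sorted by concentration. Duplicate concentrations are
#' aggregated by the mean (combined sigma), with a message.
#'
#' @param fits List of [fit_transport()] results; their `C_total` fields
#'   supply the concentrations. >= 4 distinct concentrations required.
#' @param sample An [shg_sample()].
#' @param alpha,B Fixed calibration values.
#' @return An [adsorption_isotherm()].
#' @export
assemble_isotherm <- function(fits, sample, alpha = 0, B = 0) {
  C <- vapply(fits, function(f) f$C_total, numeric(1))
  tz <- lapply(fits, time_zero_intensity)
  I0 <- vapply(tz, `[[`, numeric(1), "I0")
  sg <- vapply(tz, `[[`, numeric(1), "sigma")
  if (anyDuplicated(C)) {
    message("assemble_isotherm: aggregating duplicate concentrations by mean")
    grp <- split(seq_along(C), C)
    C  <- as.numeric(names(grp))
    I0 <- vapply(grp, function(i) mean(I0[i]), numeric(1))
    sg <- vapply(grp, function(i) sqrt(sum(sg[i]^2)) / length(i), numeric(1))
  }
  adsorption_isotherm(C, I0, sg, sample = sample, alpha = alpha, B = B)
}

#' Fit the modified Langmuir model to an adsorption isotherm
#'
#' Weighted nonlinear least squares of [isotherm_intensity()] over
#' (A, Nmax, K) with `alpha` and `B` held fixed at their calibrated values.
#' `K` is fitted as log10(K) with box constraint `K` in [1e3, 1e12] to tame
#' the seven-decade scale disparity with A and Nmax. Weights are
#' `1/I0_sigma^2` when sigmas are present (uniform otherwise). Default
#' initialization: `A = max(I0) - B`, `Nmax = max(C)/2`,
#' `K = W/max(C)` (half-depletion heuristic); on failure, up to 5 restarts
#' with seeded +-50% jitter on the initial values.
#'
#' @param iso An [adsorption_isotherm()].
#' @param init Optional named list/vector with `A`, `Nmax`, `K` starting
#'   values.
#' @param hrs_mode Passed to [isotherm_intensity()].
#' @param n_restarts Jittered restarts before giving up (default 5).
#' @param restart_seed Seed for the jitter stream (default 42).
#' @param k_scale `"log10"` (default) fits log10(K); `"linear"` fits K
#'   directly (kept for reparameterization-invariance checks; poorly
#'   conditioned on real problems).
#' @return Object of class `isotherm_fit`: `params` ([langmuir_params()]
#'   with fitted A, Nmax, K and carried-over alpha, B), `stderr` (named,
#'   on the natural scale; K via the delta method), `cov` (3x3 on the
#'   (A, Nmax, log10K) fitting scale), `rss`, `saturation_unidentified`
#'   flag (Nmax at its upper bound 10*max(C)), `bootstrap` (NULL until
#'   [bootstrap_uncertainties()]), `iso`, `hrs_mode`.
#' @export
fit_modified_langmuir <- function(iso, init = NULL,
                                  hrs_mode = c("free", "total"),
                                  n_restarts = 5, restart_seed = 42,
                                  k_scale = c("log10", "linear")) {
  stopifnot(inherits(iso, "adsorption_isotherm"))
  hrs_mode <- match.arg(hrs_mode)
  k_scale <- match.arg(k_scale)
  W <- shg_constants$water_uM
  C <- iso$C_total; I0 <- iso$I0
  w <- if (any(iso$I0_sigma > 0)) 1 / pmax(iso$I0_sigma, 1e-6 * max(abs(I0)))^2
       else rep(1, length(I0))
  maxC <- max(C)
  to_k  <- if (k_scale == "log10") function(lk) 10^lk else function(lk) lk
  from_k <- if (k_scale == "log10") log10 else identity
  start0 <- list(A = max(max(I0) - iso$B, 1e-3),
                 Nmax = maxC / 2,
                 lk = from_k(W / maxC))
  if (!is.null(init))
    start0 <- list(A = init[["A"]], Nmax = init[["Nmax"]], lk = from_k(init[["K"]]))
  lower <- c(A = 1e-8, Nmax = 1e-4, lk = from_k(1e3))
  upper <- c(A = Inf, Nmax = 10 * maxC, lk = from_k(1e12))

  model <- function(A, Nmax, lk)
    isotherm_intensity(C, langmuir_params(A, Nmax, to_k(lk), iso$alpha, iso$B),
                       hrs_mode = hrs_mode)
  dat <- data.frame(C = C, y = I0)

  try_fit <- function(st) {
    st$Nmax <- min(max(st$Nmax, lower["Nmax"] * 2), upper["Nmax"])
    st$lk <- min(max(st$lk, lower["lk"]), upper["lk"])
    tryCatch(
      stats::nls(y ~ model(A, Nmax, lk), data = dat, weights = w,
                 start = st, algorithm = "port",
                 lower = lower, upper = upper,
                 control = stats::nls.control(maxiter = 500, warnOnly = FALSE)),
      error = function(e) e)
  }

  fit <- try_fit(start0)
  if (inherits(fit, "error") && n_restarts > 0) {
    rng <- make_rng(restart_seed)
    for (r in seq_len(n_restarts)) {
      jit <- lapply(start0, function(v) v * stats::runif(1, 0.5, 1.5))
      fit2 <- try_fit(jit)
      if (!inherits(fit2, "error")) { fit <- fit2; break }
      fit <- fit2
    }
    restore_rng(rng)
  }
  if (inherits(fit, "error"))
    stop("fit error: modified Langmuir fit failed after restarts (",
         conditionMessage(fit), ")", call. = FALSE)

  cf <- stats::coef(fit)
  K_hat <- to_k(unname(cf["lk"]))
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(pmax(diag(vc), 0))
  stderr <- c(A = unname(se[1]), Nmax = unname(se[2]),
              K = if (k_scale == "log10") log(10) * K_hat * unname(se[3])
                  else unname(se[3]))
  structure(list(
    params = langmuir_params(unname(cf["A"]), unname(cf["Nmax"]), K_hat,
                             iso$alpha, iso$B),
    stderr = stderr, cov = vc, rss = sum(stats::resid(fit)^2),
    saturation_unidentified = unname(cf["Nmax"]) >= upper["Nmax"] * (1 - 1e-6),
    bootstrap = NULL, iso = iso, hrs_mode = hrs_mode),
    class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("Modified Langmuir fit ('%s'):\n", x$iso$sample$label))
  cat(sprintf("  A    = %.4g +/- %.2g counts\n", p$A, x$stderr["A"]))
  cat(sprintf("  Nmax = %.4g +/- %.2g uM\n", p$Nmax, x$stderr["Nmax"]))
  cat(sprintf("  K    = %.4g +/- %.2g\n", p$K, x$stderr["K"]))
  if (isTRUE(x$saturation_unidentified))
    cat("  [saturation unidentified: Nmax at its upper bound]\n")
  invisible(x)
}

# Save/restore the global RNG state around seeded internals so that seeded
# helpers do not perturb a caller's random stream.
make_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Residual-resampling bootstrap for the modified Langmuir fit
#'
#' Resamples the base fit's residuals with replacement, refits each
#' replicate starting from the base solution, and attaches the draws and
#' their percentile 68% intervals to the result. Reproducible under a
#' fixed seed.
#'
#' @param fit An [fit_modified_langmuir()] result.
#' @param n_boot Number of replicates, >= 100.
#' @param seed Integer seed.
#' @return The `isotherm_fit` with `bootstrap`: list of `draws` (n x 3
#'   matrix, columns A, Nmax, K), `ci68` (2 x 3 percentile interval),
#'   `n_failed`.
#' @export
bootstrap_uncertainties <- function(fit, n_boot = 500, seed = 1) {
  stopifnot(inherits(fit, "isotherm_fit"))
  if (n_boot < 100) stop("invalid input: n_boot must be >= 100", call. = FALSE)
  iso <- fit$iso
  p <- fit$params
  yhat <- isotherm_intensity(iso$C_total, p, hrs_mode = fit$hrs_mode)
  res <- iso$I0 - yhat
  init <- list(A = p$A, Nmax = p$Nmax, K = p$K)
  rng <- make_rng(seed)
  on.exit(restore_rng(rng))
  draws <- matrix(NA_real_, n_boot, 3,
                  dimnames = list(NULL, c("A", "Nmax", "K")))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    ystar <- yhat + sample(res, length(res), replace = TRUE)
    iso_b <- iso
    iso_b$I0 <- ystar
    fb <- tryCatch(
      fit_modified_langmuir(iso_b, init = init, hrs_mode = fit$hrs_mode,
                            n_restarts = 0),
      error = function(e) NULL)
    if (is.null(fb)) n_failed <- n_failed + 1L
    else draws[b, ] <- c(fb$params$A, fb$params$Nmax, fb$params$K)
  }
  if (n_failed > 0.2 * n_boot)
    warning("bootstrap unstable: more than 20% of replicates failed to converge")
  ok <- stats::complete.cases(draws)
  fit$bootstrap <- list(
    draws = draws,
    ci68 = apply(draws[ok, , drop = FALSE], 2, stats::quantile,
                 probs = c(0.16, 0.84)),
    n_failed = n_failed)
  fit
}

#' Derived thermodynamic and coverage report
#'
#' Computes the adsorption free energy `-RT ln K`, the lipids per
#' adsorption site `lipid/Nmax`, and the signal per coverage `A/Nmax^2`
#' from a fitted isotherm, with first-order uncertainty propagation
#' (sigma_dG = RT * sigma_K / K; ratios propagate relative errors in
#' quadrature ignoring parameter correlations). When bootstrap draws are
#' attached, percentile 68% intervals of the derived quantities are
#' reported alongside.
#'
#' @param fit An [fit_modified_langmuir()] result.
#' @param T Absolute temperature (K); default 293 (ambient; the
#'   experiments have no stated temperature).
#' @return Object of class `derived_report`: `sample`, `delta_g`,
#'   `delta_g_sigma` (kcal/mol), `lipids_per_site`, `lipids_per_site_sigma`,
#'   `signal_per_coverage`, `signal_per_coverage_sigma` (counts uM^-2),
#'   `T`, `params`, `param_stderr`, optional `bootstrap_ci68`.
#' @export
derived_report <- function(fit, T = shg_constants$default_T) {
  stopifnot(inherits(fit, "isotherm_fit"))
  p <- fit$params
  se <- fit$stderr
  th <- adsorption_free_energy(p$K, T)
  lipid <- fit$iso$sample$lipid_uM
  lps <- lipids_per_site(lipid, p$Nmax)
  spc <- signal_per_coverage(p$A, p$Nmax)
  relN <- se["Nmax"] / p$Nmax
  relA <- se["A"] / p$A
  rep <- list(
    sample = fit$iso$sample,
    delta_g = th$delta_g,
    delta_g_sigma = unname(shg_constants$R_kcal * T * se["K"] / p$K),
    lipids_per_site = lps,
    lipids_per_site_sigma = unname(lps * relN),
    signal_per_coverage = spc,
    signal_per_coverage_sigma = unname(spc * sqrt(relA^2 + (2 * relN)^2)),
    T = T, params = p, param_stderr = se)
  if (!is.null(fit$bootstrap)) {
    d <- fit$bootstrap$draws
    ok <- stats::complete.cases(d)
    der <- cbind(delta_g = -shg_constants$R_kcal * T * log(d[ok, "K"]),
                 lipids_per_site = lipid / d[ok, "Nmax"],
                 signal_per_coverage = d[ok, "A"] / d[ok, "Nmax"]^2)
    rep$bootstrap_ci68 <- apply(der, 2, stats::quantile, probs = c(0.16, 0.84))
  }
  structure(rep, class = "derived_report")
}

#' @export
print.derived_report <- function(x, ...) {
  cat(sprintf("Derived report ('%s', T = %g K):\n", x$sample$label, x$T))
  cat(sprintf("  deltaG          = %.3f +/- %.3f kcal/mol\n", x$delta_g, x$delta_g_sigma))
  cat(sprintf("  lipids/site     = %.3g +/- %.2g\n", x$lipids_per_site, x$lipids_per_site_sigma))
  cat(sprintf("  A/Nmax^2        = %.3g +/- %.2g uM^-2\n", x$signal_per_coverage,
              x$signal_per_coverage_sigma))
  invisible(x)
}
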