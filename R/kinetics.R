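#' SHG time trace
#'
#' Intensity versus time after dye addition (t = 0) at a known total dye
#' concentration, for one liposome sample. Each trace corresponds to a
#' fresh liposome sample.
#'
#' @param time Strictly increasing times (s).
#' @param intensity Counts per point, finite; may dip below zero from noise.
#' @param C_total Total added dye concentration (uM), > 0.
#' @param sample An [shg_sample()].
#' @return An object of class `shg_trace`.
#' @export
shg_trace <- function(time, intensity, C_total, sample) {
  check_finite(time, "time"); check_finite(intensity, "intensity")
  check_pos(C_total, "C_total")
  stopifnot(inherits(sample, "shg_sample"))
  if (length(time) != length(intensity))
    stop("invalid input: time and intensity must have equal length", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("invalid input: time grid must be strictly increasing", call. = FALSE)
  structure(list(time = time, intensity = intensity, C_total = C_total,
                 sample = sample),
            class = "shg_trace")
}

#' @export
print.shg_trace <- function(x, ...) {
  cat(sprintf("SHG time trace: %d points over %.4g s, C = %g uM, sample '%s'\n",
              length(x$time), max(x$time) - min(x$time), x$C_total,
              x$sample$label))
  invisible(x)
}

#' Read / write time-trace CSV files
#'
#' Two-column CSV `time_s,intensity_counts` with `# sample=`, `# dye_uM=`,
#' `# lipid_uM=`, `# apap_uM=` comment headers.
#'
#' @param path File path.
#' @return [read_trace()] returns an `shg_trace`; [write_trace()] returns
#'   `path` invisibly.
#' @export
read_trace <- function(path) {
  meta <- read_comment_meta(path)
  df <- utils::read.csv(path, comment.char = "#")
  samp <- shg_sample(lipid_uM = meta$lipid_uM %||% 75,
                     apap_uM = meta$apap_uM %||% 0,
                     label = meta$sample)
  shg_trace(df[[1]], df[[2]], C_total = meta$dye_uM, sample = samp)
}

#' @rdname read_trace
#' @param trace An `shg_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "shg_trace"))
  meta <- list(sample = trace$sample$label, dye_uM = trace$C_total,
               lipid_uM = trace$sample$lipid_uM, apap_uM = trace$sample$apap_uM)
  df <- data.frame(time_s = trace$time, intensity_counts = trace$intensity)
  write_commented_csv(df, path, meta)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Intensity-to-field transform of a time trace
#'
#' Converts an intensity trace to the SHG field domain pointwise as
#' `E = sqrt(max(I, 0))`; negative intensities (noise) are clamped at zero
#' and counted. An optional constant `background` (incoherent HRS plus
#' baseline, time-independent within a trace) is subtracted first.
#'
#' @param trace An [shg_trace()].
#' @param background Constant background (counts) subtracted before the
#'   square root. Default 0.
#' @return List with `time`, `field`, `n_clamped`, `background`.
#' @export
intensity_to_field <- function(trace, background = 0) {
  stopifnot(inherits(trace, "shg_trace"))
  check_nonneg(background, "background")
  shifted <- trace$intensity - background
  list(time = trace$time,
       field = sqrt(pmax(shifted, 0)),
       n_clamped = sum(shifted < 0),
       background = background)
}

#' Fit the single-exponential transport model to a time trace
#'
#' Nonlinear least squares of `E(t) = A0 + A1 * exp(-t / tau)` on the
#' field-domain trace (square root of the background-subtracted intensity).
#' Initialization: `A0` = mean of the last decile of the field, `A1` =
#' first point minus `A0`, `tau` = time at which the field first crosses
#' `A0 + A1/e` (linear interpolation). The field transform already
#' variance-stabilizes shot noise approximately, so the default weighting
#' is uniform; `"poisson"` weights each point by `1/max(E, eps)`.
#'
#' A constant trace (no resolvable decay) returns `A1 = 0` with the
#' `unresolved` flag set rather than an error; a fitted `tau` exceeding
#' 100x the trace span also sets the flag.
#'
#' @param trace An [shg_trace()].
#' @param weighting `"uniform"` (default) or `"poisson"`.
#' @param background Constant background subtracted before the field
#'   transform; stored on the result so that [time_zero_intensity()] can
#'   add it back.
#' @param domain `"field"` (default, the model's own domain) or
#'   `"intensity"` to fit `(A0 + A1 e^{-t/tau})^2` directly to intensities
#'   (sensitivity option).
#' @return Object of class `transport_fit`: `A0`, `A1`, `tau`, `cov` (3x3,
#'   order A0, A1, tau; heteroscedasticity-consistent sandwich covariance,
#'   since trace noise is closer to multiplicative than additive), `stderr`,
#'   `rss`, `unresolved`, `n_clamped`, `background`, `C_total`, `sample`.
#' @export
fit_transport <- function(trace, weighting = c("uniform", "poisson"),
                          background = 0, domain = c("field", "intensity")) {
  stopifnot(inherits(trace, "shg_trace"))
  weighting <- match.arg(weighting)
  domain <- match.arg(domain)
  fd <- intensity_to_field(trace, background = background)
  t <- fd$time; E <- fd$field
  if (length(t) < 6)
    stop("invalid input: need >= 6 points to fit the transport model", call. = FALSE)
  span <- max(t) - min(t)

  n_tail <- max(2L, ceiling(length(E) / 10))
  A0_0 <- mean(E[(length(E) - n_tail + 1):length(E)])
  A1_0 <- E[1] - A0_0

  # degenerate flat trace: report no decay instead of failing
  if (abs(A1_0) <= 1e-8 * (abs(A0_0) + 1e-12) || stats::sd(E) == 0) {
    return(new_transport_fit(A0 = mean(E), A1 = 0, tau = span,
                             cov = matrix(0, 3, 3), rss = sum((E - mean(E))^2),
                             unresolved = TRUE, fd = fd, trace = trace))
  }

  target <- A0_0 + A1_0 / exp(1)
  tau_0 <- {
    crossed <- if (A1_0 > 0) which(E <= target) else which(E >= target)
    crossed <- crossed[crossed > 1]
    if (length(crossed)) {
      i <- crossed[1]
      # linear interpolation between the bracketing samples
      t[i - 1] + (target - E[i - 1]) * (t[i] - t[i - 1]) / (E[i] - E[i - 1])
    } else span / 3
  }
  if (!is.finite(tau_0) || tau_0 <= 0) tau_0 <- span / 3

  w <- if (weighting == "poisson") 1 / pmax(E, 1e-8) else rep(1, length(E))
  dat <- data.frame(t = t, y = if (domain == "field") E else pmax(trace$intensity - background, 0))
  form <- if (domain == "field") y ~ A0 + A1 * exp(-t / tau)
          else y ~ (A0 + A1 * exp(-t / tau))^2
  # tolerance ladder: the strict pass makes noiseless round trips exact
  # (few iterations from a good start); noisy data fall through to the
  # standard tolerances
  controls <- list(
    stats::nls.control(maxiter = 50, minFactor = 1e-12, scaleOffset = 1,
                       tol = 1e-11),
    stats::nls.control(maxiter = 500, minFactor = 1e-12, scaleOffset = 1,
                       tol = 1e-8),
    stats::nls.control(maxiter = 500, minFactor = 1e-12, scaleOffset = 1))
  try_nls <- function(st) {
    for (ctrl in controls) {
      cand <- tryCatch(stats::nls(form, data = dat, weights = w, start = st,
                                  control = ctrl),
                       error = function(e) e)
      if (!inherits(cand, "error")) return(cand)
    }
    cand
  }
  # ladder of tau starts: noisy traces often defeat the crossing heuristic
  starts <- lapply(unique(c(tau_0, span / 10, span / 3, span)),
                   function(tt) list(A0 = A0_0, A1 = A1_0, tau = tt))
  fit <- NULL
  for (st in starts) {
    cand <- try_nls(st)
    if (!inherits(cand, "error")) { fit <- cand; break }
  }
  if (is.null(fit)) {
    # last resort: direct RSS minimization, then one nls polish for vcov
    obj <- function(p) sum(w * (dat$y - (p[1] + p[2] * exp(-dat$t / exp(p[3]))))^2)
    op <- stats::optim(c(A0_0, A1_0, log(max(tau_0, span / 10))), obj,
                       method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    polish <- try_nls(list(A0 = op$par[1], A1 = op$par[2], tau = exp(op$par[3])))
    if (inherits(polish, "error")) {
      return(new_transport_fit(A0 = op$par[1], A1 = op$par[2],
                               tau = exp(op$par[3]),
                               cov = matrix(NA_real_, 3, 3), rss = op$value,
                               unresolved = exp(op$par[3]) > 100 * span,
                               fd = fd, trace = trace))
    }
    fit <- polish
  }
  cf <- stats::coef(fit)
  vc <- tryCatch(sandwich_vcov(fit, w), error = function(e) matrix(NA_real_, 3, 3))
  new_transport_fit(A0 = unname(cf["A0"]), A1 = unname(cf["A1"]),
                    tau = unname(cf["tau"]), cov = vc,
                    rss = sum(stats::resid(fit)^2),
                    unresolved = unname(cf["tau"]) > 100 * span,
                    fd = fd, trace = trace)
}

# Heteroscedasticity-consistent covariance for an nls fit: the intensity
# noise of real traces is closer to multiplicative than additive, so the
# classical (homoscedastic) nls covariance under-covers tau noticeably.
# V = (J'WJ)^-1 J'W diag(r^2) WJ (J'WJ)^-1 with J the model Jacobian.
sandwich_vcov <- function(fit, w) {
  J <- fit$m$gradient()
  r <- as.numeric(stats::resid(fit))
  B <- crossprod(J, w * J)
  Bi <- solve(B)
  meat <- crossprod(J, (w^2 * r^2) * J)
  V <- Bi %*% meat %*% Bi
  (V + t(V)) / 2
}

new_transport_fit <- function(A0, A1, tau, cov, rss, unresolved, fd, trace) {
  structure(list(A0 = A0, A1 = A1, tau = tau, cov = cov,
                 stderr = sqrt(pmax(diag(cov), 0)),
                 rss = rss, unresolved = unresolved,
                 n_clamped = fd$n_clamped, background = fd$background,
                 C_total = trace$C_total, sample = trace$sample),
            class = "transport_fit")
}

#' @export
print.transport_fit <- function(x, ...) {
  cat(sprintf("Transport fit: A0 = %.4g, A1 = %.4g, tau = %.4g s%s (C = %g uM, '%s')\n",
              x$A0, x$A1, x$tau,
              if (isTRUE(x$unresolved)) " [unresolved decay]" else "",
              x$C_total, x$sample$label))
  invisible(x)
}

#' Time-zero SHG intensity from a transport fit
#'
#' Extrapolated intensity at the instant of dye addition,
#' `I(0) = (A0 + A1)^2` plus any background that was subtracted before the
#' field-domain fit. The adsorption step is faster than the experimental
#' resolution, so the fit extrapolation is more robust than the first
#' measured sample. Uncertainty by the first-order delta method from the
#' parameter covariance.
#'
#' @param fit A [fit_transport()] result.
#' @return List with `I0` (counts) and `sigma` (counts).
#' @export
time_zero_intensity <- function(fit) {
  stopifnot(inherits(fit, "transport_fit"))
  E0 <- fit$A0 + fit$A1
  grad <- c(2 * E0, 2 * E0, 0)
  v <- if (all(is.finite(fit$cov))) drop(t(grad) %*% fit$cov %*% grad) else NA_real_
  list(I0 = E0^2 + fit$background, sigma = sqrt(max(v, 0)))
}

#' Transport-time table across traces
#'
#' Fits every trace and tabulates one row per (sample, concentration) pair,
#' sorted by sample then concentration. Duplicate (sample, C) pairs are
#' aggregated by the mean with combined standard error, with a message.
#'
#' @param traces List of [shg_trace()] objects (may be empty).
#' @param backgrounds Optional numeric vector of per-trace backgrounds.
#' @param ... Passed to [fit_transport()].
#' @return data.frame of class `transport_table` with columns `sample`,
#'   `C_total`, `tau`, `tau_stderr`, `n`.
#' @export
transport_table <- function(traces, backgrounds = NULL, ...) {
  if (length(traces) == 0)
    return(structure(data.frame(sample = character(), C_total = numeric(),
                                tau = numeric(), tau_stderr = numeric(),
                                n = integer()),
                     class = c("transport_table", "data.frame")))
  if (is.null(backgrounds)) backgrounds <- rep(0, length(traces))
  rows <- lapply(seq_along(traces), function(i) {
    f <- fit_transport(traces[[i]], background = backgrounds[i], ...)
    data.frame(sample = f$sample$label, C_total = f$C_total,
               tau = f$tau, tau_stderr = f$stderr[3])
  })
  tab <- do.call(rbind, rows)
  key <- paste(tab$sample, tab$C_total, sep = "\r")
  if (anyDuplicated(key)) {
    message("transport_table: aggregating duplicate (sample, C) pairs by mean")
    agg <- lapply(split(tab, key), function(g)
      data.frame(sample = g$sample[1], C_total = g$C_total[1],
                 tau = mean(g$tau),
                 tau_stderr = sqrt(sum(g$tau_stderr^2)) / nrow(g),
                 n = nrow(g)))
    tab <- do.call(rbind, agg)
  } else tab$n <- 1L
  tab <- tab[order(tab$sample, tab$C_total), ]
  rownames(tab) <- NULL
  structure(tab, class = c("transport_table", "data.frame"))
}
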