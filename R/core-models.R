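#' Interface populations of an SHG-active adsorbate
#'
#' Bundles the adsorbate populations on the outer and inner leaflets of a
#' bilayer together with the incident optical field amplitude. Oppositely
#' oriented adsorbates on the two leaflets radiate second-harmonic
#' polarizations of opposite sign, so only the population difference
#' contributes to the coherent SHG field.
#'
#' @param N_outer Adsorbate surface population on the outer leaflet
#'   (uM equivalents), >= 0.
#' @param N_inner Adsorbate surface population on the inner leaflet
#'   (uM equivalents), >= 0.
#' @param E_omega Incident optical field amplitude (arbitrary units), >= 0.
#' @return An object of class `interface_populations`.
#' @export
interface_populations <- function(N_outer, N_inner, E_omega = 1) {
  check_nonneg(N_outer, "N_outer")
  check_nonneg(N_inner, "N_inner")
  check_nonneg(E_omega, "E_omega")
  structure(list(N_outer = N_outer, N_inner = N_inner, E_omega = E_omega),
            class = "interface_populations")
}

#' Sample composition
#'
#' @param lipid_uM Total lipid concentration (uM), > 0.
#' @param apap_uM Additive (APAP) concentration (uM), >= 0.
#' @param label Free-text sample name.
#' @return An object of class `shg_sample`.
#' @export
shg_sample <- function(lipid_uM, apap_uM = 0, label = NULL) {
  check_pos(lipid_uM, "lipid_uM")
  check_nonneg(apap_uM, "apap_uM")
  if (is.null(label))
    label <- if (apap_uM > 0) sprintf("%g uM DOPC + %g uM APAP", lipid_uM, apap_uM)
             else sprintf("pure %g uM DOPC", lipid_uM)
  structure(list(lipid_uM = lipid_uM, apap_uM = apap_uM, label = label),
            class = "shg_sample")
}

#' Parameters of the modified Langmuir observation model
#'
#' `A` is the SHG intensity at adsorbate saturation, `Nmax` the maximum
#' adsorption site concentration, `K` the (dimensionless, water-referenced)
#' adsorption equilibrium constant, `alpha` the hyper-Rayleigh scattering
#' slope of intensity versus free dye concentration, and `B` the baseline
#' offset from liposomes in water without dye.
#'
#' @param A Saturation SHG intensity (counts), > 0.
#' @param Nmax Maximum adsorption site concentration (uM), > 0.
#' @param K Adsorption equilibrium constant (dimensionless), > 0.
#' @param alpha HRS slope (counts per uM free dye), >= 0.
#' @param B Baseline offset (counts), >= 0.
#' @return An object of class `langmuir_params`.
#' @export
langmuir_params <- function(A, Nmax, K, alpha = 0, B = 0) {
  check_pos(A, "A"); check_pos(Nmax, "Nmax"); check_pos(K, "K")
  check_nonneg(alpha, "alpha"); check_nonneg(B, "B")
  structure(list(A = A, Nmax = Nmax, K = K, alpha = alpha, B = B),
            class = "langmuir_params")
}

#' @export
print.langmuir_params <- function(x, ...) {
  cat(sprintf("Modified Langmuir parameters: A = %.4g counts, Nmax = %.4g uM, K = %.4g, alpha = %.4g counts/uM, B = %.4g counts\n",
              x$A, x$Nmax, x$K, x$alpha, x$B))
  invisible(x)
}

#' Coherent SHG field from leaflet populations
#'
#' The second-harmonic field is linearly proportional to the population
#' difference between the outer and inner leaflets and to the square of the
#' incident field: `E_SHG = prefactor * (N_outer - N_inner) * E_omega^2`.
#' The sign is preserved; populations with `N_inner > N_outer` give a
#' negative field.
#'
#' @param pop An [interface_populations()] object.
#' @param prefactor Positive proportionality constant.
#' @return Signed field amplitude (numeric).
#' @export
coherent_field <- function(pop, prefactor = 1) {
  stopifnot(inherits(pop, "interface_populations"))
  check_pos(prefactor, "prefactor")
  prefactor * (pop$N_outer - pop$N_inner) * pop$E_omega^2
}

#' SHG intensity from a field amplitude
#'
#' `I_SHG = E_SHG^2`; the detected intensity is insensitive to the sign of
#' the coherent field.
#'
#' @param field Signed field amplitude (finite numeric).
#' @return Non-negative intensity.
#' @export
shg_intensity <- function(field) {
  check_finite(field, "field")
  field^2
}

#' Depletion-corrected Langmuir surface coverage
#'
#' Solves the modified Langmuir equilibrium for the adsorbed concentration
#' `N` when binding to the large cumulative liposome surface area depletes
#' the bulk: `N / (Nmax - N) = (K / W) * (C_total - N)` with
#' `W = 55.5e6` uM (55.5 M water reference). The solution is the physical
#' (smaller) root of the quadratic
#' `N = 0.5 * (b - sqrt(b^2 - 4 C Nmax))`, `b = C + Nmax + W/K`,
#' evaluated in the cancellation-safe form `2 C Nmax / (b + sqrt(disc))`.
#'
#' @param C_total Total added dye concentration (uM), >= 0. Vectorized.
#' @param Nmax Maximum adsorption site concentration (uM), > 0.
#' @param K Dimensionless adsorption equilibrium constant, > 0.
#' @return A data.frame of class `coverage_result` with columns
#'   `C_total`, `N_adsorbed`, `M_free` (mass balance `N + M = C` holds by
#'   construction).
#' @seealso [langmuir_coverage_oracle()] for the independent bisection
#'   solver used in verification.
#' @export
langmuir_coverage <- function(C_total, Nmax, K) {
  check_nonneg(C_total, "C_total")
  check_pos(Nmax, "Nmax"); check_pos(K, "K")
  W <- shg_constants$water_uM
  b <- C_total + Nmax + W / K
  disc <- b^2 - 4 * C_total * Nmax
  # guard: clamp tiny negative discriminants from rounding
  bad <- disc < 0
  if (any(bad)) {
    if (any(disc[bad] < -1e-12 * b[bad]^2))
      stop("internal consistency error: negative discriminant in coverage solver",
           call. = FALSE)
    disc[bad] <- 0
  }
  N <- 2 * C_total * Nmax / (b + sqrt(disc))
  structure(data.frame(C_total = C_total, N_adsorbed = N, M_free = C_total - N),
            class = c("coverage_result", "data.frame"))
}

#' Bisection oracle for the depletion-corrected coverage
#'
#' Independent verification solver: finds the root of
#' `f(N) = N * W - K * (C - N) * (Nmax - N)` by plain bracketed bisection on
#' `[0, min(C, Nmax)]`. Kept deliberately simple (no closed form, no
#' derivatives) so it can serve as an oracle for [langmuir_coverage()].
#'
#' @inheritParams langmuir_coverage
#' @param tol Absolute tolerance on N (uM).
#' @return Adsorbed concentration N (uM), scalar.
#' @export
langmuir_coverage_oracle <- function(C_total, Nmax, K, tol = 1e-12) {
  check_nonneg(C_total, "C_total")
  check_pos(Nmax, "Nmax"); check_pos(K, "K"); check_pos(tol, "tol")
  stopifnot(length(C_total) == 1L)
  if (C_total == 0) return(0)
  W <- shg_constants$water_uM
  f <- function(N) N * W - K * (C_total - N) * (Nmax - N)
  lo <- 0; hi <- min(C_total, Nmax)
  if (f(lo) > 0 || f(hi) < 0)
    stop("bracket error: no sign change on [0, min(C, Nmax)]", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' SHG intensity of an adsorption isotherm point
#'
#' Observation model for the time-zero SHG intensity at total dye
#' concentration `C`:
#' `I(C) = A * (N/Nmax)^2 + alpha * M + B`,
#' where `N` is the depletion-corrected Langmuir coverage, the quadratic
#' coherent term reflects `I = E^2` with field proportional to surface
#' coverage, and the incoherent hyper-Rayleigh term is linear in the free
#' dye concentration `M = C - N` (or in total `C` when
#' `hrs_mode = "total"`, for sensitivity checks).
#'
#' @param C_total Total dye concentration (uM), >= 0. Vectorized.
#' @param params A [langmuir_params()] object.
#' @param hrs_mode `"free"` (default) uses `alpha * (C - N)`; `"total"`
#'   uses `alpha * C`.
#' @return Intensity in counts.
#' @export
isotherm_intensity <- function(C_total, params, hrs_mode = c("free", "total")) {
  stopifnot(inherits(params, "langmuir_params"))
  hrs_mode <- match.arg(hrs_mode)
  cov <- langmuir_coverage(C_total, params$Nmax, params$K)
  hrs_conc <- if (hrs_mode == "free") cov$M_free else cov$C_total
  params$A * (cov$N_adsorbed / params$Nmax)^2 + params$alpha * hrs_conc + params$B
}

#' Single-exponential field decay
#'
#' The SHG field during translocation follows
#' `E(t) = A0 + A1 * exp(-t / tau)`: the coherent field decays as dye
#' migrates to the inner leaflet and cancels, with `A0` the equilibrium
#' plateau and `tau` the transport time.
#'
#' @param t Time since dye addition (s), >= 0. Vectorized.
#' @param A0 Equilibrium field offset.
#' @param A1 Decaying field amplitude.
#' @param tau Transport time (s), > 0.
#' @return Field amplitude at `t`.
#' @export
field_decay <- function(t, A0, A1, tau) {
  check_nonneg(t, "t")
  check_finite(A0, "A0"); check_finite(A1, "A1")
  if (!is.finite(tau) || tau <= 0)
    stop("invalid parameter: `tau` must be > 0 and finite", call. = FALSE)
  A0 + A1 * exp(-t / tau)
}

#' Adsorption free energy from the equilibrium constant
#'
#' `deltaG = -R * T * ln(K)` in kcal/mol, with the water-referenced,
#' dimensionless `K` of the modified Langmuir model.
#'
#' @param K Dimensionless equilibrium constant, > 0. Vectorized.
#' @param T Absolute temperature (K), > 0. Defaults to
#'   `shg_constants$default_T` (293 K, ambient).
#' @return A list of class `thermo_result` with `delta_g` (kcal/mol),
#'   `K`, and `T`.
#' @export
adsorption_free_energy <- function(K, T = shg_constants$default_T) {
  check_pos(K, "K"); check_pos(T, "T")
  structure(list(delta_g = -shg_constants$R_kcal * T * log(K), K = K, T = T),
            class = "thermo_result")
}

#' Lipids per adsorption site
#'
#' Total lipid concentration divided by the maximum adsorption site
#' concentration: how many lipid molecules make up one adsorption site.
#'
#' @param lipid_uM Total lipid concentration (uM), > 0.
#' @param Nmax Maximum adsorption site concentration (uM), > 0.
#' @return Dimensionless ratio.
#' @export
lipids_per_site <- function(lipid_uM, Nmax) {
  check_pos(lipid_uM, "lipid_uM"); check_pos(Nmax, "Nmax")
  lipid_uM / Nmax
}

#' SHG signal per adsorbate surface coverage
#'
#' The ratio `A / Nmax^2` compares samples on the basis of SHG signal per
#' squared surface coverage; equal ratios indicate a similar adsorbate
#' angular distribution.
#'
#' @param A Saturation SHG intensity (counts).
#' @param Nmax Maximum adsorption site concentration (uM), > 0.
#' @return Ratio in counts * uM^-2.
#' @export
signal_per_coverage <- function(A, Nmax) {
  check_finite(A, "A"); check_pos(Nmax, "Nmax")
  A / Nmax^2
}
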