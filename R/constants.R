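#' Physical constants and unit conventions
#'
#' All solution concentrations in this package are in micromolar (uM).
#' The Langmuir equilibrium constant `K` is dimensionless because it is
#' referenced to the molarity of water; the reference enters the model as
#' `shg_constants$water_uM` = 55.5 M expressed in uM. Mixing mol/L with uM
#' is the dominant failure mode for this model, so a single unit is enforced
#' throughout.
#'
#' @format A list with components:
#' \describe{
#'   \item{R_kcal}{Gas constant, 1.98720425e-3 kcal mol^-1 K^-1.}
#'   \item{water_uM}{Molar concentration of water, 55.5e6 uM (55.5 M).}
#'   \item{default_T}{Default absolute temperature, 293 K (ambient).}
#' }
#' @export
shg_constants <- list(
  R_kcal    = 1.98720425e-3,
  water_uM  = 55.5e6,
  default_T = 293
)

# internal: scalar finiteness / domain checks with consistent messages
check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("invalid input: `", name, "` must be finite numeric", call. = FALSE)
  invisible(x)
}

check_nonneg <- function(x, name) {
  check_finite(x, name)
  if (any(x < 0))
    stop("invalid input: `", name, "` must be >= 0", call. = FALSE)
  invisible(x)
}

check_pos <- function(x, name) {
  check_finite(x, name)
  if (any(x <= 0))
    stop("invalid input: `", name, "` must be > 0", call. = FALSE)
  invisible(x)
}
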