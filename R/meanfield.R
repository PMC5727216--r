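#' Low-density-phase analytics of the l-TASEP
#'
#' Closed-form mean-field relations for the exclusion process with
#' particles of footprint `ell`, in the initiation-limited (low-density)
#' phase. All quantities are dimensionless: the initiation rate enters
#' as `alpha_bar = alpha/p` and the current as `J_bar = J/p`; multiply
#' by the elongation rate `p` to restore physical units.
#'
#' The low-density phase extends up to the critical initiation rate
#' `alpha_bar_c = 1/(1 + sqrt(ell))`, at which the density reaches
#' `rho* = 1/(sqrt(ell) (sqrt(ell) + 1))` — about 0.076 for `ell = 10`
#' — and the current is maximal. Termination never limits the dynamics
#' in this phase, so neither density nor current depends on `beta`.
#'
#' @param alpha_bar dimensionless initiation rate `alpha/p` (vectorised).
#' @param ell ribosome footprint in codons.
#' @return `rhoLD`: density in ribosomes/codon,
#'   `alpha_bar / (1 + (ell - 1) alpha_bar)`.
#' @examples
#' rhoLD(0.1, 10)        # 0.0526...
#' currentLD(0.1, 1)     # 0.09, the bare TASEP value
#' maxDensityLD(10)      # 0.076
#' @seealso [runSteadyState()] for the stochastic ground truth.
#' @export
rhoLD <- function(alpha_bar, ell = 10L) {
  checkAlphaBar(alpha_bar, ell)
  alpha_bar / (1 + (ell - 1) * alpha_bar)
}

#' @rdname rhoLD
#' @return `currentLD`: dimensionless current
#'   `alpha_bar (1 - alpha_bar) / (1 + (ell - 1) alpha_bar)`, identical
#'   to `currentOfDensity(rhoLD(alpha_bar))`.
#' @export
currentLD <- function(alpha_bar, ell = 10L) {
  checkAlphaBar(alpha_bar, ell)
  alpha_bar * (1 - alpha_bar) / (1 + (ell - 1) * alpha_bar)
}

#' @rdname rhoLD
#' @param rho ribosome density in ribosomes/codon, `0 <= rho <= 1/ell`.
#' @return `currentOfDensity`: the current-density relation
#'   `rho (1 - ell rho) / (1 - (ell - 1) rho)`.
#' @export
currentOfDensity <- function(rho, ell = 10L) {
  if (any(rho < 0 | rho > 1 / ell + 1e-12))
    stop("'rho' outside [0, 1/ell]")
  rho * (1 - ell * rho) / (1 - (ell - 1) * rho)
}

#' @rdname rhoLD
#' @return `maxDensityLD`: the density `1/(sqrt(ell) (sqrt(ell) + 1))`
#'   at which the current is maximal; the upper bound of the
#'   low-density-phase density.
#' @export
maxDensityLD <- function(ell = 10L) {
  if (any(ell < 1)) stop("'ell' must be >= 1")
  1 / (sqrt(ell) * (sqrt(ell) + 1))
}

#' @rdname rhoLD
#' @return `alphaBarCritical`: the initiation rate
#'   `1/(1 + sqrt(ell))` at which the low-density phase ends.
#' @export
alphaBarCritical <- function(ell = 10L) {
  if (any(ell < 1)) stop("'ell' must be >= 1")
  1 / (1 + sqrt(ell))
}

checkAlphaBar <- function(alpha_bar, ell) {
  if (any(alpha_bar < 0))
    stop("'alpha_bar' must be >= 0")
  ac <- alphaBarCritical(ell)
  if (any(alpha_bar > ac + 1e-12))
    stop(sprintf(
      "alpha_bar = %g is above the low-density phase boundary %g for ell = %g",
      max(alpha_bar), ac, ell))
  invisible(TRUE)
}
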