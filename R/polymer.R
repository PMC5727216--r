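#' Polymer parameters of the transcript
#'
#' Parameters of the Gaussian-chain description of an mRNA whose
#' stiffness depends on its polysome state. All lengths are in codon
#' units with the fixed conversion 1 codon = 1 nm (the approximate
#' contour length of a codon), so values quoted in nm can be used
#' directly.
#'
#' @param l_p persistence length of the bare (ribosome-free) mRNA,
#'   codons; about 1 nm = 1 codon.
#' @param ell ribosome footprint, codons; sets the stiffness of covered
#'   segments.
#' @param d 5'-3' end separation in the circularised (closed-loop)
#'   state, codons/nm; the scale of the bridging protein complex
#'   (default 5 nm).
#' @param epsilon end-end interaction free energy in units of kT;
#'   negative favours circularisation. Default -8.3, a representative
#'   eukaryotic value.
#' @return An object of class `"polymer_params"`.
#' @examples
#' polymerParams()
#' @export
polymerParams <- function(l_p = 1, ell = 10L, d = 5, epsilon = -8.3) {
  if (l_p <= 0) stop("'l_p' must be > 0")
  if (d <= 0) stop("'d' must be > 0")
  ell <- as.integer(ell)
  if (is.na(ell) || ell < 1L) stop("'ell' must be an integer >= 1")
  structure(list(l_p = l_p, ell = ell, d = d, epsilon = epsilon),
            class = "polymer_params")
}

#' @export
print.polymer_params <- function(x, ...) {
  cat(sprintf(
    "polymer parameters: l_p = %g, ell = %d, d = %g codons (1 codon = 1 nm), epsilon = %g kT\n",
    x$l_p, x$ell, x$d, x$epsilon))
  invisible(x)
}

#' Effective persistence length of a loaded transcript
#'
#' Bound ribosomes stiffen the mRNA: the effective persistence length
#' interpolates between the bare value `l_p` and the footprint `ell`,
#' weighted by the covered fraction `f = rho * ell`:
#' `l_eff = f * ell + (1 - f) * l_p = ell^2 rho + (1 - rho ell) l_p`.
#' It equals `l_p` for an empty mRNA and reaches `ell` at the maximal
#' density `rho = 1/ell`.
#'
#' @param rho ribosome density, ribosomes/codon, in `[0, 1/ell]`
#'   (vectorised).
#' @param params a [polymerParams()] object.
#' @return Effective persistence length in codons.
#' @examples
#' effectivePersistence(0.05, polymerParams())  # 5.5
#' @export
effectivePersistence <- function(rho, params = polymerParams()) {
  stopifnot(inherits(params, "polymer_params"))
  if (any(rho < 0 | rho > 1 / params$ell + 1e-12))
    stop("'rho' outside [0, 1/ell]")
  params$ell^2 * rho + (1 - rho * params$ell) * params$l_p
}

#' Average 5'-3' end-to-end distance of a polysome
#'
#' Gaussian-chain estimate `R = sqrt(2 L l_eff)` with the
#' density-dependent persistence length of [effectivePersistence()]:
#' a heavily loaded transcript is stretched, an empty one collapses to
#' the bare-polymer value `sqrt(2 L l_p)`.
#'
#' @param L transcript length, codons (vectorised).
#' @inheritParams effectivePersistence
#' @return End-to-end distance in codons (= nm).
#' @examples
#' endToEnd(300, 0)          # sqrt(600) ~ 24.5 for the bare chain
#' endToEnd(300, 0.076)      # stretched by the ribosome load
#' @export
endToEnd <- function(L, rho, params = polymerParams()) {
  if (any(L <= 0)) stop("'L' must be > 0")
  sqrt(2 * L * effectivePersistence(rho, params))
}

#' Probability of the circularised (closed-loop) mRNA state
#'
#' Eukaryotic transcripts switch between an open conformation with
#' end-to-end distance `R` and a circularised one in which protein
#' bridging holds the ends at separation `d`. The occupancy of the
#' closed state follows a two-state Boltzmann weight,
#' `P_c = 1 / (1 + exp(dG))` with the free-energy gap (in kT)
#' `dG = log[(l_eff L / d^2)^{3/2} sqrt(4 pi / 3) - 1]
#'       + 2 pi^2 l_eff / L + epsilon`:
#' an entropic cost that grows with `L` against the contact energy
#' `epsilon`. Short or strongly bound transcripts are mostly closed;
#' long ones mostly open.
#'
#' When the bracketed factor is non-positive (conceivable only for
#' `d` comparable to the whole coil size) the closed state is taken to
#' be certain: `P_c = 1`, with a degenerate-geometry warning.
#'
#' @param L transcript length, codons (vectorised).
#' @param l_eff effective persistence length, codons (vectorised;
#'   typically from [effectivePersistence()]).
#' @inheritParams effectivePersistence
#' @return A list with components `P_c`, `P_o = 1 - P_c` and `dG` (kT;
#'   `-Inf` in the degenerate case).
#' @examples
#' circularisationProb(300, 1, polymerParams(epsilon = -8.3))$P_c  # ~0.978
#' @export
circularisationProb <- function(L, l_eff, params = polymerParams()) {
  stopifnot(inherits(params, "polymer_params"))
  if (any(L <= 0)) stop("'L' must be > 0")
  if (any(l_eff <= 0)) stop("'l_eff' must be > 0")
  bracket <- (l_eff * L / params$d^2)^(3 / 2) * sqrt(4 * pi / 3) - 1
  dG <- ifelse(bracket > 0,
               log(pmax(bracket, .Machine$double.xmin)) +
                 2 * pi^2 * l_eff / L + params$epsilon,
               -Inf)
  if (any(bracket <= 0))
    warning("degenerate geometry (d comparable to coil size); P_c set to 1")
  P_c <- 1 / (1 + exp(dG))
  list(P_c = P_c, P_o = 1 - P_c, dG = dG)
}

#' Circularisation-weighted end-to-end distance
#'
#' Average of the open-state distance `R` and the closed-state
#' separation `d`, weighted by the state probabilities:
#' `R_circ = P_o R + P_c d`.
#'
#' @param R open-state end-to-end distance, codons (vectorised).
#' @param P_c circularisation probability in `[0, 1]`.
#' @inheritParams effectivePersistence
#' @return Weighted end-to-end distance in codons.
#' @examples
#' endToEndCirc(24.49, 0.5, polymerParams(d = 5))  # 14.745
#' @export
endToEndCirc <- function(R, P_c, params = polymerParams()) {
  stopifnot(inherits(params, "polymer_params"))
  if (any(P_c < 0 | P_c > 1)) stop("'P_c' must be in [0, 1]")
  (1 - P_c) * R + P_c * params$d
}
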