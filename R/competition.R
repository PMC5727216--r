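#' Sweep ribosome-pool concentration and compute competition effects
#'
#' Solves the recycling model over a grid of transcript lengths for
#' several free-ribosome pool sizes. Pool changes enter through the
#' background term only (`alpha_bar_inf -> f * alpha_bar_inf`): the
#' recycling term is fed by the transcript's own terminating ribosomes
#' and is pool-independent. Because short transcripts draw mostly on
#' recycling while long ones depend on the pool, shrinking the pool
#' favours short transcripts; the relative expression
#' `eta(L1, L2) = J_L1 / J_L2` quantifies this and tends to 1 as
#' resources become abundant.
#'
#' @param lengths transcript lengths in codons.
#' @param c_factors positive multipliers of the baseline pool
#'   concentration (default `c(0.25, 0.5, 1, 2, 4)`).
#' @param params baseline [feedbackParams()].
#' @return An object of class `"competition_sweep"`: list with matrices
#'   `rho` and `J_bar` (`length(lengths)` x `length(c_factors)`,
#'   dimnames set), a matching `converged` logical matrix, and the
#'   input grids.
#' @examples
#' sw <- competitionSweep(c(100, 500, 2500))
#' relativeExpression(sw, 100, 2500)
#' @export
competitionSweep <- function(lengths, c_factors = c(0.25, 0.5, 1, 2, 4),
                             params = feedbackParams()) {
  if (!length(lengths)) stop("'lengths' must be non-empty")
  if (any(c_factors <= 0)) stop("'c_factors' must be positive")
  nL <- length(lengths); nF <- length(c_factors)
  rho <- J <- matrix(NA_real_, nL, nF,
                     dimnames = list(as.character(lengths),
                                     as.character(c_factors)))
  conv <- matrix(NA, nL, nF, dimnames = dimnames(rho))
  for (j in seq_len(nF)) {
    pj <- params
    pj$c_inf_factor <- params$c_inf_factor * c_factors[j]
    cur <- densityLengthCurve(lengths, pj)
    rho[, j] <- cur$rho
    J[, j] <- cur$J_bar
    conv[, j] <- cur$converged
  }
  structure(list(lengths = lengths, c_factors = c_factors, rho = rho,
                 J_bar = J, converged = conv, params = params),
            class = "competition_sweep")
}

#' @rdname competitionSweep
#' @param sweep a `"competition_sweep"` object.
#' @param L1,L2 two lengths present in the sweep grid.
#' @return `relativeExpression`: named vector of
#'   `eta = J_bar(L1) / J_bar(L2)` over the pool factors.
#' @export
relativeExpression <- function(sweep, L1, L2) {
  stopifnot(inherits(sweep, "competition_sweep"))
  i1 <- match(L1, sweep$lengths); i2 <- match(L2, sweep$lengths)
  if (is.na(i1) || is.na(i2))
    stop("L1/L2 must be members of the sweep's length grid")
  sweep$J_bar[i1, ] / sweep$J_bar[i2, ]
}

#' @export
print.competition_sweep <- function(x, ...) {
  cat(sprintf("competition sweep: %d lengths x %d pool factors\n",
              length(x$lengths), length(x$c_factors)))
  cat("densities (ribosomes/codon):\n")
  print(signif(x$rho, 3))
  invisible(x)
}

#' Monosome:polysome ratio of a transcript
#'
#' Estimates, from the time-weighted occupancy distribution of the
#' stochastic simulator, the ratio of time spent as a monosome (exactly
#' one bound ribosome) to time spent as a polysome (two or more),
#' conditioned on the mRNA carrying at least one ribosome — the
#' experimental definition among ribosome-bound transcripts. Over a
#' length sweep at fitted-scale parameters the ratio falls with `L` in
#' a power-law-like fashion.
#'
#' @param L transcript length, codons.
#' @param params a [feedbackParams()] object; the initiation rate is
#'   the analytic fixed point [solveAlpha()] at this length.
#' @param rates a [kineticRates()] object supplying `p`, `beta`,
#'   `delta`, `ell` (the `alpha` slot is overridden).
#' @param seed integer seed.
#' @param tSample sampling time, s; must be long enough that both
#'   monosome and polysome states are visited.
#' @return List with `ratio` (may be `Inf`), `P_mono`, `P_poly`
#'   (probabilities conditioned on `N >= 1`), `stable` (logical; both
#'   states observed for at least 1% of the bound time) and the
#'   underlying `steady_state` object.
#' @examples
#' \donttest{
#' monosomePolysomeRatio(300, seed = 1)$ratio
#' }
#' @export
monosomePolysomeRatio <- function(L, params = feedbackParams(),
                                  rates = kineticRates(
                                    alpha = 0, p = 10,
                                    ell = params$polymer$ell),
                                  seed, tSample = 2e4) {
  if (missing(seed)) stop("'seed' is required for reproducibility")
  sol <- solveAlpha(L, params)
  run_rates <- kineticRates(alpha = sol$alpha_bar * rates$p, p = rates$p,
                            beta = rates$beta, delta = rates$delta,
                            ell = rates$ell)
  ss <- runSteadyState(L, run_rates, tSample = tSample, seed = seed)
  h <- ss$N_hist
  p_bound <- sum(h[-1L])
  if (p_bound <= 0)
    return(list(ratio = NA_real_, P_mono = NA_real_, P_poly = NA_real_,
                stable = FALSE, steady_state = ss))
  P_mono <- h[["1"]] / p_bound
  P_poly <- sum(h[-(1:2)]) / p_bound
  ratio <- if (P_poly > 0) P_mono / P_poly else Inf
  list(ratio = ratio, P_mono = P_mono, P_poly = P_poly,
       stable = is.finite(ratio) && P_mono > 0.01 && P_poly > 0.01,
       steady_state = ss)
}
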