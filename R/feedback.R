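#' Parameters of the ribosome-recycling feedback on initiation
#'
#' The initiation rate of a transcript is set by the local concentration
#' of free ribosomal subunits near its 5' end. Subunits terminating at
#' the 3' end diffuse back and are recycled, which couples initiation to
#' the protein production current `J` and to the 5'-3' end-to-end
#' distance `R` of the polysome:
#' `alpha_bar = alpha_bar_inf + lam * J_bar / R`.
#' `alpha_bar_inf` is the feedback-free (background-pool) initiation
#' rate; `lam` is the separation (in codons = nm) below which recycling
#' matters. Three variants of the denominator are supported:
#' \describe{
#'   \item{`plain`}{`R` from the open-chain polymer model
#'     ([endToEnd()]);}
#'   \item{`circularised`}{the closed-loop-weighted distance
#'     ([endToEndCirc()]), with `P_c` from [circularisationProb()];}
#'   \item{`two_subunit`}{independent diffusion of the two ribosomal
#'     subunits gives an `R^2` denominator with coefficient `lam2`
#'     (codons^2).}
#' }
#'
#' Defaults are the representative circular-model working point
#' `alpha_bar_inf = 4.7e-3`, `lam = 7` codons, `epsilon = -8.3` kT,
#' `d = 5` nm.
#'
#' @param alpha_bar_inf dimensionless background initiation rate
#'   (`alpha_inf / p`).
#' @param lam feedback strength, codons.
#' @param variant `"plain"`, `"circularised"` or `"two_subunit"`.
#' @param lam2 feedback strength of the two-subunit variant, codons^2;
#'   defaults to `lam^2` (a free phenomenological parameter).
#' @param polymer a [polymerParams()] object (carries `ell`).
#' @param c_inf_factor multiplier on the free-subunit pool
#'   concentration; rescales `alpha_bar_inf` only, since the recycling
#'   term is pool-independent. Used for competition sweeps.
#' @return An object of class `"feedback_params"`.
#' @examples
#' feedbackParams(variant = "circularised")
#' @export
feedbackParams <- function(alpha_bar_inf = 4.7e-3, lam = 7,
                           variant = c("plain", "circularised",
                                       "two_subunit"),
                           lam2 = lam^2, polymer = polymerParams(),
                           c_inf_factor = 1) {
  variant <- match.arg(variant)
  stopifnot(inherits(polymer, "polymer_params"))
  if (alpha_bar_inf < 0) stop("'alpha_bar_inf' must be >= 0")
  if (lam < 0) stop("'lam' must be >= 0")
  if (lam2 < 0) stop("'lam2' must be >= 0")
  if (c_inf_factor <= 0) stop("'c_inf_factor' must be > 0")
  structure(list(alpha_bar_inf = alpha_bar_inf, lam = lam,
                 variant = variant, lam2 = lam2, polymer = polymer,
                 c_inf_factor = c_inf_factor),
            class = "feedback_params")
}

#' @export
print.feedback_params <- function(x, ...) {
  cat(sprintf(
    "recycling feedback (%s): alpha_bar_inf = %g, lambda = %g codons%s%s\n",
    x$variant, x$alpha_bar_inf, x$lam,
    if (x$variant == "two_subunit") sprintf(", lambda2 = %g codons^2", x$lam2)
    else "",
    if (x$c_inf_factor != 1) sprintf(", pool x %g", x$c_inf_factor) else ""))
  print(x$polymer)
  invisible(x)
}

# the feedback map F(alpha_bar) = alpha_bar_inf * c + lam * J / R_eff;
# vectorised over alpha_bar. Returns the full evaluation so callers can
# reuse rho, J, R, P_c.
feedbackMap <- function(alpha_bar, L, params) {
  ell <- params$polymer$ell
  rho <- rhoLD(alpha_bar, ell)
  J_bar <- currentLD(alpha_bar, ell)
  R <- endToEnd(L, rho, params$polymer)
  P_c <- rep(NA_real_, length(alpha_bar))
  a0 <- params$alpha_bar_inf * params$c_inf_factor
  if (params$variant == "circularised") {
    l_eff <- effectivePersistence(rho, params$polymer)
    P_c <- circularisationProb(L, l_eff, params$polymer)$P_c
    R_eff <- endToEndCirc(R, P_c, params$polymer)
    Fab <- a0 + params$lam * J_bar / R_eff
  } else if (params$variant == "two_subunit") {
    R_eff <- R
    Fab <- a0 + params$lam2 * J_bar / R^2
  } else {
    R_eff <- R
    Fab <- a0 + params$lam * J_bar / R
  }
  list(F = Fab, rho = rho, J_bar = J_bar, R = R_eff, P_c = P_c)
}

#' Solve the self-consistent initiation rate of one transcript
#'
#' Finds the fixed point `alpha_bar*` of the implicit recycling
#' equation `alpha_bar = alpha_bar_inf + lam * J(alpha_bar) /
#' R(alpha_bar, L)`, using the low-density-phase analytics for
#' `J(alpha_bar)` and the polymer model for `R`. The smallest fixed
#' point in `[alpha_bar_inf, alpha_bar_c]` is returned — the one
#' reachable from the feedback-off initial condition — located by a
#' grid scan for the first sign change followed by bisection, then
#' polished by fixed-point iteration to a relative residual below
#' 1e-9.
#'
#' If the feedback map stays above the identity all the way to the
#' phase boundary `alpha_bar_c = 1/(1 + sqrt(ell))`, the transcript
#' leaves the low-density phase; the solution is then clamped at the
#' boundary and flagged `converged = FALSE` with a warning.
#'
#' @param L transcript length, codons (`L >= ell`).
#' @param params a [feedbackParams()] object.
#' @return An object of class `"feedback_solution"`: list with
#'   `alpha_bar`, `rho`, `J_bar`, `R` (effective end-to-end distance
#'   used in the feedback, codons), `P_c` (`NA` unless circularised),
#'   `converged`, `n_iter`.
#' @examples
#' sol <- solveAlpha(500, feedbackParams())
#' c(sol$alpha_bar, sol$rho)
#' @export
solveAlpha <- function(L, params = feedbackParams()) {
  stopifnot(inherits(params, "feedback_params"))
  ell <- params$polymer$ell
  if (L < ell) stop("need L >= ell")
  ac <- alphaBarCritical(ell)
  a0 <- params$alpha_bar_inf * params$c_inf_factor

  finish <- function(ab, converged, n_iter) {
    ev <- feedbackMap(ab, L, params)
    structure(list(alpha_bar = ab, rho = ev$rho, J_bar = ev$J_bar,
                   R = ev$R, P_c = ev$P_c, converged = converged,
                   n_iter = n_iter, L = L, params = params),
              class = "feedback_solution")
  }

  if (a0 >= ac) {
    warning("background initiation alone exceeds the low-density phase; clamped")
    return(finish(ac, FALSE, 0L))
  }
  if (params$lam == 0 && params$variant != "two_subunit")
    return(finish(a0, TRUE, 0L))
  if (params$variant == "two_subunit" && params$lam2 == 0)
    return(finish(a0, TRUE, 0L))
  if (a0 == 0)                          # J(0) = 0: feedback has no seed
    return(finish(0, TRUE, 0L))

  g <- function(ab) feedbackMap(ab, L, params)$F - ab

  grid <- seq(a0, ac, length.out = 256L)
  gv <- g(grid)
  idx <- which(gv <= 0)
  if (!length(idx)) {
    warning(sprintf(
      "no fixed point below the phase boundary for L = %g; clamped at alpha_bar_c", L))
    return(finish(ac, FALSE, 0L))
  }
  i <- idx[1L]
  if (gv[i] == 0) {
    ab <- grid[i]
  } else if (i == 1L) {
    ab <- grid[1L]                      # g(a0) <= 0 only when lam J = 0
  } else {
    ab <- stats::uniroot(g, c(grid[i - 1L], grid[i]),
                         tol = .Machine$double.eps^0.75)$root
  }

  # polish: the smallest root is stable under the forward map
  n_iter <- 0L
  repeat {
    Fab <- min(feedbackMap(ab, L, params)$F, ac)
    n_iter <- n_iter + 1L
    if (ab > 0 && abs(Fab - ab) / ab < 1e-9) { ab <- Fab; break }
    ab <- Fab
    if (n_iter >= 200L) break
  }
  finish(min(ab, ac), n_iter <= 200L, n_iter)
}

#' @export
print.feedback_solution <- function(x, ...) {
  cat(sprintf(
    "feedback solution (L = %g, %s): alpha_bar = %.5g, rho = %.5g, J_bar = %.5g, R = %.4g%s%s\n",
    x$L, x$params$variant, x$alpha_bar, x$rho, x$J_bar, x$R,
    if (!is.na(x$P_c)) sprintf(", P_c = %.3g", x$P_c) else "",
    if (!x$converged) "  [clamped at phase boundary]" else ""))
  invisible(x)
}

#' Density, current and end-to-end distance along a length sweep
#'
#' Vectorised [solveAlpha()]: solves the recycling equation for every
#' requested transcript length and tabulates the results. Solver
#' clamps (lengths pushed out of the low-density phase) are flagged in
#' the `converged` column, and the sweep continues.
#'
#' @param lengths transcript lengths in codons (non-empty).
#' @inheritParams solveAlpha
#' @return A data frame with columns `L`, `alpha_bar`, `rho`, `J_bar`,
#'   `R`, `P_c`, `converged`, in the input order.
#' @examples
#' densityLengthCurve(c(100, 500, 2500), feedbackParams())
#' @export
densityLengthCurve <- function(lengths, params = feedbackParams()) {
  if (!length(lengths)) stop("'lengths' must be non-empty")
  rows <- lapply(lengths, function(L) {
    s <- tryCatch(solveAlpha(L, params), error = function(e) NULL)
    if (is.null(s))
      return(data.frame(L = L, alpha_bar = NA_real_, rho = NA_real_,
                        J_bar = NA_real_, R = NA_real_, P_c = NA_real_,
                        converged = FALSE))
    data.frame(L = L, alpha_bar = s$alpha_bar, rho = s$rho,
               J_bar = s$J_bar, R = s$R, P_c = s$P_c,
               converged = s$converged)
  })
  do.call(rbind, rows)
}

#' Self-consistent stochastic solution of the recycling feedback
#'
#' Stochastic counterpart of [solveAlpha()] that replaces the
#' mean-field current by kinetic Monte Carlo measurements, thereby
#' including finite-size effects and, optionally, ribosome drop-off:
#' \enumerate{
#'   \item simulate the l-TASEP at the current initiation rate
#'     `alpha^(i)` to steady state and measure `J^(i)` and `rho^(i)`;
#'   \item compute the end-to-end distance from `rho^(i)` and update
#'     `alpha^(i+1)` from the recycling equation;
#'   \item repeat until `|alpha^(i) - alpha^(i-1)| / alpha^(i) < tol`
#'     (default 0.01); typically fewer than 10 iterations;
#'   \item run a final production simulation at the converged rate.
#' }
#'
#' @inheritParams solveAlpha
#' @param rates a [kineticRates()] object supplying `p`, `beta`,
#'   `delta` and `ell` (its `alpha` slot is ignored; the scheme sets
#'   it). `ell` must match `params$polymer$ell`.
#' @param tol relative convergence tolerance on `alpha` (default 0.01).
#' @param seed integer seed for the whole scheme.
#' @param maxIter iteration cap (default 50).
#' @param tSampleIter sampling time (s) per iteration.
#' @param tSampleFinal sampling time (s) of the production run.
#' @return An object of class `"feedback_solution"` with the measured
#'   `rho` and `J_bar`, the converged `alpha_bar`, `n_iter` (number of
#'   alpha updates until the stopping rule fired), `converged`, and an
#'   `alpha_trace` attribute-like list element with the iterates.
#' @examples
#' \donttest{
#' sc <- selfConsistentSim(500, feedbackParams(),
#'                         kineticRates(alpha = 0, p = 10), seed = 1)
#' sc$n_iter
#' }
#' @export
selfConsistentSim <- function(L, params = feedbackParams(),
                              rates = kineticRates(alpha = 0, p = 10,
                                                   ell = params$polymer$ell),
                              tol = 0.01, seed, maxIter = 50L,
                              tSampleIter = 2e4, tSampleFinal = 4e4) {
  stopifnot(inherits(params, "feedback_params"),
            inherits(rates, "kinetic_rates"))
  if (tol <= 0) stop("'tol' must be > 0")
  if (missing(seed)) stop("'seed' is required for reproducibility")
  if (rates$ell != params$polymer$ell)
    stop("footprint mismatch between rates and polymer parameters")
  p <- rates$p
  if (p <= 0) stop("elongation rate must be > 0")
  a0 <- params$alpha_bar_inf * params$c_inf_factor

  # derive per-iteration seeds from one base seed
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, maxIter + 1L)

  updateAlpha <- function(rho, J_bar) {
    R <- endToEnd(L, min(rho, 1 / rates$ell), params$polymer)
    if (params$variant == "circularised") {
      l_eff <- effectivePersistence(min(rho, 1 / rates$ell), params$polymer)
      P_c <- circularisationProb(L, l_eff, params$polymer)$P_c
      list(ab = a0 + params$lam * J_bar / endToEndCirc(R, P_c, params$polymer),
           R = endToEndCirc(R, P_c, params$polymer), P_c = P_c)
    } else if (params$variant == "two_subunit") {
      list(ab = a0 + params$lam2 * J_bar / R^2, R = R, P_c = NA_real_)
    } else {
      list(ab = a0 + params$lam * J_bar / R, R = R, P_c = NA_real_)
    }
  }

  ab <- a0                     # feedback-off initial condition
  trace <- ab
  converged <- FALSE
  n_iter <- 0L
  R_eff <- endToEnd(L, rhoLD(min(ab, alphaBarCritical(rates$ell)),
                             rates$ell), params$polymer)
  P_c <- NA_real_
  for (i in seq_len(maxIter)) {
    it_rates <- kineticRates(alpha = ab * p, p = p, beta = rates$beta,
                             delta = rates$delta, ell = rates$ell)
    # iteration runs only need ~1% precision on J; silence the
    # half-window stationarity chatter here (the production run keeps it)
    ss <- withCallingHandlers(
      runSteadyState(L, it_rates, tSample = tSampleIter, seed = seeds[i]),
      warning = function(w) {
        if (grepl("window halves", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    up <- updateAlpha(ss$rho, ss$J_bar)
    n_iter <- i
    ab_new <- up$ab
    R_eff <- up$R
    P_c <- up$P_c
    rel <- abs(ab_new - ab) / ab_new
    ab <- ab_new
    trace <- c(trace, ab)
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("self-consistent scheme not converged after %d iterations",
                    maxIter))

  fin_rates <- kineticRates(alpha = ab * p, p = p, beta = rates$beta,
                            delta = rates$delta, ell = rates$ell)
  fin <- runSteadyState(L, fin_rates, tSample = tSampleFinal,
                        seed = seeds[maxIter + 1L])

  structure(list(alpha_bar = ab, rho = fin$rho, J_bar = fin$J_bar,
                 R = R_eff, P_c = P_c, converged = converged,
                 n_iter = n_iter, alpha_trace = trace, L = L,
                 params = params, production = fin),
            class = "feedback_solution")
}

#' Back-of-envelope magnitude of the recycling concentration boost
#'
#' The recycling source raises the free-subunit concentration near the
#' 5' end by `delta_R ~ J / (D R)`, with `J` the protein production
#' rate, `D` the subunit diffusion coefficient and `R` the end-to-end
#' distance. This helper computes the interval spanned by
#' `delta_R / c_inf` over given ranges of `J` and of the background
#' concentration, for a transcript of length `L` (the scaling form has
#' an undetermined O(1) prefactor, so only the order of magnitude is
#' meaningful).
#'
#' @param J_range range of production rates, proteins/s.
#' @param D subunit diffusion coefficient, um^2/s (default 0.04).
#' @param L transcript length, codons.
#' @param c_inf_range range of background free-subunit concentrations,
#'   subunits/um^3.
#' @param rho ribosome density used for the end-to-end distance
#'   (default 0: bare chain).
#' @param params a [polymerParams()] object.
#' @return List with `R_um` (end-to-end distance in um), `delta_R_range`
#'   (um^-3) and `ratio_range` (= `delta_R / c_inf`, dimensionless).
#' @examples
#' recyclingRegime()$ratio_range   # spans roughly 0.1 - 20
#' @export
recyclingRegime <- function(J_range = c(0.1, 10), D = 0.04, L = 300,
                            c_inf_range = c(500, 1000), rho = 0,
                            params = polymerParams()) {
  stopifnot(all(J_range > 0), D > 0, all(c_inf_range > 0))
  R_um <- endToEnd(L, rho, params) * 1e-3   # 1 codon = 1 nm = 1e-3 um
  dR <- sort(J_range / (D * R_um))
  ratio <- c(dR[1] / max(c_inf_range), dR[2] / min(c_inf_range))
  list(R_um = R_um, delta_R_range = dR, ratio_range = ratio)
}
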