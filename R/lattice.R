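#' Kinetic rate set for the l-TASEP translation model
#'
#' Bundles the four rate constants and the ribosome footprint used by the
#' simulator. Rates are in physical units; the analytic layer works with
#' the dimensionless initiation rate `alpha/p`.
#'
#' @param alpha initiation rate (1/s): attempted ribosome entry at the 5'
#'   end, realised only when the first `ell` codons are vacant.
#' @param p elongation rate (codons/s), uniform along the transcript.
#' @param beta termination rate (1/s) for a ribosome whose A-site sits on
#'   the last codon. Defaults to `p`: termination is not limiting in the
#'   low-density phase, so density and current do not depend on it.
#' @param delta drop-off rate (1/s per bound ribosome); 0 disables
#'   premature detachment. The biologically estimated scale is
#'   1e-4/codon x 10 codons/s = 1e-3/s.
#' @param ell ribosome footprint in codons (default 10, ~28 nt).
#'
#' @return An object of class `"kinetic_rates"`.
#' @examples
#' kineticRates(alpha = 0.5, p = 10)
#' @export
kineticRates <- function(alpha, p = 10, beta = p, delta = 0, ell = 10L) {
  stopifnot(is.numeric(alpha), is.numeric(p), is.numeric(beta),
            is.numeric(delta), length(alpha) == 1L, length(p) == 1L)
  if (alpha < 0 || p < 0 || beta < 0 || delta < 0)
    stop("all rates must be non-negative")
  ell <- as.integer(ell)
  if (is.na(ell) || ell < 1L) stop("'ell' must be an integer >= 1")
  structure(list(alpha = alpha, p = p, beta = beta, delta = delta,
                 ell = ell),
            class = "kinetic_rates")
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat("l-TASEP kinetic rates\n")
  cat(sprintf("  initiation  alpha = %g /s  (alpha/p = %g)\n",
              x$alpha, if (x$p > 0) x$alpha / x$p else NA_real_))
  cat(sprintf("  elongation  p     = %g codons/s\n", x$p))
  cat(sprintf("  termination beta  = %g /s\n", x$beta))
  cat(sprintf("  drop-off    delta = %g /s per ribosome\n", x$delta))
  cat(sprintf("  footprint   ell   = %d codons\n", x$ell))
  invisible(x)
}

#' Create an empty elongation lattice
#'
#' The lattice records the occupancy state of one transcript: the A-site
#' codon of every bound ribosome (1-based, ascending 5' to 3'), the
#' footprint, and the simulation clock. A ribosome with A-site at codon
#' `i` covers codons `i .. i + ell - 1`; successive A-sites therefore
#' differ by at least `ell`.
#'
#' @param L transcript length in codons.
#' @param ell ribosome footprint in codons.
#' @return An object of class `"elongation_lattice"` with fields `L`,
#'   `ell`, `positions` (integer vector, initially empty) and `t` (s).
#' @examples
#' lat <- initLattice(300, 10)
#' ribosomeCount(lat)       # 0
#' @export
initLattice <- function(L, ell = 10L) {
  L <- as.integer(L); ell <- as.integer(ell)
  if (is.na(ell) || ell < 1L) stop("'ell' must be an integer >= 1")
  if (is.na(L) || L < ell)
    stop("invalid transcript: need L >= ell (got L = ", L,
         ", ell = ", ell, ")")
  structure(list(L = L, ell = ell, positions = integer(0), t = 0),
            class = "elongation_lattice")
}

#' @rdname initLattice
#' @param lattice an `"elongation_lattice"`.
#' @export
ribosomeCount <- function(lattice) length(lattice$positions)

#' @export
print.elongation_lattice <- function(x, ...) {
  cat(sprintf("elongation lattice: L = %d codons, ell = %d, %d ribosome(s), t = %.4g s\n",
              x$L, x$ell, length(x$positions), x$t))
  if (length(x$positions))
    cat("  A-sites:", paste(utils::head(x$positions, 25L), collapse = " "),
        if (length(x$positions) > 25L) "..." else "", "\n")
  invisible(x)
}

validateLattice <- function(lattice) {
  p <- lattice$positions
  if (length(p)) {
    stopifnot(all(p >= 1L), all(p <= lattice$L))
    if (length(p) > 1L && any(diff(p) < lattice$ell))
      stop("exclusion violated: A-sites closer than the footprint")
  }
  invisible(lattice)
}

#' Enumerate enabled transitions of a lattice configuration
#'
#' Lists every kinetic event currently possible together with its rate:
#' initiation (codons `1..ell` all vacant), elongation of each unblocked
#' ribosome, termination (A-site on the last codon) and drop-off of each
#' bound ribosome when `delta > 0`.
#'
#' @param lattice an `"elongation_lattice"`.
#' @param rates a [kineticRates()] object (its `ell` must match).
#' @return A data frame with columns `type` (one of `"init"`, `"step"`,
#'   `"term"`, `"drop"`), `ribosome` (index into `positions`, `NA` for
#'   initiation) and `rate`.
#' @examples
#' lat <- initLattice(300, 10)
#' enabledEvents(lat, kineticRates(alpha = 0.1))  # initiation only
#' @export
enabledEvents <- function(lattice, rates) {
  stopifnot(inherits(lattice, "elongation_lattice"),
            inherits(rates, "kinetic_rates"))
  if (rates$ell != lattice$ell)
    stop("footprint mismatch between lattice and rates")
  pos <- lattice$positions
  n <- length(pos)
  ev <- list()
  if (rates$alpha > 0 && (n == 0L || pos[1L] > lattice$ell))
    ev[[length(ev) + 1L]] <- data.frame(type = "init", ribosome = NA_integer_,
                                        rate = rates$alpha)
  if (n > 0L && rates$p > 0) {
    gap_ok <- c(if (n > 1L) diff(pos) > lattice$ell, TRUE)
    movable <- which(pos < lattice$L & gap_ok)
    if (length(movable))
      ev[[length(ev) + 1L]] <- data.frame(type = "step", ribosome = movable,
                                          rate = rates$p)
  }
  if (n > 0L && pos[n] == lattice$L && rates$beta > 0)
    ev[[length(ev) + 1L]] <- data.frame(type = "term", ribosome = n,
                                        rate = rates$beta)
  if (n > 0L && rates$delta > 0)
    ev[[length(ev) + 1L]] <- data.frame(type = "drop", ribosome = seq_len(n),
                                        rate = rates$delta)
  if (!length(ev))
    return(data.frame(type = character(0), ribosome = integer(0),
                      rate = numeric(0)))
  do.call(rbind, ev)
}

#' Execute one Gillespie event on a lattice
#'
#' Reference (pure-R) implementation of one step of the kinetic Monte
#' Carlo: draws an exponential waiting time with the total enabled rate,
#' picks one enabled event with probability proportional to its rate,
#' and applies it. The compiled [runSteadyState()] engine implements the
#' same dynamics for long runs; this stepper is the inspectable surface
#' used for unit checks and small-scale cross-validation.
#'
#' Uses R's global RNG: call `set.seed()` beforehand for reproducibility.
#'
#' @inheritParams enabledEvents
#' @return A list with elements `lattice` (updated state), `event` (the
#'   executed row of [enabledEvents()]) and `dt` (waiting time, s).
#'   Signals a condition of class `"riboloop_absorbing_state"` when no
#'   event is enabled (empty lattice with `alpha = 0`).
#' @examples
#' set.seed(1)
#' st <- gillespieStep(initLattice(300, 10), kineticRates(alpha = 0.1))
#' st$lattice$positions  # ribosome placed at codon 1
#' @export
gillespieStep <- function(lattice, rates) {
  ev <- enabledEvents(lattice, rates)
  if (!nrow(ev))
    stop(structure(class = c("riboloop_absorbing_state", "error", "condition"),
                   list(message = "no enabled event: absorbing state",
                        call = sys.call())))
  total <- sum(ev$rate)
  dt <- stats::rexp(1L, total)
  k <- if (nrow(ev) == 1L) 1L else
    sample.int(nrow(ev), 1L, prob = ev$rate)
  pos <- lattice$positions
  switch(ev$type[k],
         init = { pos <- c(1L, pos) },
         step = { pos[ev$ribosome[k]] <- pos[ev$ribosome[k]] + 1L },
         term = { pos <- pos[-length(pos)] },
         drop = { pos <- pos[-ev$ribosome[k]] })
  lattice$positions <- pos
  lattice$t <- lattice$t + dt
  validateLattice(lattice)
  list(lattice = lattice, event = ev[k, , drop = FALSE], dt = dt)
}
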