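#' Read a ribosome density versus CDS-length table
#'
#' Reads delimited text (TSV or CSV, auto-detected from the file
#' extension unless `sep` is given) with one row per gene or per length
#' bin. The table must name a length column and a density column in its
#' header; column names are matched case-insensitively against common
#' spellings (`length`, `length_codons`, `L`, `cds_length`; `density`,
#' `rho`, `density_ribosomes_per_codon`; `sd`, `se`, `stdev`; `gene_id`,
#' `gene`, `id`; `n`, `count`). Lengths quoted in nucleotides and
#' densities quoted per nucleotide or per 100 nt are converted to codon
#' units.
#'
#' Rows with non-numeric or non-positive lengths, or non-numeric
#' densities, are dropped with a warning that reports their line
#' numbers; densities outside `[0, 1]` ribosomes/codon raise an error
#' (per-codon density cannot exceed 1). Densities above the steric bound
#' `1/ell` are *not* rejected here — measurement noise can exceed the
#' theoretical bound — but [fitParams()] flags them.
#'
#' @param path path to the delimited text file.
#' @param lengthUnit `"codons"` (default) or `"nt"` (divided by 3).
#' @param densityUnit `"per_codon"` (default), `"per_nt"` (multiplied by
#'   3) or `"per_100nt"` (multiplied by 3/100).
#' @param sep field separator; `NULL` chooses `","` for `.csv` and tab
#'   otherwise.
#' @return A data frame of class `"density_length"` with columns
#'   `gene_id` (may be `NA`), `L` (codons), `rho` (ribosomes/codon),
#'   `sd` (may be `NA`) and `n` (may be `NA`).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(data.frame(length_codons = c(100, 300, 900),
#'                        density = c(0.03, 0.02, 0.01)),
#'             tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' readDensityTable(tf)
#' @export
readDensityTable <- function(path, lengthUnit = c("codons", "nt"),
                             densityUnit = c("per_codon", "per_nt",
                                             "per_100nt"),
                             sep = NULL) {
  lengthUnit <- match.arg(lengthUnit)
  densityUnit <- match.arg(densityUnit)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "#"),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e)))
  if (!nrow(tab) || !ncol(tab)) stop("empty table: ", path)

  findCol <- function(cands) {
    hit <- which(tolower(names(tab)) %in% cands)
    if (length(hit)) hit[1L] else NA_integer_
  }
  iL <- findCol(c("length", "length_codons", "l", "cds_length",
                  "length_nt"))
  iR <- findCol(c("density", "rho", "density_ribosomes_per_codon",
                  "ribosome_density"))
  if (is.na(iL) || is.na(iR))
    stop("schema error: need a length column and a density column; found: ",
         paste(names(tab), collapse = ", "))
  iS <- findCol(c("sd", "se", "stdev", "sd_rho"))
  iG <- findCol(c("gene_id", "gene", "id"))
  iN <- findCol(c("n", "count", "n_genes"))

  L <- suppressWarnings(as.numeric(tab[[iL]]))
  rho <- suppressWarnings(as.numeric(tab[[iR]]))
  bad <- which(is.na(L) | is.na(rho) | L <= 0)
  if (length(bad)) {
    warning("dropping ", length(bad), " malformed row(s) at line(s): ",
            paste(bad + 1L, collapse = ", "))   # +1 for the header line
    L <- L[-bad]; rho <- rho[-bad]
    tab <- tab[-bad, , drop = FALSE]
  }
  if (!length(L)) stop("no usable rows in ", path)

  if (lengthUnit == "nt") L <- L / 3
  scale <- switch(densityUnit, per_codon = 1, per_nt = 3,
                  per_100nt = 3 / 100)
  rho <- rho * scale
  sdv <- if (!is.na(iS))
    suppressWarnings(as.numeric(tab[[iS]])) * scale else NA_real_
  if (any(rho < 0 | rho > 1))
    stop("density outside [0, 1] ribosomes/codon after unit conversion")

  out <- data.frame(
    gene_id = if (!is.na(iG)) as.character(tab[[iG]]) else NA_character_,
    L = L, rho = rho, sd = sdv,
    n = if (!is.na(iN)) suppressWarnings(as.numeric(tab[[iN]]))
        else NA_real_)
  class(out) <- c("density_length", "data.frame")
  out
}

#' Bin density records by transcript length
#'
#' Aggregates per-gene records into length bins, mimicking the
#' length-binned genome-wide summaries produced from sucrose-gradient
#' data: per-bin representative length (geometric mean for the `log`
#' scheme, arithmetic mean for `linear`), mean density, standard
#' deviation of density and record count. Empty bins are dropped with a
#' warning.
#'
#' @param records a `"density_length"` data frame (columns `L`, `rho`).
#' @param nBins number of bins (`>= 1`).
#' @param scheme `"log"` (default, bins equally spaced in `log L`) or
#'   `"linear"`.
#' @return A `"density_length"` data frame with one row per non-empty
#'   bin.
#' @examples
#' rec <- data.frame(gene_id = NA, L = c(100, 110, 900, 950),
#'                   rho = c(0.03, 0.028, 0.011, 0.009), sd = NA, n = NA)
#' binByLength(rec, 2)
#' @export
binByLength <- function(records, nBins, scheme = c("log", "linear")) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(records), all(c("L", "rho") %in% names(records)))
  nBins <- as.integer(nBins)
  if (is.na(nBins) || nBins < 1L) stop("'nBins' must be >= 1")

  x <- if (scheme == "log") log(records$L) else records$L
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  breaks[1] <- breaks[1] - 1e-9; breaks[nBins + 1L] <- breaks[nBins + 1L] + 1e-9
  bin <- cut(x, breaks, labels = FALSE)

  counts <- tabulate(bin, nBins)
  if (any(counts == 0L))
    warning("dropping ", sum(counts == 0L), " empty bin(s)")

  rows <- lapply(which(counts > 0L), function(b) {
    i <- which(bin == b)
    Lb <- if (scheme == "log") exp(mean(log(records$L[i])))
          else mean(records$L[i])
    data.frame(gene_id = NA_character_, L = Lb,
               rho = mean(records$rho[i]),
               sd = if (length(i) > 1L) stats::sd(records$rho[i])
                    else NA_real_,
               n = length(i))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("density_length", "data.frame")
  out
}

# model densities for a parameter vector theta; theta layout depends on
# the variant: plain / two_subunit -> (alpha_bar_inf, lam);
# circularised -> (alpha_bar_inf, lam, epsilon)
modelDensities <- function(theta, lengths, variant, polymer) {
  if (variant == "circularised")
    polymer <- polymerParams(l_p = polymer$l_p, ell = polymer$ell,
                             d = polymer$d, epsilon = theta[3L])
  fp <- if (variant == "two_subunit")
    feedbackParams(alpha_bar_inf = theta[1L], lam = sqrt(theta[2L]),
                   variant = variant, lam2 = theta[2L], polymer = polymer)
  else
    feedbackParams(alpha_bar_inf = theta[1L], lam = theta[2L],
                   variant = variant, polymer = polymer)
  vapply(lengths, function(L) solveAlpha(L, fp)$rho, numeric(1))
}

#' Fit the recycling-feedback parameters to density-length data
#'
#' Weighted nonlinear least squares of the implicit feedback model
#' against observed (length, density) records: minimises
#' `sum_i w_i (rho_model(L_i; theta) - rho_i)^2` with
#' `w_i = 1/sd_i^2` when per-record standard deviations are available
#' (inverse-variance weighting of binned data) and `w_i = 1` otherwise.
#' `rho_model` is evaluated by [solveAlpha()]. The fitted parameters
#' are `theta = (alpha_bar_inf, lam)` for the `plain` and `two_subunit`
#' variants (the latter fits `lam2`) and
#' `theta = (alpha_bar_inf, lam, epsilon)` for `circularised`.
#'
#' Optimisation uses bounded Levenberg-Marquardt
#' (\code{\link[minpack.lm]{nls.lm}}) with bounds
#' `alpha_bar_inf in (0, alpha_bar_c)`, `lam in [0, 1000]` codons,
#' `epsilon in [-20, 5]` kT, restarted from `nStarts` spread-out
#' initial guesses to guard against local minima; the best final
#' residual sum of squares wins. Standard errors and the covariance
#' matrix come from the Gauss-Newton approximation at the optimum,
#' `cov = s^2 (J'WJ)^-1` with `s^2 = RSS/(n - p)`.
#'
#' @param records a `"density_length"` data frame (columns `L`, `rho`,
#'   optionally `sd`).
#' @param variant model variant, see [feedbackParams()].
#' @param init optional numeric vector of starting values (overrides
#'   the multi-start grid).
#' @param weights `"auto"` (inverse variance when `sd` is usable),
#'   `"none"`, or a numeric vector.
#' @param polymer a [polymerParams()] object; its `epsilon` is ignored
#'   for the circularised variant (fitted instead).
#' @param nStarts number of multi-start initial guesses when `init` is
#'   not given.
#' @return An object of class `"feedback_fit"`: list with `params`
#'   (named estimates), `se`, `cov`, `rss` (weighted), `n_obs`,
#'   `variant`, `fitted`, `residuals`, `converged`, `pinned` (logical,
#'   any parameter at a bound) and `starts` (per-start diagnostics).
#' @examples
#' \donttest{
#' truth <- feedbackParams(alpha_bar_inf = 5e-3, lam = 7)
#' rec <- makeSyntheticDataset(syntheticDatasetSpec(
#'   theta = c(5e-3, 7), nLengths = 20, cv = 0, seed = 1))
#' fitParams(rec)$params
#' }
#' @export
fitParams <- function(records, variant = c("plain", "circularised",
                                           "two_subunit"),
                      init = NULL, weights = "auto",
                      polymer = polymerParams(), nStarts = 3L) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(records), all(c("L", "rho") %in% names(records)))
  L <- as.numeric(records$L)
  rho <- as.numeric(records$rho)
  n_obs <- length(L)
  if (n_obs < 3L)
    warning("fewer than 3 records: parameters are weakly identifiable")
  if (diff(range(log10(L))) < 1)
    warning("lengths span less than one decade: expect wide standard errors")
  ell <- polymer$ell
  if (any(rho > 1 / ell))
    warning(sum(rho > 1 / ell),
            " record(s) exceed the steric bound 1/ell; retained in the fit")

  w <- if (identical(weights, "auto")) {
    if ("sd" %in% names(records) &&
        all(is.finite(records$sd)) && all(records$sd > 0))
      1 / records$sd^2 else rep(1, n_obs)
  } else if (identical(weights, "none")) rep(1, n_obs)
  else {
    stopifnot(is.numeric(weights), length(weights) == n_obs,
              all(weights > 0))
    weights
  }
  sw <- sqrt(w)

  ac <- alphaBarCritical(ell)
  npar <- if (variant == "circularised") 3L else 2L
  lower <- c(1e-8, 0, if (npar == 3L) -20)
  upper <- c(ac * 0.999, if (variant == "two_subunit") 1e6 else 1e3,
             if (npar == 3L) 5)

  residFun <- function(theta)
    sw * (modelDensities(theta, L, variant, polymer) - rho)

  starts <- if (!is.null(init)) list(as.numeric(init)) else {
    base <- list(c(1e-3, 1), c(5e-3, 10), c(2e-2, 50),
                 c(1e-4, 100), c(5e-2, 3))
    base <- base[seq_len(max(1L, min(nStarts, length(base))))]
    if (variant == "two_subunit")
      base <- lapply(base, function(s) c(s[1], s[2]^2))
    if (npar == 3L) base <- lapply(base, function(s) c(s, -8))
    base
  }

  runs <- lapply(starts, function(s0) {
    tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(s0, lower), upper),
                         lower = lower, upper = upper, fn = residFun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop("all optimisation starts failed")
  rss <- vapply(runs, function(r) r$deviance, numeric(1))
  best <- runs[[which.min(rss)]]

  theta <- best$par
  dof <- max(n_obs - npar, 1L)
  s2 <- best$deviance / dof
  covm <- tryCatch(s2 * solve(best$hessian),
                   error = function(e) matrix(NA_real_, npar, npar))
  covm <- (covm + t(covm)) / 2
  se <- sqrt(pmax(diag(covm), 0))
  pnames <- c("alpha_bar_inf",
              if (variant == "two_subunit") "lam2" else "lam",
              if (npar == 3L) "epsilon")
  names(theta) <- names(se) <- pnames
  dimnames(covm) <- list(pnames, pnames)
  pinned <- theta <= lower * (1 + 1e-6) | theta >= upper * (1 - 1e-6)

  if (best$info < 1 || best$info > 4)
    warning("optimizer did not report convergence: ", best$message,
            "; parameter trace available in $starts")
  if (any(pinned))
    warning("parameter(s) pinned at bounds: ",
            paste(pnames[pinned], collapse = ", "))

  structure(list(
    params = theta, se = se, cov = covm, rss = best$deviance,
    n_obs = n_obs, variant = variant,
    fitted = modelDensities(theta, L, variant, polymer),
    residuals = best$fvec, converged = best$info >= 1 && best$info <= 4,
    pinned = pinned,
    starts = data.frame(
      t(vapply(runs, function(r) c(r$par, rss = r$deviance),
               numeric(npar + 1L)))),
    polymer = polymer
  ), class = "feedback_fit")
}

#' @export
print.feedback_fit <- function(x, ...) {
  cat(sprintf("recycling-feedback fit (%s variant), %d observations\n",
              x$variant, x$n_obs))
  est <- cbind(estimate = x$params, se = x$se)
  print(signif(est, 4))
  cat(sprintf("weighted RSS = %.4g%s\n", x$rss,
              if (!x$converged) "  [not converged]" else ""))
  invisible(x)
}
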