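test_that("feedback off reduces to the background initiation rate", {
  for (v in c("plain", "circularised")) {
    s <- solveAlpha(800, feedbackParams(alpha_bar_inf = 3e-3, lam = 0,
                                        variant = v))
    expect_equal(s$alpha_bar, 3e-3)
    expect_true(s$converged)
  }
  s2 <- solveAlpha(800, feedbackParams(alpha_bar_inf = 3e-3,
                                       variant = "two_subunit", lam2 = 0))
  expect_equal(s2$alpha_bar, 3e-3)
})

test_that("the fixed point satisfies the recycling equation tightly", {
  for (v in c("plain", "circularised", "two_subunit")) {
    fp <- repFeedback(v)
    for (L in c(80, 500, 3000)) {
      s <- solveAlpha(L, fp)
      # recompute the map by hand from the public pieces
      Jb <- currentLD(s$alpha_bar, 10)
      expected <- fp$alpha_bar_inf +
        if (v == "two_subunit") fp$lam2 * Jb / endToEnd(L, s$rho)^2
        else fp$lam * Jb / s$R
      expect_lt(abs(expected - s$alpha_bar) / s$alpha_bar, 1e-8)
      # feedback only ever enhances initiation
      expect_gte(s$alpha_bar, fp$alpha_bar_inf)
    }
  }
})

test_that("density decreases with transcript length when recycling is on", {
  Ls <- round(10^seq(log10(50), 4, length.out = 25))
  for (v in c("plain", "circularised", "two_subunit")) {
    cur <- densityLengthCurve(Ls, repFeedback(v))
    expect_true(all(cur$converged))
    expect_true(all(diff(cur$rho) < 0))
    expect_lte(max(cur$rho), maxDensityLD(10) + 1e-12)
  }
  # lambda = 0: flat profile
  flat <- densityLengthCurve(Ls, feedbackParams(alpha_bar_inf = 4.7e-3,
                                                lam = 0))
  expect_equal(diff(range(flat$rho)), 0)
  # circularisation boosts short transcripts above the plain model
  short <- 100
  expect_gt(solveAlpha(short, repFeedback("circularised"))$rho,
            solveAlpha(short, repFeedback("plain"))$rho)
})

test_that("solver clamps at the phase boundary when feedback is too strong", {
  expect_warning(
    s <- solveAlpha(50, feedbackParams(alpha_bar_inf = 0.1, lam = 500)),
    "clamped|no fixed point")
  expect_false(s$converged)
  expect_equal(s$alpha_bar, alphaBarCritical(10))
  # the sweep keeps going past problem lengths
  cur <- suppressWarnings(
    densityLengthCurve(c(50, 5000),
                       feedbackParams(alpha_bar_inf = 0.1, lam = 500)))
  expect_equal(nrow(cur), 2L)
  expect_false(cur$converged[1])
})

test_that("self-consistent simulation agrees with the analytic fixed point", {
  fp <- repFeedback()
  sc <- selfConsistentSim(500, fp, seed = 4)
  expect_true(sc$converged)
  expect_lte(sc$n_iter, 10)
  an <- solveAlpha(500, fp)
  expect_lt(abs(sc$rho - an$rho) / an$rho, 0.1)
  # feedback off: the first update already satisfies the criterion
  sc0 <- selfConsistentSim(200, feedbackParams(alpha_bar_inf = 5e-3,
                                               lam = 0),
                           seed = 4, tSampleIter = 2000,
                           tSampleFinal = 2000)
  expect_equal(sc0$n_iter, 1L)
  expect_equal(sc0$alpha_bar, 5e-3)
})

test_that("recycling boost spans the biologically quoted magnitude", {
  reg <- recyclingRegime(J_range = c(0.1, 10), D = 0.04, L = 300,
                         c_inf_range = c(500, 1000))
  # interval overlap with 0.1 - 10: order-of-magnitude claim only
  expect_lt(reg$ratio_range[1], 10)
  expect_gt(reg$ratio_range[2], 0.1)
  expect_equal(reg$R_um, sqrt(600) * 1e-3)
})
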