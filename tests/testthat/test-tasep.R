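test_that("lattice construction enforces the footprint geometry", {
  lat <- initLattice(300, 10)
  expect_equal(ribosomeCount(lat), 0)
  expect_equal(lat$t, 0)
  expect_s3_class(initLattice(10, 10), "elongation_lattice")  # capacity 1
  expect_error(initLattice(5, 10), "invalid transcript")
  expect_error(initLattice(100, 0), "ell")
})

test_that("enabled transitions match hand enumeration", {
  rates <- kineticRates(alpha = 0.2, p = 10, beta = 3, delta = 0, ell = 10)

  # empty lattice: initiation is the only enabled event
  ev <- enabledEvents(initLattice(300, 10), rates)
  expect_equal(ev$type, "init")
  expect_equal(ev$rate, 0.2)

  # ribosomes at codons 1 and 11 with ell = 10: the upstream one is
  # blocked (A-site spacing must exceed ell to advance), codons 1..10
  # are covered so initiation is blocked; only the downstream ribosome
  # can step
  lat <- initLattice(300, 10)
  lat$positions <- c(1L, 11L)
  ev <- enabledEvents(lat, rates)
  expect_equal(ev$type, "step")
  expect_equal(ev$ribosome, 2L)

  # with drop-off on, both ribosomes also gain a detachment channel
  rates_d <- kineticRates(alpha = 0.2, p = 10, beta = 3, delta = 1e-3,
                          ell = 10)
  ev <- enabledEvents(lat, rates_d)
  expect_equal(sum(ev$type == "step"), 1L)
  expect_equal(sum(ev$type == "drop"), 2L)
  expect_equal(nrow(ev), 3L)

  # a ribosome with A-site on the last codon can terminate; with codons
  # 1..ell free, initiation is enabled too
  lat$positions <- 300L
  ev <- enabledEvents(lat, rates)
  expect_setequal(ev$type, c("init", "term"))

  # spacing exactly ell+1 unblocks the upstream ribosome
  lat$positions <- c(1L, 12L)
  ev <- enabledEvents(lat, rates)
  expect_equal(sort(ev$ribosome[ev$type == "step"]), c(1L, 2L))
})

test_that("single Gillespie steps execute one event and keep invariants", {
  rates <- kineticRates(alpha = 0.5, p = 10, beta = 10, delta = 0.01,
                        ell = 10)
  set.seed(11)
  st <- gillespieStep(initLattice(300, 10), rates)
  expect_equal(st$lattice$positions, 1L)
  expect_equal(st$event$type, "init")
  expect_gt(st$dt, 0)

  # absorbing state: empty lattice, no initiation
  expect_error(
    gillespieStep(initLattice(300, 10), kineticRates(alpha = 0, p = 10)),
    class = "riboloop_absorbing_state")

  # property: a long random trajectory never violates exclusion,
  # bounds, or capacity
  set.seed(42)
  lat <- initLattice(120, 10)
  for (i in 1:3000) {
    st <- gillespieStep(lat, rates)
    lat <- st$lattice
    p <- lat$positions
    expect_true(all(p >= 1 & p <= 120))
    if (length(p) > 1) expect_true(all(diff(p) >= 10))
    expect_lte(length(p), 12)
  }
})

test_that("steady-state runs are reproducible and conserve ribosomes", {
  rates <- kineticRates(alpha = 1, p = 10, ell = 10)
  a <- runSteadyState(300, rates, tSample = 1500, seed = 7)
  b <- runSteadyState(300, rates, tSample = 1500, seed = 7)
  expect_identical(a$rho, b$rho)
  expect_identical(a$n_events, b$n_events)
  expect_identical(a$N_hist, b$N_hist)
  expect_equal(a$N_mean, a$rho * 300)

  # alpha = 0: empty absorbing lattice
  z <- runSteadyState(300, kineticRates(alpha = 0, p = 10), tSample = 10,
                      seed = 1)
  expect_equal(z$rho, 0)
  expect_equal(z$J, 0)
  expect_true(z$absorbed)

  # event bookkeeping: inflow - outflow equals the change in occupancy,
  # so over the window |init - term - drop| is at most the capacity
  withDrop <- suppressWarnings(   # only bookkeeping is asserted here
    runSteadyState(500, kineticRates(alpha = 1, p = 10,
                                     delta = 5e-3, ell = 10),
                   tSample = 4000, seed = 3))
  ev <- withDrop$n_events
  expect_gt(ev[["drop"]], 0)
  expect_lte(abs(ev[["init"]] - ev[["term"]] - ev[["drop"]]), 500 / 10)

  # without drop-off, initiation and termination event rates balance
  # within Monte Carlo error (>= 1e5 events sampled)
  nd <- runSteadyState(500, kineticRates(alpha = 1, p = 10, ell = 10),
                       tSample = 6000, seed = 5)
  expect_gt(sum(nd$n_events), 1e5)
  diffN <- abs(nd$n_events[["init"]] - nd$n_events[["term"]])
  se <- sqrt(nd$n_events[["init"]] + nd$n_events[["term"]])
  expect_lte(diffN, max(3 * se, 500 / 10))
})

test_that("density never exceeds the steric bound 1/ell", {
  # drive initiation far above the phase boundary; occupancy must cap
  ss <- runSteadyState(100, kineticRates(alpha = 50, p = 10, ell = 10),
                      tSample = 500, seed = 9)
  occupied <- as.integer(names(ss$N_hist))[ss$N_hist > 0]
  expect_lte(max(occupied), 10)       # floor(100/10)
  expect_lte(ss$rho, 0.1)
})

test_that("pure-R stepper and compiled engine sample the same process", {
  # time-averaged density from the reference stepper vs the compiled
  # long-run engine, small system
  rates <- kineticRates(alpha = 0.8, p = 10, beta = 10, ell = 10)
  set.seed(123)
  lat <- initLattice(60, 10)
  tN <- 0; tTot <- 0
  for (i in 1:20000) {
    st <- gillespieStep(lat, rates)
    if (i > 4000) {                     # crude burn-in
      tN <- tN + st$dt * ribosomeCount(lat)
      tTot <- tTot + st$dt
    }
    lat <- st$lattice
  }
  rho_r <- tN / tTot / 60
  ss <- runSteadyState(60, rates, tSample = 4000, seed = 321)
  expect_lt(abs(rho_r - ss$rho) / ss$rho, 0.1)
})
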