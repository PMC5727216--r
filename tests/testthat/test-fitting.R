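test_that("density tables are read, validated and unit-converted", {
  df <- data.frame(gene_id = c("g1", "g2", "g3"),
                   length_codons = c(100, 300, 900),
                   density = c(0.03, 0.02, 0.01),
                   sd = c(0.003, 0.002, 0.001))
  rec <- readDensityTable(writeDensityFixture(df))
  expect_s3_class(rec, "density_length")
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$L, df$length_codons)
  expect_equal(rec$rho, df$density)
  expect_equal(rec$sd, df$sd)

  # CSV autodetection
  rec2 <- readDensityTable(writeDensityFixture(df, ext = ".csv", sep = ","))
  expect_equal(rec2$rho, rec$rho)

  # nucleotide lengths and per-100nt densities convert to codon units
  df_nt <- data.frame(length = c(300, 900), density = c(1.0, 0.5))
  rec_nt <- readDensityTable(writeDensityFixture(df_nt),
                             lengthUnit = "nt", densityUnit = "per_100nt")
  expect_equal(rec_nt$L, c(100, 300))
  expect_equal(rec_nt$rho, c(1.0, 0.5) * 3 / 100)
  # round trip: converting back recovers the original numbers
  expect_equal(rec_nt$L * 3, df_nt$length)
  expect_equal(rec_nt$rho * 100 / 3, df_nt$density)

  # malformed rows are dropped with their line numbers reported
  tf <- writeDensityFixture(data.frame(length = c("100", "oops", "900"),
                                       density = c(0.03, 0.02, 0.01)))
  expect_warning(bad <- readDensityTable(tf), "line.*3")
  expect_equal(nrow(bad), 2L)

  # schema and empty-file errors
  expect_error(readDensityTable(writeDensityFixture(
    data.frame(foo = 1, bar = 2))), "schema")
  tf0 <- tempfile(fileext = ".tsv"); file.create(tf0)
  expect_error(readDensityTable(tf0), "empty|parse")
})

test_that("length binning reproduces hand-computed summaries", {
  rec <- data.frame(gene_id = NA, n = NA, sd = NA,
                    L = c(100, 110, 120, 900, 950, 1000),
                    rho = c(0.030, 0.028, 0.026, 0.011, 0.009, 0.010))
  b <- binByLength(rec, 2, scheme = "log")
  expect_equal(nrow(b), 2L)
  expect_equal(b$L[1], exp(mean(log(c(100, 110, 120)))))
  expect_equal(b$rho[1], mean(c(0.030, 0.028, 0.026)))
  expect_equal(b$sd[2], sd(c(0.011, 0.009, 0.010)))
  expect_equal(b$n, c(3, 3))

  # all records in one bin
  one <- binByLength(rec, 1)
  expect_equal(one$rho, mean(rec$rho))
  # more bins than records: only non-empty bins survive
  many <- suppressWarnings(binByLength(rec, 50))
  expect_lte(nrow(many), 6L)
  expect_equal(sum(many$n), 6)
  # linear scheme uses arithmetic mean lengths
  lin <- binByLength(rec, 2, scheme = "linear")
  expect_equal(lin$L[1], 110)
})

test_that("noiseless synthetic data return the true parameters", {
  theta <- c(5e-3, 7)
  rec <- makeSyntheticDataset(syntheticDatasetSpec(theta = theta,
                                                   nLengths = 20, cv = 0,
                                                   seed = 1))
  f <- fitParams(rec)
  expect_lt(abs(f$params[["alpha_bar_inf"]] - theta[1]) / theta[1], 1e-4)
  expect_lt(abs(f$params[["lam"]] - theta[2]) / theta[2], 1e-4)
  expect_true(all(f$se >= 0))
  expect_equal(f$cov, t(f$cov))
  expect_true(all(eigen(f$cov, only.values = TRUE)$values > -1e-12))

  # invariance to record order
  f2 <- fitParams(rec[sample.int(nrow(rec)), ])
  expect_equal(f2$params, f$params, tolerance = 1e-6)
})

test_that("fits survive unit round trips through the table reader", {
  rec <- makeSyntheticDataset(syntheticDatasetSpec(theta = c(5e-3, 7),
                                                   nLengths = 15,
                                                   cv = 0.05, seed = 3))
  f_direct <- fitParams(rec)
  # write in nucleotides / per-100nt and read back
  tf <- writeDensityFixture(data.frame(length = rec$L * 3,
                                       density = rec$rho * 100 / 3,
                                       sd = rec$sd * 100 / 3))
  rec_rt <- readDensityTable(tf, lengthUnit = "nt",
                             densityUnit = "per_100nt")
  f_rt <- fitParams(rec_rt)
  expect_equal(f_rt$params, f_direct$params, tolerance = 1e-6)
})

test_that("degenerate designs are flagged rather than silently fitted", {
  rec <- makeSyntheticDataset(syntheticDatasetSpec(theta = c(5e-3, 7),
                                                   lengthRange = c(300, 400),
                                                   nLengths = 6, cv = 0,
                                                   seed = 1))
  expect_warning(fitParams(rec), "decade")
  two <- makeSyntheticDataset(syntheticDatasetSpec(theta = c(5e-3, 7),
                                                   nLengths = 2, cv = 0,
                                                   seed = 1))
  expect_warning(fitParams(two), "3 records")
})

test_that("circularised fit on open-chain data collapses onto the plain fit", {
  # data generated without any circularisation signal: the nested model
  # must switch its own circularisation off (P_c ~ 0, epsilon driven to
  # the weak-binding bound) and return the plain lambda
  rec <- makeSyntheticDataset(syntheticDatasetSpec(theta = c(5e-3, 7),
                                                   nLengths = 25,
                                                   cv = 0, seed = 8))
  f_plain <- fitParams(rec, variant = "plain")
  f_circ <- suppressWarnings(fitParams(rec, variant = "circularised"))
  expect_lt(abs(f_circ$params[["lam"]] - f_plain$params[["lam"]]) /
              f_plain$params[["lam"]], 0.01)
  fitted_pc <- circularisationProb(
    rec$L, effectivePersistence(f_circ$fitted,
                                polymerParams(epsilon = f_circ$params[["epsilon"]])),
    polymerParams(epsilon = f_circ$params[["epsilon"]]))$P_c
  expect_lt(max(fitted_pc), 0.01)
})
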