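# shared fixtures: the representative working point and small helpers

repFeedback <- function(variant = "plain", ...) {
  feedbackParams(alpha_bar_inf = 4.7e-3, lam = 7, variant = variant, ...)
}

# invert rhoLD: the dimensionless initiation rate giving density rho
alphaOfRho <- function(rho, ell = 10) rho / (1 - (ell - 1) * rho)

# write a small density table to a temp file
writeDensityFixture <- function(df, ext = ".tsv", sep = "\t") {
  tf <- tempfile(fileext = ext)
  utils::write.table(df, tf, sep = sep, row.names = FALSE, quote = FALSE)
  tf
}
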