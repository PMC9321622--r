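# Small programmatic fixtures shared across test files.

# a clean Gaussian emission spectrum on an integer nm grid
gaussSpectrum <- function(center = 327, amp = 1000, width = 25,
                          axis = 220:500, kind = "emission") {
  Spectrum(axis, amp * exp(-(axis - center)^2 / (2 * width^2)),
           kind = kind)
}

# a noiseless static-quenching titration with known Ksv (n = 1)
idealSeries <- function(ksv = 5.7e4, f0 = 1000,
                        q = seq(0, 2.5e-5, 2.5e-6), temperature = 298,
                        n = 1) {
  TitrationSeries(q, f0 / (1 + ksv * q^n), F0 = f0,
                  temperature = temperature)
}

# write lines to a temp file and return its path
tmpText <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
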