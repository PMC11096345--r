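wn_fine <- seq(400, 1800, by = 1)

test_that("baseline correction annihilates a pure degree-6 polynomial", {
  u <- (wn_fine - 1100) / 700
  y <- 3 + u - 2 * u^2 + 0.5 * u^3 - u^4 + 0.2 * u^5 - 0.7 * u^6
  out <- baselineCorrect(y, wn_fine)
  expect_lt(max(abs(out)), 1e-6 * max(abs(y)))
})

test_that("baseline correction recovers a peak sitting on a polynomial", {
  u <- (wn_fine - 1100) / 700
  peak <- 1 / (1 + ((wn_fine - 1000) / 6)^2)
  y <- (2 + u + 0.8 * u^2 - 0.5 * u^3) + peak
  out <- baselineCorrect(y, wn_fine)
  i <- which.min(abs(wn_fine - 1000))
  expect_lt(abs(out[i] - 1), 0.05)
})

test_that("baseline correction of the zero spectrum is zero", {
  out <- baselineCorrect(rep(0, length(wn_fine)), wn_fine)
  expect_equal(out, rep(0, length(wn_fine)))
})

test_that("baseline operator is near-idempotent on its own output", {
  set.seed(4)
  u <- (wn_fine - 1100) / 700
  y <- 2 + u^2 + 1 / (1 + ((wn_fine - 1446) / 9)^2) +
    rnorm(length(wn_fine), 0, 0.01)
  once <- baselineCorrect(y, wn_fine)
  twice <- baselineCorrect(once, wn_fine)
  expect_lt(max(abs(twice - once)), 0.02 * max(abs(once)))
})

test_that("band normalization rescales by the window maximum", {
  y <- rep(0.5, length(wn_fine))
  y[which.min(abs(wn_fine - 1665))] <- 2
  out <- normalizeBand(y, wn_fine)
  expect_equal(max(out[abs(wn_fine - 1667) <= 5]), 1)
  expect_equal(out[1], 0.25)
  expect_error(normalizeBand(rep(0, length(wn_fine)), wn_fine),
               "degenerate normalization band")
})

test_that("normalization makes the window maximum exactly 1 for a batch", {
  sim <- simulateSpectra(smallConfig(n = c(HC = 2, RD = 2, SjD = 2),
                                     m = 4, step = 1, seed = 8))
  bc <- baselineCorrect(sim$dataset)
  nb <- normalizeBand(bc)
  Y <- spectraMatrix(nb)
  win <- abs(wavenumbers(nb) - 1667) <= 5
  expect_equal(unname(apply(Y[, win, drop = FALSE], 1, max)),
               rep(1, nrow(Y)))
})

test_that("Savitzky-Golay leaves degree-<=5 polynomials unchanged", {
  x <- seq_along(wn_fine)
  y <- 2 + 0.3 * x - 1e-4 * x^2 + 1e-7 * x^3 - 1e-11 * x^5
  out <- smoothSpectrum(y)
  expect_lt(max(abs(out - y)) / max(abs(y)), 1e-9)
  const <- smoothSpectrum(rep(3.5, 100))
  expect_equal(const, rep(3.5, 100))
  expect_error(smoothSpectrum(rep(1, 20)), "shorter than")
})

test_that("smoothing reduces white-noise variance", {
  set.seed(6)
  vars <- replicate(10, {
    y <- rnorm(500)
    var(smoothSpectrum(y)) / var(y)
  })
  expect_true(all(vars < 1))
})

test_that("QC retains clean spectra, rejects spikes and dead spectra", {
  cfg0 <- generatorConfig(n_donors = c(HC = 1, RD = 1, SjD = 1),
                          spectra_per_donor = 2, noise_sd = 0.01,
                          cosmic_ray_rate = 0, seed = 15)
  sim <- simulateSpectra(cfg0)
  Y <- t(spectraMatrix(sim$dataset))
  n_clean <- ncol(Y)

  spiked <- Y[, 1]
  resid_mad <- mad(spiked - runmed(spiked, 7))
  spiked[700] <- spiked[700] + 50 * resid_mad
  dead <- abs(rnorm(nrow(Y), 0, 0.01)) + 0.5   # noise only, no bands
  aug <- cbind(Y, spiked, dead)
  ds <- RamanSet(aug, wavenumbers(sim$dataset),
                 donor_id = c(donorIds(sim$dataset), "bad1", "bad2"),
                 class_label = c(classLabels(sim$dataset), "HC", "HC"),
                 spot_index = c(spotIndices(sim$dataset), 99L, 99L))
  out <- qcFilter(ds)
  log <- rejectionLog(out)
  expect_identical(ncol(out), n_clean)
  expect_setequal(log$donor_id, c("bad1", "bad2"))
  expect_identical(log$reason[log$donor_id == "bad1"], "cosmic_ray")
  expect_identical(log$reason[log$donor_id == "bad2"], "low_snr")
})

test_that("QC false-rejection rate on clean synthetic data is under 1%", {
  sim <- simulateSpectra(generatorConfig(
    n_donors = c(HC = 4, RD = 4, SjD = 4), spectra_per_donor = 10,
    cosmic_ray_rate = 0, seed = 23))
  out <- qcFilter(sim$dataset)
  expect_lt(nrow(rejectionLog(out)) / ncol(sim$dataset), 0.01)
})

test_that("the full chain composes and is stable on reapplication", {
  ## low noise so the smoothing perturbation of the normalized band is
  ## negligible and the chain's numerical properties are visible
  sim <- simulateSpectra(generatorConfig(
    n_donors = c(HC = 2, RD = 2, SjD = 2), spectra_per_donor = 6,
    noise_sd = 0.002, cosmic_ray_rate = 0, seed = 42))
  pp <- preprocess(sim$dataset)
  win <- abs(wavenumbers(pp) - 1667) <= 5
  Y <- spectraMatrix(pp)
  ## smoothing (the last step) attenuates the normalized band top by a
  ## bounded systematic amount: a 31-point order-5 filter takes ~1% off a
  ## Lorentzian of comparable width, up to ~2-3% for composite shapes
  expect_true(all(abs(apply(Y[, win, drop = FALSE], 1, max) - 1) < 0.03))
  expect_identical(ncol(pp) + nrow(rejectionLog(pp)), ncol(sim$dataset))
  ## reapplication re-normalizes by the attenuated maximum; the drift is
  ## bounded by about twice the attenuation
  pp2 <- preprocess(pp, qc = FALSE)
  common <- intersect(colnames(pp), colnames(pp2))
  d <- abs(spectraMatrix(pp2)[common, ] - spectraMatrix(pp)[common, ])
  expect_lt(max(d), 0.05 * max(abs(spectraMatrix(pp))))
})

test_that("spectra with injected cosmic spikes are removed by the chain", {
  sim <- simulateSpectra(generatorConfig(
    n_donors = c(HC = 2, RD = 2, SjD = 2), spectra_per_donor = 6,
    cosmic_ray_rate = 0.3, seed = 42))
  pp <- preprocess(sim$dataset)
  spiky <- sim$truth$spectra$n_cosmic > 0
  kept <- paste(donorIds(pp), spotIndices(pp))
  injected <- paste(sim$truth$spectra$donor_id,
                    sim$truth$spectra$spot_index)[spiky]
  expect_length(intersect(kept, injected), 0)
  expect_identical(ncol(pp) + nrow(rejectionLog(pp)), ncol(sim$dataset))
})
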