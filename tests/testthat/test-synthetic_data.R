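test_that("a single noiseless band yields the analytic Lorentzian", {
  wn <- seq(400, 1800, by = 2)
  cfg <- generatorConfig(
    n_donors = c(HC = 1, RD = 1, SjD = 1), spectra_per_donor = 3,
    wavenumbers = wn,
    bands = data.frame(center = 1000, width = 10, amplitude = 1),
    effect_bands = numeric(), rd_effect_bands = numeric(),
    donor_sd = 0, spot_sd = 0, baseline_amp = 0, noise_sd = 0,
    cosmic_ray_rate = 0, seed = 5)
  sim <- simulateSpectra(cfg)
  Y <- spectraMatrix(sim$dataset)
  lorentz <- 1 / (1 + ((wn - 1000) / 5)^2)
  for (i in seq_len(nrow(Y))) {
    expect_equal(unname(Y[i, ]), lorentz, tolerance = 1e-12)
    expect_identical(which.max(Y[i, ]), which.min(abs(wn - 1000)))
  }
})

test_that("generation is fully determined by the seed", {
  a <- simulateSpectra(smallConfig(seed = 9))
  b <- simulateSpectra(smallConfig(seed = 9))
  c <- simulateSpectra(smallConfig(seed = 10))
  expect_identical(spectraMatrix(a$dataset), spectraMatrix(b$dataset))
  expect_identical(a$truth, b$truth)
  expect_false(identical(spectraMatrix(a$dataset),
                         spectraMatrix(c$dataset)))
})

test_that("intensities are finite, non-negative, and clipping is logged", {
  sim <- simulateSpectra(smallConfig(seed = 2, noise_sd = 0.2))
  Y <- spectraMatrix(sim$dataset)
  expect_true(all(is.finite(Y)))
  expect_true(min(Y) >= 0)
  expect_match(paste(provenance(sim$dataset), collapse = " "),
               "clipped")
})

test_that("the configured SjD deficit appears at the effect bands", {
  ## 20 donors per class, no baseline/noise so the band ratio is read
  ## directly off the 1000 cm-1 intensity
  cfg <- generatorConfig(
    n_donors = c(HC = 20, RD = 20, SjD = 20), spectra_per_donor = 4,
    wavenumbers = seq(400, 1800, by = 4), sjd_multiplier = 0.7,
    baseline_amp = 0, noise_sd = 0.005, cosmic_ray_rate = 0, seed = 21)
  sim <- simulateSpectra(cfg)
  Y <- spectraMatrix(sim$dataset)
  i1000 <- which.min(abs(wavenumbers(sim$dataset) - 1000))
  cl <- classLabels(sim$dataset)
  ## donor-level means (donors are the independent unit)
  donor_mean <- tapply(Y[, i1000], donorIds(sim$dataset), mean)
  donor_class <- cl[!duplicated(donorIds(sim$dataset))]
  names(donor_class) <- donorIds(sim$dataset)[!duplicated(donorIds(sim$dataset))]
  hc <- donor_mean[names(donor_class)[donor_class == "HC"]]
  sjd <- donor_mean[names(donor_class)[donor_class == "SjD"]]
  expect_lt(mean(sjd), mean(hc))
  ratio <- mean(sjd) / mean(hc)
  se <- ratio * sqrt(stats::var(sjd) / (length(sjd) * mean(sjd)^2) +
                     stats::var(hc) / (length(hc) * mean(hc)^2))
  expect_lt(abs(ratio - 0.7), 3 * se)
})

test_that("with all multipliers 1 a permutation test finds no effect", {
  cfg <- smallConfig(n = c(HC = 8, RD = 8, SjD = 8), m = 6, seed = 31,
                     sjd_multiplier = 1, rd_multiplier = 1)
  sim <- simulateSpectra(cfg)
  Y <- spectraMatrix(sim$dataset)
  i1000 <- which.min(abs(wavenumbers(sim$dataset) - 1000))
  donor_mean <- tapply(Y[, i1000], donorIds(sim$dataset), mean)
  donor_class <- classLabels(sim$dataset)[
    match(names(donor_mean), donorIds(sim$dataset))]
  obs <- abs(mean(donor_mean[donor_class == "SjD"]) -
             mean(donor_mean[donor_class == "HC"]))
  set.seed(99)
  perm <- replicate(400, {
    sh <- sample(donor_class)
    abs(mean(donor_mean[sh == "SjD"]) - mean(donor_mean[sh == "HC"]))
  })
  p <- mean(perm >= obs)
  expect_gt(p, 0.05)
})

test_that("stronger injected effects give higher downstream accuracy", {
  accs <- vapply(c(1.0, 0.85, 0.6), function(mult) {
    sim <- simulateSpectra(smallConfig(
      n = c(HC = 5, RD = 5, SjD = 5), m = 8, seed = 77,
      sjd_multiplier = mult, rd_multiplier = max(mult, 0.85)))
    pp <- preprocess(sim$dataset, qc = FALSE)
    cvr <- crossValidate(pp, NULL,
                         classifierConfig(svm_cost = 10, rbf_gamma = 0.1),
                         cvScheme(n_splits = 5, seed = 3))
    voteDonors(cvr$predictions)$accuracy
  }, numeric(1))
  expect_true(accs[3] >= accs[2] - 0.1)
  expect_true(accs[2] >= accs[1] - 0.1)
  expect_gt(accs[3], accs[1])
})

test_that("ground truth records outlier donors and effect bands", {
  cfg <- smallConfig(n = c(HC = 7, RD = 7, SjD = 7), m = 4, seed = 13,
                     outlier_donor_fraction = 4 / 21)
  sim <- simulateSpectra(cfg)
  expect_identical(sum(sim$truth$donors$outlier), 4L)
  eb <- sim$truth$effect_bands
  expect_true(all(eb$SjD[eb$center %in% setdiff(SJD_EFFECT_BANDS, 1667)]
                  == 0.72))
  expect_identical(eb$SjD[eb$center == 1667], 0.9)
  expect_true(all(eb$SjD[!eb$center %in% SJD_EFFECT_BANDS] == 1))
  expect_identical(nrow(sim$truth$spectra), ncol(sim$dataset))
})
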