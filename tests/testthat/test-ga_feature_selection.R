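## A compact labelled dataset with exactly one informative spectral region
## (SjD deficit at the 1000 cm-1 band only), preprocessed once for reuse.
gaFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generatorConfig(
        n_donors = c(HC = 5, RD = 5, SjD = 5), spectra_per_donor = 8,
        wavenumbers = seq(400, 1800, by = 4),
        effect_bands = 1000, sjd_multiplier = 0.55,
        rd_effect_bands = numeric(), donor_sd = 0.1, spot_sd = 0.05,
        baseline_amp = 0, cosmic_ray_rate = 0, seed = 11)
      cache <<- preprocess(simulateSpectra(cfg)$dataset, qc = FALSE)
    }
    cache
  }
})

test_that("an informative mask beats a pure-noise mask on RMSECV", {
  pp <- gaFixture()
  cfg <- gaConfig(window_width_points = 10, inner_lv = 5, cv_folds = 5)
  nw <- length(salivaRaman:::.makeWindows(nrow(pp),
                                          cfg$window_width_points))
  wn <- wavenumbers(pp)
  centers <- vapply(salivaRaman:::.makeWindows(nrow(pp), 10),
                    function(ix) mean(wn[ix]), numeric(1))
  info <- abs(centers - 1000) <= 20
  noise <- abs(centers - 700) <= 60   # same #windows, no class effect
  expect_lt(rmsecvFitness(pp, info, cfg), rmsecvFitness(pp, noise, cfg))
})

test_that("empty masks hit the declared sentinel, fitness is deterministic", {
  pp <- gaFixture()
  cfg <- gaConfig(window_width_points = 10, inner_lv = 5, cv_folds = 5)
  nw <- length(salivaRaman:::.makeWindows(nrow(pp), 10))
  expect_identical(rmsecvFitness(pp, rep(FALSE, nw), cfg),
                   salivaRaman:::.RMSECV_SENTINEL)
  m <- rep(FALSE, nw); m[c(3, 10, 25)] <- TRUE
  expect_identical(rmsecvFitness(pp, m, cfg), rmsecvFitness(pp, m, cfg))
  expect_gte(rmsecvFitness(pp, m, cfg), 0)
})

test_that("full-mask fitness equals a directly coded PLS-DA RMSECV", {
  pp <- gaFixture()
  cfg <- gaConfig(window_width_points = 10, inner_lv = 5, cv_folds = 5)
  nw <- length(salivaRaman:::.makeWindows(nrow(pp), 10))
  got <- rmsecvFitness(pp, rep(TRUE, nw), cfg)
  ## independent oracle: NIPALS per fold on the raw spectra, with the same
  ## donor-grouped venetian fold assignment the fitness uses
  X <- spectraMatrix(pp)
  classes <- intersect(CLASS_LEVELS, unique(classLabels(pp)))
  Y <- onehot(classLabels(pp), classes)
  don <- donorIds(pp)
  ud <- unique(don)
  fold <- (((match(don, ud) - 1L) %% 5L) + 1L)
  sse <- 0
  for (f in 1:5) {
    tr <- fold != f
    o <- nipalsPLS(X[tr, ], Y[tr, ], 5)
    Yhat <- sweep(sweep(X[!tr, , drop = FALSE], 2, o$xmean) %*% o$B,
                  2, o$ymean, `+`)
    sse <- sse + sum((Y[!tr, ] - Yhat)^2)
  }
  expect_equal(got, sqrt(sse / length(Y)), tolerance = 1e-6)
})

test_that("zero generations degenerates to the best initial chromosome", {
  pp <- gaFixture()
  cfg <- gaConfig(population_size = 12, max_generations = 0, n_runs = 2,
                  window_width_points = 10, inner_lv = 5, cv_folds = 5,
                  seed = 4)
  res <- runGA(pp, cfg)
  expect_true(all(lengths(res@traces) == 1))
  for (r in 1:2) {
    expect_identical(res@runFitness[r], res@traces[[r]][1])
    expect_equal(res@runFitness[r],
                 rmsecvFitness(pp, res@runBest[r, ], cfg))
  }
})

test_that("GA recovers a single informative window", {
  pp <- gaFixture()
  cfg <- gaConfig(population_size = 20, max_generations = 15, n_runs = 8,
                  window_width_points = 10, inner_lv = 5, cv_folds = 5,
                  window_fraction = 0.2, seed = 8)
  res <- runGA(pp, cfg)
  wn <- wavenumbers(pp)
  centers <- vapply(res@windows, function(ix) mean(wn[ix]), numeric(1))
  info <- abs(centers - 1000) <= 22
  ## uninformative = windows in band-free regions. Windows on the flanks
  ## of non-effect bands are excluded from the comparison: they carry no
  ## class signal but legitimate normalizer-cancellation value, which a
  ## multivariate fitness may reward.
  bands <- salivaBands()
  flat <- vapply(res@windows, function(ix)
    all(vapply(seq_len(nrow(bands)), function(b)
      all(abs(wn[ix] - bands$center[b]) > 1.5 * bands$width[b]),
      logical(1))), logical(1))
  expect_gt(max(res@windowFrequency[info]),
            max(res@windowFrequency[flat & !info]))
  expect_true(any(res@mask[unlist(res@windows[info])]))
  ## within-run elitism: best fitness never increases
  for (tr in res@traces) expect_true(all(diff(tr) <= 1e-12))
})

test_that("selected bands merge into contiguous wavenumber intervals", {
  mask <- rep(FALSE, 141)
  wn <- seq(400, 1800, by = 10)
  mask[60:66] <- TRUE   # 990-1050
  mask[100:101] <- TRUE
  res <- new("GAResult", windows = list(), runBest = matrix(FALSE, 1, 1),
             runFitness = 0.5, windowFrequency = numeric(),
             variableFrequency = rep(0, 141), mask = mask,
             frequencyThreshold = 0.5, traces = list(),
             wavenumbers = wn)
  tab <- selectedBands(res)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$center_cm1[1], 1020)
  expect_equal(tab$start_cm1[1], 990)
  empty <- res
  empty@mask <- rep(FALSE, 141)
  expect_identical(nrow(selectedBands(empty)), 0L)
})
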