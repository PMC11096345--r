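#' Catalogue of the main Raman bands of dried saliva
#'
#' Band centers follow the literature assignments for dried-saliva Raman
#' spectra between 400 and 1800 cm^-1 (proline 426/1275, phenylalanine 1000,
#' amide I 1667, CH deformations 1446, etc.). Widths (FWHM, cm^-1) and
#' relative base amplitudes are generator choices: sharp aromatic ring modes
#' are narrow, the amide I envelope broad, with the amide I and CH bands the
#' strongest features, as in measured saliva spectra.
#'
#' @return data.frame with columns `center`, `width`, `amplitude`.
#' @export
salivaBands <- function() {
  data.frame(
    center    = c(426, 528, 590, 622, 640, 750, 873, 926, 1000, 1048,
                  1122, 1154, 1275, 1336, 1373, 1408, 1446, 1550, 1602,
                  1667),
    width     = c(14, 14, 16, 10, 10, 12, 14, 14, 9, 12,
                  14, 12, 18, 14, 14, 14, 18, 16, 12, 28),
    amplitude = c(0.30, 0.20, 0.22, 0.28, 0.25, 0.35, 0.30, 0.28, 0.75,
                  0.40, 0.30, 0.35, 0.40, 0.45, 0.35, 0.30, 0.85, 0.30,
                  0.35, 1.00))
}

#' Default centers carrying the disease deficit
#'
#' The band subset whose intensity is reduced in Sjogren's disease spectra
#' (proline, phenylalanine, carbonate/phospholipid, nucleic-acid phosphate,
#' CH deformation and amide I bands).
#' @export
SJD_EFFECT_BANDS <- c(426, 1000, 1048, 1154, 1275, 1336, 1373, 1408, 1667)

#' Configuration for the synthetic saliva-spectrum generator
#'
#' Defaults emulate the study conditions of a three-class dried-saliva
#' cohort: 22 HC + 22 RD + 26 SjD donors, 36 mapping spots per donor,
#' 400-1800 cm^-1 at 1 cm^-1 steps, Lorentzian bands at the saliva band
#' catalogue, a reduced-intensity SjD signature on the nine effect bands, a
#' milder RD signature on a disjoint band set (radiation xerostomia also
#' changes saliva composition; without it the RD class would be spectrally
#' identical to HC and the three-class problem unidentifiable), smooth
#' random polynomial fluorescence baselines, heteroscedastic shot-like
#' noise, occasional cosmic-ray spikes, and multiplicative lognormal
#' donor-level and spot-level variability.
#'
#' @param n_donors named integer vector, donors per class.
#' @param spectra_per_donor spectra (mapping spots) per donor.
#' @param wavenumbers the Raman shift axis.
#' @param bands band catalogue as from [salivaBands()].
#' @param effect_bands centers whose SjD amplitude is multiplied by
#'   `sjd_multiplier` (< 1: deficit).
#' @param sjd_multiplier SjD amplitude multiplier on `effect_bands`.
#' @param ref_band_multiplier SjD multiplier at the 1667 cm^-1 amide I
#'   band, milder than `sjd_multiplier`: were the reference band's deficit
#'   identical to the other effect bands', dividing by it would cancel the
#'   deficit pattern exactly and no wavelength selection could recover it;
#'   a milder reference deficit reproduces the reported picture, in which
#'   every disease band sits lower in the *normalized* mean spectra.
#' @param rd_effect_bands,rd_multiplier analogous mild RD signature
#'   (set `rd_multiplier = 1` for an HC-identical RD class).
#' @param donor_sd,spot_sd sdlog of multiplicative lognormal per-(donor,
#'   band) and per-(spectrum, band) amplitude factors.
#' @param norm_band_stability multiplier (< 1) applied to `donor_sd` and
#'   `spot_sd` for the 1667 cm^-1 amide I band: the normalization reference
#'   is the most stable strong band of real saliva spectra, which is the
#'   reason it is used as the reference at all.
#' @param baseline_amp overall fluorescence baseline scale relative to the
#'   amide I peak (unit amplitude).
#' @param baseline_coeffs_sd spread of the random degree-<=6 polynomial
#'   baseline shape coefficients.
#' @param noise_sd additive noise scale at zero signal; the noise standard
#'   deviation grows with the Poisson-like square root of the local signal.
#' @param cosmic_ray_rate expected cosmic-ray spikes per spectrum
#'   (1-2 point wide, amplitude 30-100 x `noise_sd`).
#' @param outlier_donor_fraction fraction of donors given a gross spectral
#'   distortion (broad alien band + strong band-amplitude jitter).
#' @param donor_prefix prefix for generated donor ids (lets two calls
#'   produce disjoint donor populations).
#' @param seed integer; fully determines the generated dataset.
#' @return list of class `generatorConfig`.
#' @export
generatorConfig <- function(n_donors = c(HC = 22, RD = 22, SjD = 26),
                            spectra_per_donor = 36,
                            wavenumbers = seq(400, 1800, by = 1),
                            bands = salivaBands(),
                            effect_bands = SJD_EFFECT_BANDS,
                            sjd_multiplier = 0.72,
                            ref_band_multiplier = 0.9,
                            rd_effect_bands = c(590, 622, 640, 750, 1446,
                                                1602),
                            rd_multiplier = 0.8,
                            donor_sd = 0.10,
                            spot_sd = 0.25,
                            norm_band_stability = 0.2,
                            baseline_amp = 2,
                            baseline_coeffs_sd = 0.3,
                            noise_sd = 0.02,
                            cosmic_ray_rate = 0.03,
                            outlier_donor_fraction = 0,
                            donor_prefix = "",
                            seed = 1L) {
  stopifnot(all(n_donors >= 0), sum(n_donors) > 0, spectra_per_donor > 0,
            sjd_multiplier > 0, rd_multiplier > 0,
            ref_band_multiplier > 0,
            donor_sd >= 0, spot_sd >= 0, noise_sd >= 0,
            norm_band_stability > 0, norm_band_stability <= 1,
            cosmic_ray_rate >= 0,
            outlier_donor_fraction >= 0, outlier_donor_fraction <= 1,
            all(bands$width > 0), all(bands$amplitude >= 0),
            all(diff(wavenumbers) > 0))
  if (length(wavenumbers) < 62)
    stop("axis too short: need at least 62 points")
  cfg <- as.list(environment())
  class(cfg) <- "generatorConfig"
  cfg
}

.lorentz <- function(x, center, fwhm) 1 / (1 + ((x - center) / (fwhm / 2))^2)

#' Generate a synthetic hyperspectral saliva dataset
#'
#' Each spectrum is a sum of Lorentzian bands (amplitude = catalogue base
#' amplitude x class multiplier x donor factor x spot factor), plus a random
#' smooth polynomial fluorescence baseline, heteroscedastic Gaussian noise
#' and Poisson-count cosmic-ray spikes. Donors drawn as outliers receive a
#' gross distortion: an extra broad Gaussian band at a random position and a
#' strong jitter of all band amplitudes. Negative intensities are clipped to
#' zero (logged in provenance). The same config and seed always produce an
#' identical dataset.
#'
#' @param cfg a [generatorConfig()]
#' @return list with elements
#'   \describe{
#'     \item{dataset}{the generated [RamanSet-class]}
#'     \item{truth}{list of ground-truth tables: `donors` (donor_id, class,
#'       outlier flag), `spectra` (per-spectrum injected cosmic-ray count),
#'       `effect_bands` (center, per-class multiplier) — every injected
#'       property, for downstream validation.}
#'   }
#' @export
simulateSpectra <- function(cfg = generatorConfig()) {
  stopifnot(inherits(cfg, "generatorConfig"))
  set.seed(cfg$seed)
  x <- cfg$wavenumbers
  p <- length(x)
  bands <- cfg$bands
  nb <- nrow(bands)
  if (max(bands$width) * 2 > diff(range(x)))
    stop("axis too short for requested band widths")

  ## per-class amplitude multipliers
  mult <- matrix(1, nb, 3, dimnames = list(NULL, c("HC", "RD", "SjD")))
  mult[bands$center %in% cfg$effect_bands, "SjD"] <- cfg$sjd_multiplier
  mult[bands$center %in% cfg$effect_bands & bands$center == 1667,
       "SjD"] <- cfg$ref_band_multiplier
  mult[bands$center %in% cfg$rd_effect_bands, "RD"] <- cfg$rd_multiplier

  ## precomputed unit band profiles (p x nb)
  prof <- vapply(seq_len(nb),
                 function(b) .lorentz(x, bands$center[b], bands$width[b]),
                 numeric(p))

  ## the amide I reference band varies less than the rest
  stab <- rep(1, nb)
  stab[bands$center == 1667] <- cfg$norm_band_stability

  classes <- names(cfg$n_donors)
  donors <- data.frame(donor_id = character(), class = character())
  for (cl in classes) {
    n <- cfg$n_donors[[cl]]
    if (n > 0)
      donors <- rbind(donors, data.frame(
        donor_id = sprintf("%s%s%02d", cfg$donor_prefix, cl, seq_len(n)),
        class = cl))
  }
  nd <- nrow(donors)
  n_out <- round(cfg$outlier_donor_fraction * nd)
  donors$outlier <- FALSE
  if (n_out > 0) donors$outlier[sample.int(nd, n_out)] <- TRUE

  m <- cfg$spectra_per_donor
  total <- nd * m
  intensity <- matrix(0, p, total)
  donor_id <- character(total)
  class_label <- character(total)
  spot_index <- integer(total)
  n_cosmic <- integer(total)
  u <- (x - mean(range(x))) / (diff(range(x)) / 2)  # scaled to [-1, 1]

  col <- 0L
  for (d in seq_len(nd)) {
    amp_d <- bands$amplitude * mult[, donors$class[d]] *
      exp(stats::rnorm(nb, 0, cfg$donor_sd * stab))
    hump <- NULL
    if (donors$outlier[d]) {
      amp_d <- amp_d * exp(stats::rnorm(nb, 0, 0.4))
      hump <- stats::runif(1, 1, 2) *
        exp(-4 * log(2) * ((x - stats::runif(1, 600, 1600)) / 120)^2)
    }
    for (s in seq_len(m)) {
      col <- col + 1L
      amp <- amp_d * exp(stats::rnorm(nb, 0, cfg$spot_sd * stab))
      clean <- drop(prof %*% amp)
      if (!is.null(hump)) clean <- clean + hump
      ## smooth fluorescence baseline: random degree-<=6 polynomial,
      ## shifted to be non-negative
      co <- stats::rnorm(6, 0, cfg$baseline_coeffs_sd / seq_len(6))
      bl <- stats::runif(1, 0.5, 1.5) +
        drop(outer(u, seq_len(6), `^`) %*% co)
      bl <- cfg$baseline_amp * (bl - min(bl, 0))
      y <- clean + bl
      if (cfg$noise_sd > 0)
        y <- y + stats::rnorm(p, 0, cfg$noise_sd * sqrt(1 + pmax(y, 0)))
      nspk <- stats::rpois(1, cfg$cosmic_ray_rate)
      n_cosmic[col] <- nspk
      for (k in seq_len(nspk)) {
        pos <- sample.int(p - 1, 1)
        w <- sample(1:2, 1)
        y[pos:(pos + w - 1)] <- y[pos:(pos + w - 1)] +
          stats::runif(1, 30, 100) * max(cfg$noise_sd, 1e-3)
      }
      intensity[, col] <- pmax(y, 0)
      donor_id[col] <- donors$donor_id[d]
      class_label[col] <- donors$class[d]
      spot_index[col] <- s - 1L
    }
  }

  ds <- RamanSet(intensity, x, donor_id, class_label, spot_index,
                 provenance = sprintf(
                   "simulated: %d donors x %d spectra, seed %d, negatives clipped to 0",
                   nd, m, cfg$seed))
  truth <- list(
    donors = donors,
    spectra = data.frame(donor_id = donor_id, spot_index = spot_index,
                         n_cosmic = n_cosmic),
    effect_bands = data.frame(center = bands$center,
                              HC = mult[, "HC"], RD = mult[, "RD"],
                              SjD = mult[, "SjD"]))
  list(dataset = ds, truth = truth)
}
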