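#' Preprocessing configuration
#'
#' Parameters of the QC screen and the three-step preprocessing chain:
#' asymmetric weighted least-squares polynomial baseline (order 6), band
#' normalization by the amide I band at 1667 cm^-1, then Savitzky-Golay
#' smoothing (31-point window, order 5), applied in that order.
#'
#' @param baseline_order polynomial degree of the baseline fit.
#' @param norm_band normalization band center (cm^-1).
#' @param norm_window half-width (cm^-1) of the window in which the
#'   normalization maximum is located.
#' @param savgol_width odd Savitzky-Golay window length (points).
#' @param savgol_order Savitzky-Golay polynomial order (< width).
#' @param cosmic_mad_factor QC spike threshold: reject when any point rises
#'   more than this many MADs above a rolling median.
#' @param min_snr QC threshold: reject spectra whose estimated
#'   signal-to-noise ratio falls below this.
#' @param baseline_max_iter,baseline_tol iteration controls of the
#'   reweighted baseline fit (`baseline_tol` is relative to the spectrum's
#'   intensity scale).
#' @param w_above down-weight applied to points above the running baseline
#'   fit (points below keep weight 1), making the fit hug the valleys under
#'   the Raman peaks.
#' @return list of class `preprocessConfig`.
#' @export
preprocessConfig <- function(baseline_order = 6, norm_band = 1667,
                             norm_window = 5, savgol_width = 31,
                             savgol_order = 5, cosmic_mad_factor = 15,
                             min_snr = 3, baseline_max_iter = 100,
                             baseline_tol = 1e-6, w_above = 0.01) {
  stopifnot(baseline_order >= 1, savgol_width %% 2 == 1,
            savgol_order < savgol_width, norm_window > 0,
            cosmic_mad_factor > 0, min_snr > 0, w_above > 0, w_above <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "preprocessConfig"
  cfg
}

## orthogonal polynomial basis with intercept, cached per (axis, degree)
.polyBasis <- function(x, degree) {
  cbind(1, stats::poly(x, degree = degree))
}

#' Asymmetric weighted least-squares baseline correction
#'
#' Iteratively reweighted polynomial baseline: fit a degree-`baseline_order`
#' polynomial by weighted least squares, down-weight points lying above the
#' fit (weight `w_above` versus 1 below), and refit until the maximum
#' absolute change of the baseline falls under `baseline_tol` times the
#' intensity scale, or `baseline_max_iter` is reached (then the last iterate
#' is returned with a warning). The converged baseline is subtracted.
#'
#' @param y intensity vector (or a [RamanSet-class], corrected per
#'   spectrum).
#' @param wavenumbers axis matching `y` (taken from the object when `y` is
#'   a `RamanSet`).
#' @param cfg a [preprocessConfig()]
#' @return corrected vector (or `RamanSet`).
#' @export
baselineCorrect <- function(y, wavenumbers = NULL,
                            cfg = preprocessConfig()) {
  if (is(y, "RamanSet")) {
    B <- .polyBasis(wavenumbers(y), cfg$baseline_order)
    out <- apply(assay(y, "intensity"), 2, .baselineOne, B = B, cfg = cfg)
    assay(y, "intensity") <- out
    return(addProvenance(y, sprintf(
      "baseline: asymmetric WLS polynomial, order %d, w_above %g",
      cfg$baseline_order, cfg$w_above)))
  }
  stopifnot(length(y) == length(wavenumbers))
  .baselineOne(y, .polyBasis(wavenumbers, cfg$baseline_order), cfg)
}

.baselineOne <- function(y, B, cfg) {
  scale <- max(abs(y), 1e-12)
  w <- rep(1, length(y))
  bl_prev <- rep(Inf, length(y))
  converged <- FALSE
  for (it in seq_len(cfg$baseline_max_iter)) {
    wb <- B * w
    coef <- solve(crossprod(wb, B), crossprod(wb, y))
    bl <- drop(B %*% coef)
    if (max(abs(bl - bl_prev)) < cfg$baseline_tol * scale) {
      converged <- TRUE
      break
    }
    bl_prev <- bl
    w <- ifelse(y > bl, cfg$w_above, 1)
  }
  if (!converged)
    warning("baseline did not converge in ", cfg$baseline_max_iter,
            " iterations; returning last iterate")
  y - bl
}

#' Normalize a spectrum by its band maximum
#'
#' Divides all intensities by the maximum intensity found within
#' `norm_band` +/- `norm_window` cm^-1 (default: the amide I band at 1667
#' cm^-1, the most stable strong band of saliva spectra); that maximum
#' becomes exactly 1.
#'
#' @inheritParams baselineCorrect
#' @return normalized vector (or `RamanSet`). A normalizer at or below
#'   1e-10 x the spectrum scale raises a "degenerate normalization band"
#'   error — the signature of a dead spectrum or failed baseline.
#' @export
normalizeBand <- function(y, wavenumbers = NULL, cfg = preprocessConfig()) {
  if (is(y, "RamanSet")) {
    wn <- wavenumbers(y)
    idx <- .normIndex(wn, cfg)
    out <- apply(assay(y, "intensity"), 2, .normalizeOne, idx = idx)
    assay(y, "intensity") <- out
    return(addProvenance(y, sprintf(
      "normalized by max in %g +/- %g cm-1", cfg$norm_band,
      cfg$norm_window)))
  }
  .normalizeOne(y, .normIndex(wavenumbers, cfg))
}

.normIndex <- function(wn, cfg) {
  idx <- which(abs(wn - cfg$norm_band) <= cfg$norm_window)
  if (!length(idx)) stop("normalization band outside the axis range")
  idx
}

.normalizeOne <- function(y, idx) {
  m <- max(y[idx])
  if (!is.finite(m) || m <= 1e-10 * max(abs(y), 1e-300) || m <= 0)
    stop("degenerate normalization band")
  y / m
}

#' Savitzky-Golay smoothing
#'
#' Polynomial least-squares smoothing via [signal::sgolayfilt] with the
#' configured window and order (default 31 points, order 5). Edge points
#' are handled by the filter's transient rows — a polynomial fit over the
#' edge window evaluated at the edge positions — so any polynomial of
#' degree <= `savgol_order` passes through unchanged, edges included.
#'
#' @inheritParams baselineCorrect
#' @return smoothed vector (or `RamanSet`).
#' @export
smoothSpectrum <- function(y, cfg = preprocessConfig()) {
  if (is(y, "RamanSet")) {
    if (nrow(y) < cfg$savgol_width)
      stop("spectrum shorter than the Savitzky-Golay window")
    out <- apply(assay(y, "intensity"), 2, signal::sgolayfilt,
                 p = cfg$savgol_order, n = cfg$savgol_width)
    assay(y, "intensity") <- out
    return(addProvenance(y, sprintf(
      "smoothed: Savitzky-Golay width %d order %d (edge rows: truncated-window polynomial fit)",
      cfg$savgol_width, cfg$savgol_order)))
  }
  if (length(y) < cfg$savgol_width)
    stop("spectrum shorter than the Savitzky-Golay window")
  signal::sgolayfilt(y, p = cfg$savgol_order, n = cfg$savgol_width)
}

#' Quality-control screening of raw spectra
#'
#' Flags spectra for removal when (a) any point exceeds
#' `cosmic_mad_factor` x MAD above a 7-point rolling median *and* is
#' sharply isolated (an immediate neighbour's residual below half the
#' candidate's — a 1-2-point cosmic event, not a smooth band top), or
#' (b) the estimated signal-to-noise ratio — peak amplitude of
#' the baseline-corrected, lightly smoothed spectrum over a
#' first-difference noise estimate — falls below `min_snr`. Survivors are
#' returned unchanged; each rejection is logged with its reason.
#'
#' @param x a [RamanSet-class] of raw spectra
#' @param cfg a [preprocessConfig()]
#' @return the filtered `RamanSet`; the rejection log (data.frame
#'   `donor_id`, `spot_index`, `reason`) is available via [rejectionLog()].
#'   An empty result is allowed, with a warning.
#' @export
qcFilter <- function(x, cfg = preprocessConfig()) {
  stopifnot(is(x, "RamanSet"))
  wn <- wavenumbers(x)
  B <- .polyBasis(wn, cfg$baseline_order)
  Y <- assay(x, "intensity")
  reason <- character(ncol(x))
  for (j in seq_len(ncol(x))) {
    y <- Y[, j]
    if (.hasSpike(y, cfg)) {
      reason[j] <- "cosmic_ray"
      next
    }
    if (.snrEstimate(y, B, cfg) < cfg$min_snr) reason[j] <- "low_snr"
  }
  keep <- reason == ""
  log <- data.frame(donor_id = donorIds(x)[!keep],
                    spot_index = spotIndices(x)[!keep],
                    reason = reason[!keep], row.names = NULL)
  out <- x[, keep]
  out <- addProvenance(out, sprintf(
    "QC: removed %d/%d spectra (%d cosmic_ray, %d low_snr)",
    sum(!keep), length(keep), sum(reason == "cosmic_ray"),
    sum(reason == "low_snr")))
  metadata(out)$rejections <- rbind(metadata(x)$rejections, log)
  if (ncol(out) == 0) warning("QC removed every spectrum")
  out
}

## Cosmic-ray test: a point must rise cosmic_mad_factor MADs above the
## rolling median AND be sharply isolated. A genuine band top can exceed
## the MAD threshold at very low noise, but its rolling-median residual is
## smooth: both immediate neighbours hold at least half the peak residual.
## A 1-2-point cosmic event always has at least one neighbour below that.
.hasSpike <- function(y, cfg) {
  p <- length(y)
  resid <- y - stats::runmed(y, 7)
  s <- stats::mad(resid)
  if (s <= 0) return(FALSE)
  cand <- which(resid > cfg$cosmic_mad_factor * s)
  for (i in cand) {
    left <- resid[max(1L, i - 1L)]
    right <- resid[min(p, i + 1L)]
    if (min(left, right) < 0.5 * resid[i]) return(TRUE)
  }
  FALSE
}

.snrEstimate <- function(y, B, cfg) {
  corrected <- suppressWarnings(.baselineOne(y, B, cfg))
  sm <- signal::sgolayfilt(corrected, p = 3,
                           n = min(15L, length(y) - (1 - length(y) %% 2)))
  noise <- stats::mad(diff(y)) / sqrt(2)
  if (noise <= 0) return(Inf)
  max(sm) / noise
}

#' QC / preprocessing rejection log
#'
#' @param x a [RamanSet-class] that has passed through [qcFilter()] or
#'   [preprocess()]
#' @return data.frame with columns `donor_id`, `spot_index`, `reason`
#'   (empty if nothing was rejected).
#' @export
rejectionLog <- function(x) {
  metadata(x)$rejections %||%
    data.frame(donor_id = character(), spot_index = integer(),
               reason = character())
}

#' Full preprocessing chain
#'
#' Applies, in order: QC screening, asymmetric weighted least-squares
#' baseline correction, normalization by the amide I band, and
#' Savitzky-Golay smoothing. Spectra whose normalization band is degenerate
#' after baseline correction are dropped and logged with reason
#' `"degenerate_norm"`.
#'
#' @param x a raw [RamanSet-class]
#' @param cfg a [preprocessConfig()]
#' @param qc apply the QC screen first (disable for already-screened data).
#' @return the preprocessed `RamanSet` (provenance updated; rejections in
#'   [rejectionLog()]).
#' @export
preprocess <- function(x, cfg = preprocessConfig(), qc = TRUE) {
  stopifnot(is(x, "RamanSet"))
  if (qc) x <- qcFilter(x, cfg)
  x <- baselineCorrect(x, cfg = cfg)
  wn <- wavenumbers(x)
  idx <- .normIndex(wn, cfg)
  Y <- assay(x, "intensity")
  ok <- rep(TRUE, ncol(x))
  for (j in seq_len(ncol(x))) {
    res <- tryCatch(.normalizeOne(Y[, j], idx), error = function(e) NULL)
    if (is.null(res)) ok[j] <- FALSE else Y[, j] <- res
  }
  log <- data.frame(donor_id = donorIds(x)[!ok],
                    spot_index = spotIndices(x)[!ok],
                    reason = rep("degenerate_norm", sum(!ok)),
                    row.names = NULL)
  assay(x, "intensity") <- Y
  x <- x[, ok]
  metadata(x)$rejections <- rbind(metadata(x)$rejections, log)
  x <- addProvenance(x, sprintf(
    "normalized by max in %g +/- %g cm-1 (%d degenerate spectra dropped)",
    cfg$norm_band, cfg$norm_window, sum(!ok)))
  smoothSpectrum(x, cfg)
}
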