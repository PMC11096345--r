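#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' Closed vocabulary of donor class labels
#'
#' `HC` healthy control, `RD` head-and-neck radiation patient, `SjD`
#' Sjogren's disease patient. `UNKNOWN` is permitted so that unlabelled
#' external-validation sets flow through prediction.
#'
#' @export
CLASS_LEVELS <- c("HC", "RD", "SjD", "UNKNOWN")

#' RamanSet: a hyperspectral Raman dataset
#'
#' Container for a collection of Raman spectra sharing one wavenumber axis,
#' built on [SummarizedExperiment::SummarizedExperiment]. Rows are
#' wavenumbers (Raman shift, cm^-1), columns are individual spectra. Each
#' spectrum carries a donor identifier, a class label from [CLASS_LEVELS]
#' and a spot index (position in the mapping grid over the dried drop).
#' A free-text provenance log of applied transforms lives in
#' `metadata(x)$provenance` and is only ever appended to.
#'
#' Validity requires a strictly increasing numeric axis of at least 62
#' points (so that a 31-point Savitzky-Golay window and windowed wavelength
#' selection are meaningful), finite intensities, labels from the closed
#' vocabulary, and unique (donor, spot) pairs.
#'
#' @aliases RamanSet-class
#' @seealso [RamanSet()] the constructor, [readSpectra()], [simulateSpectra()]
#' @export
setClass("RamanSet", contains = "SummarizedExperiment")

.validRamanSet <- function(object) {
  msg <- character()
  wn <- rowData(object)$wavenumber
  if (is.null(wn) || !is.numeric(wn))
    msg <- c(msg, "rowData must contain a numeric 'wavenumber' column")
  else {
    if (length(wn) < 62)
      msg <- c(msg, "wavenumber axis must have at least 62 points")
    if (any(!is.finite(wn)) || any(diff(wn) <= 0))
      msg <- c(msg, "axis not strictly increasing")
  }
  cd <- colData(object)
  for (col in c("donor_id", "class_label", "spot_index"))
    if (!col %in% colnames(cd))
      msg <- c(msg, sprintf("colData must contain '%s'", col))
  if ("class_label" %in% colnames(cd)) {
    bad <- setdiff(unique(cd$class_label), CLASS_LEVELS)
    if (length(bad))
      msg <- c(msg, sprintf("unknown class label(s): %s",
                            paste(bad, collapse = ", ")))
  }
  if (all(c("donor_id", "spot_index") %in% colnames(cd)) && ncol(object)) {
    key <- paste(cd$donor_id, cd$spot_index, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "duplicated (donor_id, spot_index) pairs")
  }
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else if (ncol(object) && any(!is.finite(assay(object, "intensity"))))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
}

setValidity("RamanSet", .validRamanSet)

#' Construct a RamanSet
#'
#' @param intensity numeric matrix, wavenumbers in rows, spectra in columns.
#' @param wavenumbers strictly increasing numeric vector of Raman shifts
#'   (cm^-1), one per row of `intensity`.
#' @param donor_id character vector, one per spectrum.
#' @param class_label character vector of labels from [CLASS_LEVELS].
#' @param spot_index integer vector (>= 0) locating each spectrum within its
#'   donor's mapping grid; (donor_id, spot_index) must be unique.
#' @param provenance character vector seeding the provenance log.
#' @param excitation_nm laser excitation wavelength recorded in metadata.
#' @return A [RamanSet-class] object.
#' @examples
#' wn <- seq(400, 1800, by = 10)
#' y <- matrix(rexp(length(wn) * 3), ncol = 3)
#' rs <- RamanSet(y, wn, donor_id = c("a", "a", "b"),
#'                class_label = c("HC", "HC", "SjD"), spot_index = c(0, 1, 0))
#' rs
#' @export
RamanSet <- function(intensity, wavenumbers, donor_id, class_label,
                     spot_index, provenance = character(),
                     excitation_nm = 785) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  cd <- DataFrame(donor_id = as.character(donor_id),
                  class_label = as.character(class_label),
                  spot_index = as.integer(spot_index))
  rownames(cd) <- sprintf("%s.%d", cd$donor_id, cd$spot_index)
  colnames(intensity) <- rownames(cd)
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = DataFrame(wavenumber = as.numeric(wavenumbers)),
    colData = cd)
  metadata(se)$provenance <- as.character(provenance)
  metadata(se)$excitation_nm <- excitation_nm
  new("RamanSet", se)
}

#' Fitted PLS-DA model
#'
#' Partial least squares regression of mean-centered spectra onto one-hot
#' class indicators, stored in the projection form: `projection` maps
#' centered spectra to latent-variable (LV) scores, `coefficients` maps them
#' to predicted class indicators.
#'
#' @slot nlv number of latent variables retained.
#' @slot projection p x nlv matrix; scores = Xc %*% projection.
#' @slot loadings p x nlv X-loadings.
#' @slot yloadings nclass x nlv Y-loadings.
#' @slot coefficients p x nclass regression coefficient matrix.
#' @slot xmean,ymean centering vectors for spectra and indicators.
#' @slot scoreVar per-LV calibration score variance (lambda_a).
#' @slot classes class labels in indicator-column order.
#' @slot ncal number of calibration spectra.
#' @export
setClass("PLSDAModel",
  representation(nlv = "integer", projection = "matrix",
                 loadings = "matrix", yloadings = "matrix",
                 coefficients = "matrix", xmean = "numeric",
                 ymean = "numeric", scoreVar = "numeric",
                 classes = "character", ncal = "integer"))

setValidity("PLSDAModel", function(object) {
  msg <- character()
  if (object@nlv < 1L) msg <- c(msg, "nlv must be >= 1")
  if (ncol(object@projection) != object@nlv)
    msg <- c(msg, "projection must have nlv columns")
  if (any(object@scoreVar <= 0))
    msg <- c(msg, "score variances must be positive")
  if (length(msg)) msg else TRUE
})

#' Hotelling T-squared outlier report
#'
#' Per-spectrum T-squared values in the retained PLS-DA score space,
#' per-donor aggregates (median over the donor's spectra), the F-distribution
#' control limit and the donors flagged for removal.
#'
#' @slot t2 named numeric, per-spectrum T-squared.
#' @slot donorT2 named numeric, per-donor median T-squared.
#' @slot threshold the control limit A(n-1)/(n-A) * F_{1-alpha}(A, n-A).
#' @slot alpha confidence level used for the limit.
#' @slot nlv,ncal model dimensions the limit was computed from.
#' @slot removed donor ids whose aggregate exceeds the limit.
#' @export
setClass("T2Report",
  representation(t2 = "numeric", donorT2 = "numeric", threshold = "numeric",
                 alpha = "numeric", nlv = "integer", ncal = "integer",
                 removed = "character"))

setValidity("T2Report", function(object) {
  msg <- character()
  if (any(object@t2 < 0)) msg <- c(msg, "T2 values must be >= 0")
  if (!all(object@removed %in% names(object@donorT2)))
    msg <- c(msg, "removed donors must be a subset of scored donors")
  if (length(msg)) msg else TRUE
})

#' Genetic-algorithm wavelength-selection result
#'
#' @slot windows list of integer vectors, the variable indices of each
#'   spectral window (the GA's genes).
#' @slot runBest logical matrix, runs x windows: the best chromosome of each
#'   independent run.
#' @slot runFitness per-run best RMSECV.
#' @slot windowFrequency per-window selection frequency across run bests.
#' @slot variableFrequency the same frequencies expanded to the variable axis.
#' @slot mask final variable-level logical mask (frequency >= threshold).
#' @slot frequencyThreshold the aggregation threshold used.
#' @slot traces list (one per run) of per-generation best fitness.
#' @slot wavenumbers the variable axis the mask refers to.
#' @export
setClass("GAResult",
  representation(windows = "list", runBest = "matrix",
                 runFitness = "numeric", windowFrequency = "numeric",
                 variableFrequency = "numeric", mask = "logical",
                 frequencyThreshold = "numeric", traces = "list",
                 wavenumbers = "numeric"))

setValidity("GAResult", function(object) {
  msg <- character()
  f <- object@windowFrequency
  if (length(f) && (min(f) < 0 || max(f) > 1))
    msg <- c(msg, "selection frequencies must lie in [0, 1]")
  if (length(object@mask) != length(object@wavenumbers))
    msg <- c(msg, "mask length must equal the variable axis length")
  ok <- vapply(object@traces, function(tr)
    length(tr) < 2 || all(diff(tr) <= 1e-12), logical(1))
  if (!all(ok))
    msg <- c(msg, "best fitness must be non-increasing within each run")
  if (length(msg)) msg else TRUE
})

#' Trained SVM discriminant-analysis classifier
#'
#' Holds everything needed to classify new spectra on the training axis:
#' the wavelength mask, centering vector, PLS compression basis and the
#' fitted RBF-kernel SVM over compressed scores.
#'
#' @slot mask variable-level logical wavelength mask.
#' @slot wavenumbers training axis (full, unmasked).
#' @slot xmean centering vector over the masked variables.
#' @slot projection masked-variable x ncomp PLS compression basis.
#' @slot svm fitted [e1071::svm] object on compressed scores.
#' @slot classes class labels seen in training.
#' @slot trainingDonors donor ids used in training (contamination guard for
#'   external validation).
#' @slot cost,gamma resolved SVM hyperparameters.
#' @slot provenance free-text training log.
#' @export
setClass("RamanClassifier",
  representation(mask = "logical", wavenumbers = "numeric",
                 xmean = "numeric", projection = "matrix", svm = "ANY",
                 classes = "character", trainingDonors = "character",
                 cost = "numeric", gamma = "numeric",
                 provenance = "character"))
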