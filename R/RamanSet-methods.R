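#' @describeIn RamanSet the Raman shift axis (cm^-1)
#' @export
setMethod("wavenumbers", "RamanSet", function(x) rowData(x)$wavenumber)

#' @describeIn RamanSet per-spectrum donor identifiers
#' @export
setMethod("donorIds", "RamanSet", function(x) colData(x)$donor_id)

#' @describeIn RamanSet per-spectrum class labels
#' @export
setMethod("classLabels", "RamanSet", function(x) colData(x)$class_label)

#' @describeIn RamanSet per-spectrum spot indices within the mapping grid
#' @export
setMethod("spotIndices", "RamanSet", function(x) colData(x)$spot_index)

#' @describeIn RamanSet the append-only log of applied transforms
#' @export
setMethod("provenance", "RamanSet", function(x) metadata(x)$provenance)

#' @describeIn RamanSet append line(s) to the provenance log
#' @export
setMethod("addProvenance", "RamanSet", function(x, msg) {
  metadata(x)$provenance <- c(metadata(x)$provenance, as.character(msg))
  x
})

#' Intensity matrix in spectra-by-wavenumbers orientation
#'
#' Convenience transpose of the `intensity` assay: one row per spectrum,
#' one column per wavenumber — the orientation all the modelling code uses.
#'
#' @param x a `RamanSet`
#' @return numeric matrix, `ncol(x)` rows by `nrow(x)` columns.
#' @export
spectraMatrix <- function(x) t(assay(x, "intensity"))

setMethod("show", "RamanSet", function(object) {
  wn <- wavenumbers(object)
  cat("RamanSet:", ncol(object), "spectra,", nrow(object),
      sprintf("points (%.1f-%.1f cm-1)\n", min(wn), max(wn)))
  cl <- classLabels(object)
  don <- donorIds(object)
  for (lv in intersect(CLASS_LEVELS, unique(cl)))
    cat(sprintf("  %-8s %3d donors  %5d spectra\n", lv,
                length(unique(don[cl == lv])), sum(cl == lv)))
  prov <- provenance(object)
  if (length(prov))
    cat("provenance:", length(prov), "step(s); last:",
        utils::tail(prov, 1), "\n")
})

setMethod("show", "PLSDAModel", function(object) {
  cat("PLSDAModel:", object@nlv, "LVs over", nrow(object@projection),
      "variables;", object@ncal, "calibration spectra; classes:",
      paste(object@classes, collapse = "/"), "\n")
})

setMethod("show", "T2Report", function(object) {
  cat(sprintf(
    "T2Report: %d spectra, %d donors; limit %.2f (alpha = %.3g, A = %d)\n",
    length(object@t2), length(object@donorT2), object@threshold,
    object@alpha, object@nlv))
  if (length(object@removed))
    cat("  removed donors:", paste(object@removed, collapse = ", "), "\n")
  else cat("  no donors flagged\n")
})

setMethod("show", "GAResult", function(object) {
  cat(sprintf(
    "GAResult: %d runs over %d windows; final mask keeps %d/%d variables\n",
    nrow(object@runBest), length(object@windows), sum(object@mask),
    length(object@mask)))
  cat(sprintf("  best RMSECV %.4f (median %.4f)\n",
              min(object@runFitness), stats::median(object@runFitness)))
})

setMethod("show", "RamanClassifier", function(object) {
  cat(sprintf(
    "RamanClassifier: %d/%d variables, %d PLS components, RBF SVM (cost %.3g, gamma %.3g)\n",
    sum(object@mask), length(object@mask), ncol(object@projection),
    object@cost, object@gamma))
  cat("  classes:", paste(object@classes, collapse = "/"),
      "| trained on", length(object@trainingDonors), "donors\n")
})
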