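#' Read a spectral dataset from disk
#'
#' Reads the package's on-disk dataset layout: a directory containing
#' `spectra.csv` (columns `donor_id`, `class_label`, `spot_index`, then one
#' numeric column per wavenumber in cm^-1, increasing left to right; one row
#' per spectrum) and an optional `meta.yaml` carrying the excitation
#' wavelength and provenance log. A path ending in `.csv` is also accepted
#' and read without metadata.
#'
#' @param path directory containing `spectra.csv` (+ `meta.yaml`), or a CSV
#'   file path.
#' @return A [RamanSet-class]; row order of the CSV is preserved.
#' @seealso [writeSpectra()]
#' @export
readSpectra <- function(path) {
  if (dir.exists(path)) {
    csv <- file.path(path, "spectra.csv")
    meta_path <- file.path(path, "meta.yaml")
  } else {
    csv <- path
    meta_path <- file.path(dirname(path), "meta.yaml")
  }
  if (!file.exists(csv)) stop("no spectra.csv at ", path)
  dt <- data.table::fread(csv, header = TRUE, check.names = FALSE)
  need <- c("donor_id", "class_label", "spot_index")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  wn_cols <- setdiff(names(dt), need)
  if (anyDuplicated(names(dt)))
    stop("duplicate column(s): ",
         paste(unique(names(dt)[duplicated(names(dt))]), collapse = ", "))
  wn <- suppressWarnings(as.numeric(wn_cols))
  if (any(is.na(wn)))
    stop("non-numeric wavenumber header(s): ",
         paste(wn_cols[is.na(wn)][1], collapse = ", "))
  if (length(wn) >= 2 && any(diff(wn) <= 0))
    stop("axis not strictly increasing")
  labs <- as.character(dt$class_label)
  bad <- which(!labs %in% CLASS_LEVELS)
  if (length(bad))
    stop(sprintf("unknown class label '%s' in row %d", labs[bad[1]], bad[1]))
  intensity <- t(as.matrix(dt[, wn_cols, with = FALSE]))
  meta <- list()
  if (file.exists(meta_path)) meta <- yaml::read_yaml(meta_path)
  RamanSet(intensity, wn,
           donor_id = as.character(dt$donor_id),
           class_label = labs,
           spot_index = as.integer(dt$spot_index),
           provenance = as.character(meta$provenance %||% character()),
           excitation_nm = meta$excitation_nm %||% 785)
}

#' Write a spectral dataset to disk
#'
#' Emits `spectra.csv` and `meta.yaml` under `path` in the layout
#' [readSpectra()] inverts. The wavenumber headers are written to 2 decimal
#' places (cm^-1); intensities at full double precision, so a write/read
#' round trip reproduces the numeric payload exactly.
#'
#' @param x a [RamanSet-class]
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(x, path) {
  stopifnot(is(x, "RamanSet"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create output directory ", path)
  M <- spectraMatrix(x)
  ## %.17g guarantees an exact decimal round trip of the doubles
  dt <- data.table::as.data.table(
    matrix(sprintf("%.17g", M), nrow = nrow(M), ncol = ncol(M)))
  data.table::setnames(dt, sprintf("%.2f", wavenumbers(x)))
  dt <- cbind(data.table::data.table(
    donor_id = donorIds(x),
    class_label = classLabels(x),
    spot_index = spotIndices(x)), dt)
  data.table::fwrite(dt, file.path(path, "spectra.csv"))
  wn <- wavenumbers(x)
  yaml::write_yaml(list(
    excitation_nm = metadata(x)$excitation_nm,
    axis_min_cm1 = min(wn), axis_max_cm1 = max(wn),
    n_points = length(wn), n_spectra = ncol(x),
    provenance = as.list(provenance(x))),
    file.path(path, "meta.yaml"))
  invisible(path)
}

#' Per-class donor and spectrum counts
#'
#' @param x a [RamanSet-class]
#' @return data.frame with one row per class present plus a `total` row;
#'   columns `class`, `n_donors`, `n_spectra`. Totals conserve the record
#'   count: `n_spectra` of the total row equals `ncol(x)`.
#' @export
summarizeSpectra <- function(x) {
  stopifnot(is(x, "RamanSet"))
  cl <- classLabels(x)
  don <- donorIds(x)
  lv <- intersect(CLASS_LEVELS, unique(cl))
  out <- data.frame(
    class = c(lv, "total"),
    n_donors = c(vapply(lv, function(l) length(unique(don[cl == l])), 0L),
                 length(unique(don))),
    n_spectra = c(vapply(lv, function(l) sum(cl == l), 0L), ncol(x)),
    row.names = NULL)
  out
}

#' Per-donor spectrum counts
#'
#' @param x a [RamanSet-class]
#' @return data.frame with columns `donor_id`, `class`, `n_spectra`.
#' @export
donorCounts <- function(x) {
  don <- donorIds(x)
  cl <- classLabels(x)
  u <- !duplicated(don)
  data.frame(donor_id = don[u],
             class = cl[u],
             n_spectra = as.integer(table(don)[don[u]]),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
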