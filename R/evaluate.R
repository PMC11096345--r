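#' Custom cross-validation scheme
#'
#' `n_splits` near-equal held-out folds. `split_unit = "spectrum"` assigns
#' individual spectra to folds (the protocol mirrored here: a donor's
#' spectra can then appear on both sides of a split, which inflates
#' spectral-level figures relative to a fully donor-disjoint scheme);
#' `split_unit = "donor"` assigns whole donors and is the stricter option
#' recommended for new studies.
#'
#' @param n_splits number of folds (each held out once).
#' @param split_unit `"spectrum"` or `"donor"`.
#' @param seed seed of the random fold assignment.
#' @return list of class `cvScheme`.
#' @export
cvScheme <- function(n_splits = 50, split_unit = c("spectrum", "donor"),
                     seed = 1L) {
  split_unit <- match.arg(split_unit)
  stopifnot(n_splits >= 2)
  cfg <- list(n_splits = as.integer(n_splits), split_unit = split_unit,
              seed = seed)
  class(cfg) <- "cvScheme"
  cfg
}

.assignFolds <- function(x, scheme) {
  set.seed(scheme$seed)
  n <- ncol(x)
  if (scheme$split_unit == "spectrum") {
    if (scheme$n_splits > n) stop("more folds than spectra")
    sample(rep_len(seq_len(scheme$n_splits), n))
  } else {
    don <- donorIds(x)
    ud <- unique(don)
    if (scheme$n_splits > length(ud)) stop("more folds than donors")
    df <- sample(rep_len(seq_len(scheme$n_splits), length(ud)))
    df[match(don, ud)]
  }
}

#' Cross-validate the SVM-DA classifier
#'
#' Partitions the dataset into `n_splits` folds; for each fold the PLS
#' compression and SVM are refit on the remaining spectra (no leakage of
#' the held-out fold into centering, compression or the SVM) and the
#' held-out spectra predicted. Predictions are pooled into one confusion
#' matrix. When the SVM hyperparameters are `"auto"` they are resolved once
#' on the full dataset and reused across folds. A partition leaving a fold
#' without some class in training is redrawn once, then it is an error.
#'
#' @param x a labelled, preprocessed [RamanSet-class]
#' @param mask variable-level wavelength mask (`NULL` = all variables).
#' @param cfg a [classifierConfig()]
#' @param scheme a [cvScheme()]
#' @return list with `confusion` (predicted x actual count matrix),
#'   `predictions` (per-spectrum held-out predictions with fold ids) and
#'   `scheme`.
#' @export
crossValidate <- function(x, mask = NULL, cfg = classifierConfig(),
                          scheme = cvScheme()) {
  stopifnot(is(x, "RamanSet"))
  labels <- classLabels(x)
  classes <- intersect(CLASS_LEVELS, unique(labels))
  ## resolve "auto" hyperparameters once so every fold uses the same ones
  if (identical(cfg$svm_cost, "auto") || identical(cfg$rbf_gamma, "auto")) {
    full <- trainClassifier(x, mask, cfg)
    cfg$svm_cost <- full@cost
    cfg$rbf_gamma <- full@gamma
  }
  fold <- .assignFolds(x, scheme)
  for (attempt in 1:2) {
    ok <- all(vapply(seq_len(scheme$n_splits), function(f)
      length(unique(labels[fold != f])) == length(classes), logical(1)))
    if (ok) break
    if (attempt == 2L)
      stop("a fold leaves a class absent from training even after redraw")
    scheme$seed <- scheme$seed + 104729L
    fold <- .assignFolds(x, scheme)
  }
  preds <- vector("list", scheme$n_splits)
  for (f in seq_len(scheme$n_splits)) {
    tr <- fold != f
    clf <- trainClassifier(x[, tr], mask, cfg)
    pf <- predictClasses(clf, x[, !tr])
    pf$fold <- f
    preds[[f]] <- pf
  }
  predictions <- do.call(rbind, preds)
  list(confusion = confusionCounts(predictions$predicted,
                                   predictions$actual, classes),
       predictions = predictions, scheme = scheme)
}

#' Build a confusion-count matrix
#'
#' Rows are predicted classes, columns actual classes; column sums equal
#' the per-class actual totals and the grand total equals the number of
#' evaluated spectra.
#'
#' @param predicted,actual label vectors of equal length.
#' @param classes class order (default: the labels seen, in canonical
#'   HC/RD/SjD order).
#' @return integer matrix `classes` x `classes`.
#' @export
confusionCounts <- function(predicted, actual, classes = NULL) {
  stopifnot(length(predicted) == length(actual))
  if (is.null(classes))
    classes <- intersect(CLASS_LEVELS, unique(c(actual, predicted)))
  tab <- table(factor(predicted, levels = classes),
               factor(actual, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(predicted = classes, actual = classes))
  m
}

#' Per-class sensitivity, specificity and class error
#'
#' For class c: sensitivity = cm[c, c] / (actual-c column total);
#' specificity = TN / (TN + FP), with FP the off-diagonal of the predicted-c
#' row and TN the non-c actual total minus FP; class error =
#' 1 - (sensitivity + specificity) / 2. An empty actual column yields `NA`
#' sensitivity.
#'
#' @param cm a square predicted x actual count matrix, e.g. from
#'   [confusionCounts()].
#' @return data.frame with columns `class`, `sensitivity`, `specificity`,
#'   `class_error`.
#' @export
confusionMetrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  classes <- rownames(cm)
  total <- sum(cm)
  out <- data.frame(class = classes, sensitivity = NA_real_,
                    specificity = NA_real_, class_error = NA_real_,
                    row.names = NULL)
  for (i in seq_along(classes)) {
    actual_c <- sum(cm[, i])
    sens <- if (actual_c > 0) cm[i, i] / actual_c else NA_real_
    fp <- sum(cm[i, ]) - cm[i, i]
    tn <- (total - actual_c) - fp
    spec <- if (total - actual_c > 0) tn / (tn + fp) else NA_real_
    out$sensitivity[i] <- sens
    out$specificity[i] <- spec
    out$class_error[i] <- 1 - (sens + spec) / 2
  }
  out
}

#' Round half away from zero
#'
#' Presentation rounding for reported metrics (0.005 -> 0.01), unlike
#' [round()]'s round-half-even.
#'
#' @param x numeric
#' @param digits decimal places
#' @export
roundHalfUp <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Spectral-to-donor majority voting
#'
#' Per donor: the fraction of its spectra assigned to each class; the donor
#' is called as the arg-max class iff that fraction reaches `threshold` and
#' is a unique maximum, otherwise `INDETERMINATE` (ties are never called).
#' Donor accuracy is the fraction of correct calls among donors with known
#' labels.
#'
#' @param predictions data.frame with columns `donor_id`, `predicted` and
#'   (optionally) `actual`, e.g. from [crossValidate()]`$predictions` or
#'   [predictClasses()].
#' @param threshold vote fraction required to call a donor (default 0.5).
#' @param classes class order of the fraction columns.
#' @return list with `votes` (data.frame: `donor_id`, `actual`, one
#'   `frac_*` column per class, `call`) and `accuracy` (`NA` when no donor
#'   has a known label).
#' @export
voteDonors <- function(predictions, threshold = 0.5, classes = NULL) {
  stopifnot(all(c("donor_id", "predicted") %in% names(predictions)))
  if (is.null(classes))
    classes <- intersect(CLASS_LEVELS, unique(predictions$predicted))
  don <- unique(predictions$donor_id)
  fr <- matrix(0, length(don), length(classes),
               dimnames = list(don, classes))
  for (i in seq_along(don)) {
    p <- predictions$predicted[predictions$donor_id == don[i]]
    fr[i, ] <- vapply(classes, function(cl) mean(p == cl), numeric(1))
  }
  call <- apply(fr, 1, function(v) {
    top <- max(v)
    if (top >= threshold && sum(v == top) == 1L)
      classes[which.max(v)] else "INDETERMINATE"
  })
  actual <- if ("actual" %in% names(predictions))
    predictions$actual[match(don, predictions$donor_id)] else
      rep("UNKNOWN", length(don))
  votes <- data.frame(donor_id = don, actual = actual, row.names = NULL)
  for (cl in classes) votes[[paste0("frac_", cl)]] <- fr[, cl]
  votes$call <- unname(call)
  known <- actual != "UNKNOWN"
  acc <- if (any(known)) mean(votes$call[known] == actual[known]) else
    NA_real_
  list(votes = votes, accuracy = acc, threshold = threshold)
}

#' External validation of a trained classifier
#'
#' Predicts an external dataset whose donors must be disjoint from the
#' training donors (checked by donor id — contamination guard), then
#' applies donor-level majority voting. Spectral accuracy and donor call
#' correctness are reported when labels are known; an `UNKNOWN`-labelled
#' set yields fractions and calls only.
#'
#' @param clf a [RamanClassifier-class]
#' @param x_ext external [RamanSet-class] on the training axis
#' @param threshold vote threshold passed to [voteDonors()].
#' @return list with `votes`, `donor_accuracy`, `spectral_accuracy`,
#'   `predictions`.
#' @export
externalValidate <- function(clf, x_ext, threshold = 0.5) {
  overlap <- intersect(unique(donorIds(x_ext)), clf@trainingDonors)
  if (length(overlap))
    stop("external donors overlap the training set: ",
         paste(overlap, collapse = ", "))
  predictions <- predictClasses(clf, x_ext)
  vote <- voteDonors(predictions, threshold, classes = clf@classes)
  known <- predictions$actual != "UNKNOWN"
  spectral <- if (any(known))
    mean(predictions$predicted[known] == predictions$actual[known]) else
      NA_real_
  list(votes = vote$votes, donor_accuracy = vote$accuracy,
       spectral_accuracy = spectral, predictions = predictions)
}
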