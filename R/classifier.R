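#' SVM discriminant-analysis classifier configuration
#'
#' The classifier applies the wavelength mask, mean-centers, compresses the
#' masked spectra onto `compress_ncomp` PLS components (fit against one-hot
#' labels) and trains an RBF-kernel SVM (one-vs-one multi-class) on the
#' compressed scores. `"auto"` hyperparameters are resolved by a small,
#' fully logged grid — cost in `cost_grid`, gamma in `gamma_scale` times
#' the median-distance heuristic 1/median(d^2) — chosen by deterministic
#' donor-grouped inner CV on the scores (grouping by donor makes the
#' selection target generalization to unseen donors rather than
#' recognition of donors already in the training set).
#'
#' @param compress_ncomp PLS compression components (default 11).
#' @param svm_cost positive number or `"auto"`.
#' @param rbf_gamma positive number or `"auto"`.
#' @param cost_grid,gamma_scale the `"auto"` search grid.
#' @param tune_folds inner-CV folds of the grid search.
#' @return list of class `classifierConfig`.
#' @export
classifierConfig <- function(compress_ncomp = 11, svm_cost = "auto",
                             rbf_gamma = "auto",
                             cost_grid = c(1, 10, 100),
                             gamma_scale = c(0.1, 1, 10),
                             tune_folds = 5) {
  stopifnot(compress_ncomp >= 1,
            identical(svm_cost, "auto") || svm_cost > 0,
            identical(rbf_gamma, "auto") || rbf_gamma > 0,
            all(cost_grid > 0), all(gamma_scale > 0), tune_folds >= 2)
  cfg <- as.list(environment())
  class(cfg) <- "classifierConfig"
  cfg
}

## median squared pairwise distance on (a subsample of) score rows
.medianDist2 <- function(S) {
  n <- nrow(S)
  if (n > 400L) S <- S[round(seq(1L, n, length.out = 400L)), , drop = FALSE]
  stats::median(stats::dist(S)^2)
}

.resolveHyper <- function(S, labels, donors, cfg) {
  g0 <- 1 / max(.medianDist2(S), 1e-12)
  costs <- if (identical(cfg$svm_cost, "auto")) cfg$cost_grid else cfg$svm_cost
  gammas <- if (identical(cfg$rbf_gamma, "auto")) g0 * cfg$gamma_scale else
    cfg$rbf_gamma
  if (length(costs) == 1L && length(gammas) == 1L)
    return(c(cost = costs, gamma = gammas))
  ## donor-grouped deterministic folds
  ud <- unique(donors)
  k <- min(cfg$tune_folds, length(ud))
  fold <- .venetianFolds(length(ud), k)[match(donors, ud)]
  best <- c(cost = costs[1], gamma = gammas[1])
  best_acc <- -1
  y <- factor(labels)
  for (co in costs) for (ga in gammas) {
    acc <- 0
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) next
      m <- e1071::svm(S[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = co, gamma = ga, scale = FALSE)
      acc <- acc + sum(stats::predict(m, S[!tr, , drop = FALSE]) == y[!tr])
    }
    if (acc > best_acc) {
      best_acc <- acc
      best <- c(cost = co, gamma = ga)
    }
  }
  best
}

#' Train the SVM discriminant-analysis classifier
#'
#' @param x a labelled, preprocessed [RamanSet-class]
#' @param mask variable-level logical wavelength mask (`NULL` = all
#'   variables), e.g. the `mask` slot of a [GAResult-class].
#' @param cfg a [classifierConfig()]
#' @return a [RamanClassifier-class]
#' @seealso [predictClasses()], [crossValidate()]
#' @export
trainClassifier <- function(x, mask = NULL, cfg = classifierConfig()) {
  stopifnot(is(x, "RamanSet"))
  labels <- classLabels(x)
  if (any(labels == "UNKNOWN")) stop("cannot train on UNKNOWN labels")
  if (length(unique(labels)) < 2L) stop("training data has a single class")
  p <- nrow(x)
  if (is.null(mask)) mask <- rep(TRUE, p)
  stopifnot(length(mask) == p)
  if (!any(mask)) stop("empty wavelength mask")
  X <- spectraMatrix(x)[, mask, drop = FALSE]
  n <- nrow(X)
  if (cfg$compress_ncomp > min(ncol(X), n - 1L))
    stop("compress_ncomp exceeds the rank of the masked data")
  Y <- .onehot(labels)
  cp <- .centeredCrossprods(X, Y)
  fit <- .plsKernel(cp$XtX, cp$XtY, cfg$compress_ncomp)
  if (is.null(fit) || fit$ncomp < cfg$compress_ncomp)
    stop("compress_ncomp exceeds the rank of the masked data")
  S <- sweep(X, 2, cp$xmean) %*% fit$R
  hyper <- .resolveHyper(S, labels, donorIds(x), cfg)
  machine <- e1071::svm(S, factor(labels, levels = colnames(Y)),
                        kernel = "radial", cost = hyper["cost"],
                        gamma = hyper["gamma"], scale = FALSE)
  new("RamanClassifier", mask = as.logical(mask),
      wavenumbers = wavenumbers(x), xmean = cp$xmean, projection = fit$R,
      svm = machine, classes = colnames(Y),
      trainingDonors = unique(donorIds(x)),
      cost = unname(hyper["cost"]), gamma = unname(hyper["gamma"]),
      provenance = sprintf(
        "SVM-DA: %d/%d variables, %d PLS components, RBF cost %.4g gamma %.4g, %d spectra",
        sum(mask), p, cfg$compress_ncomp, hyper["cost"], hyper["gamma"], n))
}

#' Classify spectra with a trained classifier
#'
#' Deterministic given the model: spectra are masked, centered with the
#' training means, projected onto the stored PLS compression basis and
#' passed to the SVM. The smallest absolute pairwise decision value is
#' reported as a confidence margin (a value near 0 marks a spectrum the
#' model barely separates).
#'
#' @param clf a [RamanClassifier-class]
#' @param x a [RamanSet-class] on the training axis
#' @return data.frame with columns `donor_id`, `spot_index`, `actual`,
#'   `predicted`, `margin`.
#' @export
predictClasses <- function(clf, x) {
  stopifnot(is(clf, "RamanClassifier"), is(x, "RamanSet"))
  if (!isTRUE(all.equal(wavenumbers(x), clf@wavenumbers)))
    stop("axis mismatch: spectra are not on the training wavenumber axis")
  X <- spectraMatrix(x)[, clf@mask, drop = FALSE]
  S <- sweep(X, 2, clf@xmean) %*% clf@projection
  pred <- stats::predict(clf@svm, S, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  data.frame(donor_id = donorIds(x), spot_index = spotIndices(x),
             actual = classLabels(x), predicted = as.character(pred),
             margin = apply(abs(dv), 1, min), row.names = NULL)
}
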