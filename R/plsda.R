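#' Fit a PLS-DA model
#'
#' Partial least-squares regression of mean-centered spectra onto one-hot
#' class indicators (kernel algorithm on cross-product matrices). Scores,
#' loadings and per-LV calibration score variances are retained — the
#' latter feed the Hotelling T-squared statistic.
#'
#' @param x a labelled, preprocessed [RamanSet-class]
#' @param nlv number of latent variables (must be <= min(n - 1, p)).
#' @return a [PLSDAModel-class]
#' @seealso [hotellingT2()], [plsdaCVError()] for choosing `nlv`
#' @export
fitPLSDA <- function(x, nlv = 11) {
  stopifnot(is(x, "RamanSet"))
  X <- spectraMatrix(x)
  labels <- classLabels(x)
  if (any(labels == "UNKNOWN")) stop("cannot fit PLS-DA on UNKNOWN labels")
  n <- nrow(X)
  p <- ncol(X)
  nlv <- as.integer(nlv)
  if (nlv < 1L || nlv > min(n - 1L, p))
    stop(sprintf("nlv must be in [1, min(n - 1, p)] = [1, %d]",
                 min(n - 1L, p)))
  Y <- .onehot(labels)
  cp <- .centeredCrossprods(X, Y)
  fit <- .plsKernel(cp$XtX, cp$XtY, nlv)
  if (is.null(fit) || fit$ncomp < nlv)
    stop("requested nlv exceeds the rank of the centered data")
  scoreVar <- fit$tt / (n - 1)
  new("PLSDAModel", nlv = nlv, projection = fit$R, loadings = fit$P,
      yloadings = fit$Q, coefficients = fit$B, xmean = cp$xmean,
      ymean = cp$ymean, scoreVar = scoreVar,
      classes = colnames(Y), ncal = as.integer(n))
}

#' Latent-variable scores of spectra under a PLS-DA model
#'
#' @param model a [PLSDAModel-class]
#' @param x a [RamanSet-class] on the same axis
#' @return n x nlv score matrix.
#' @export
plsdaScores <- function(model, x) {
  X <- spectraMatrix(x)
  if (ncol(X) != length(model@xmean)) stop("axis mismatch")
  sweep(X, 2, model@xmean) %*% model@projection
}

#' Predicted class indicators and labels under a PLS-DA model
#'
#' @inheritParams plsdaScores
#' @return data.frame of predicted indicators (one column per class) plus a
#'   `predicted` column holding the arg-max label.
#' @export
plsdaPredict <- function(model, x) {
  X <- spectraMatrix(x)
  if (ncol(X) != length(model@xmean)) stop("axis mismatch")
  Yhat <- sweep(X, 2, model@xmean) %*% model@coefficients
  Yhat <- sweep(Yhat, 2, model@ymean, `+`)
  colnames(Yhat) <- model@classes
  out <- as.data.frame(Yhat)
  out$predicted <- model@classes[max.col(Yhat, ties.method = "first")]
  out
}

#' Cross-validated PLS-DA indicator error per LV count
#'
#' Venetian-blinds k-fold RMSECV of the one-hot indicator prediction for
#' 1..`max_lv` latent variables — the standard curve used to justify an LV
#' choice.
#'
#' @param x a labelled [RamanSet-class]
#' @param max_lv largest LV count to evaluate.
#' @param folds number of venetian-blinds folds.
#' @return data.frame with columns `nlv`, `rmsecv`.
#' @export
plsdaCVError <- function(x, max_lv = 15, folds = 10) {
  X <- spectraMatrix(x)
  Y <- .onehot(classLabels(x))
  n <- nrow(X)
  fold <- .venetianFolds(n, folds)
  max_lv <- min(max_lv, ncol(X), n - ceiling(n / folds) - 1L)
  sse <- numeric(max_lv)
  for (f in seq_len(folds)) {
    tr <- fold != f
    cp <- .centeredCrossprods(X[tr, , drop = FALSE], Y[tr, , drop = FALSE])
    fit <- .plsKernel(cp$XtX, cp$XtY, max_lv)
    Xc <- sweep(X[!tr, , drop = FALSE], 2, cp$xmean)
    Tnew <- Xc %*% fit$R
    for (a in seq_len(fit$ncomp)) {
      Yhat <- Tnew[, seq_len(a), drop = FALSE] %*%
        t(fit$Q[, seq_len(a), drop = FALSE])
      Yhat <- sweep(Yhat, 2, cp$ymean, `+`)
      sse[a] <- sse[a] + sum((Y[!tr, , drop = FALSE] - Yhat)^2)
    }
  }
  data.frame(nlv = seq_len(max_lv),
             rmsecv = sqrt(sse / (n * ncol(Y))))
}

#' Hotelling T-squared outlier report
#'
#' For each spectrum, T2 = sum over retained LVs of t_a^2 / lambda_a, where
#' lambda_a is the calibration score variance of LV a. The control limit is
#' the F-distribution form A(n-1)/(n-A) * F(1 - alpha; A, n - A). Donors are
#' aggregated by the median of their spectra's T2 values; donors whose
#' aggregate exceeds the limit are listed for removal.
#'
#' @param model a [PLSDAModel-class] fitted on `x`
#' @param x the [RamanSet-class] the model was calibrated on
#' @param alpha significance level of the limit (default 0.01, a
#'   conservative 99% threshold).
#' @return a [T2Report-class]
#' @export
hotellingT2 <- function(model, x, alpha = 0.01) {
  A <- model@nlv
  n <- model@ncal
  if (n <= A) stop("control limit undefined: n must exceed the LV count")
  Ts <- plsdaScores(model, x)
  t2 <- rowSums(sweep(Ts^2, 2, model@scoreVar, `/`))
  names(t2) <- colnames(x)
  donor <- donorIds(x)
  donorT2 <- vapply(split(t2, donor), stats::median, numeric(1))
  limit <- A * (n - 1) / (n - A) * stats::qf(1 - alpha, A, n - A)
  new("T2Report", t2 = t2, donorT2 = donorT2, threshold = limit,
      alpha = alpha, nlv = A, ncal = as.integer(n),
      removed = names(donorT2)[donorT2 > limit])
}

#' Remove the donors flagged by a T-squared report
#'
#' Drops all spectra of the removed donors; donor ids and the threshold are
#' logged in provenance.
#'
#' @param x the [RamanSet-class] the report was computed on
#' @param report a [T2Report-class]
#' @return the filtered `RamanSet` (unchanged when nothing was flagged).
#' @export
removeOutliers <- function(x, report) {
  stopifnot(is(x, "RamanSet"), is(report, "T2Report"))
  if (!length(report@removed))
    return(addProvenance(x, sprintf(
      "Hotelling T2 (alpha %g, limit %.2f): no outlier donors",
      report@alpha, report@threshold)))
  keep <- !donorIds(x) %in% report@removed
  out <- x[, keep]
  if (ncol(out) == 0) warning("outlier removal dropped every donor")
  addProvenance(out, sprintf(
    "Hotelling T2 (alpha %g, limit %.2f): removed donors %s",
    report@alpha, report@threshold,
    paste(report@removed, collapse = ", ")))
}
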