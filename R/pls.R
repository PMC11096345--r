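## Kernel-form PLS2 (Dayal & MacGregor modified kernel algorithm):
## works entirely from the cross-product matrices X'X (p x p) and X'Y
## (p x q) of centered data. This form is what makes GA fitness evaluation
## affordable — per-fold Gram matrices are precomputed once and training
## cross-products for any wavelength mask are obtained by subsetting.

## XtX, XtY must already be centered. Returns projection R (scores =
## Xc %*% R), loadings P, Q, coefficient matrix B = R Q', and t't per LV.
.plsKernel <- function(XtX, XtY, ncomp) {
  p <- nrow(XtX)
  q <- ncol(XtY)
  ncomp <- min(ncomp, p)
  R <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp)
  tt <- numeric(ncomp)
  XtYd <- XtY
  a <- 0L
  while (a < ncomp) {
    a <- a + 1L
    if (q == 1L) {
      w <- XtYd[, 1]
    } else {
      ## dominant left singular vector of XtY via the q x q eigenproblem
      M <- crossprod(XtYd)
      ev <- eigen(M, symmetric = TRUE)
      w <- drop(XtYd %*% ev$vectors[, 1])
    }
    nw <- sqrt(sum(w * w))
    if (!is.finite(nw) || nw < 1e-12) { a <- a - 1L; break }
    w <- w / nw
    r <- w
    if (a > 1L)
      r <- r - R[, seq_len(a - 1L), drop = FALSE] %*%
        crossprod(P[, seq_len(a - 1L), drop = FALSE], w)
    XtXr <- drop(XtX %*% r)
    tta <- sum(r * XtXr)
    if (!is.finite(tta) || tta < 1e-12) { a <- a - 1L; break }
    P[, a] <- XtXr / tta
    Q[, a] <- crossprod(XtYd, r) / tta
    XtYd <- XtYd - XtXr %*% t(Q[, a])
    R[, a] <- r
    tt[a] <- tta
  }
  if (a == 0L) return(NULL)
  keep <- seq_len(a)
  R <- R[, keep, drop = FALSE]
  Q <- Q[, keep, drop = FALSE]
  list(R = R, P = P[, keep, drop = FALSE], Q = Q,
       B = R %*% t(Q), tt = tt[keep], ncomp = a)
}

## Centered cross-products from raw X (n x p) and Y (n x q)
.centeredCrossprods <- function(X, Y) {
  n <- nrow(X)
  xm <- colMeans(X)
  ym <- colMeans(Y)
  XtX <- crossprod(X) - n * tcrossprod(xm)
  XtY <- crossprod(X, Y) - n * tcrossprod(xm, ym)
  list(XtX = XtX, XtY = XtY, xmean = xm, ymean = ym, n = n)
}

## One-hot indicator matrix for a label vector, fixed class order
.onehot <- function(labels, classes = NULL) {
  if (is.null(classes)) classes <- intersect(CLASS_LEVELS, unique(labels))
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  for (k in seq_along(classes)) Y[labels == classes[k], k] <- 1
  Y
}

## Deterministic venetian-blinds fold assignment: 1,2,...,k,1,2,...
.venetianFolds <- function(n, k) ((seq_len(n) - 1L) %% k) + 1L
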