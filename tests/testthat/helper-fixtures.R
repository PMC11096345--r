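## Fixture builders and independent oracles shared across the test files.

## A small clean generator config: coarse axis for speed, no cosmic rays
## (the spike detector assumes sampling fine enough that real bands span
## many points, so coarse-axis fixtures skip QC).
smallConfig <- function(n = c(HC = 5, RD = 5, SjD = 5), m = 8, step = 8,
                        seed = 1, ...) {
  generatorConfig(n_donors = n, spectra_per_donor = m,
                  wavenumbers = seq(400, 1800, by = step),
                  cosmic_ray_rate = 0, seed = seed, ...)
}

## Three linearly separable classes: disjoint strong top-hat features on an
## otherwise flat spectrum, negligible noise.
separableSet <- function(n_per_class = 10, p = 90, noise = 1e-3,
                         seed = 42) {
  set.seed(seed)
  classes <- c("HC", "RD", "SjD")
  wn <- seq(400, by = 10, length.out = p)
  blocks <- list(HC = 11:20, RD = 41:50, SjD = 71:80)
  n <- n_per_class * 3
  X <- matrix(stats::rnorm(n * p, 0, noise), n, p)
  lab <- rep(classes, each = n_per_class)
  for (i in seq_len(n)) X[i, blocks[[lab[i]]]] <- X[i, blocks[[lab[i]]]] + 1
  RamanSet(t(X), wn,
           donor_id = sprintf("%s%02d", lab, rep(seq_len(n_per_class), 3)),
           class_label = lab,
           spot_index = rep(0L, n))
}

## Independent NIPALS PLS2 oracle (deflation form, nothing shared with the
## package's kernel-algorithm implementation).
nipalsPLS <- function(X, Y, A) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  E <- Xc; FF <- Yc
  W <- P <- Q <- TT <- NULL
  for (a in seq_len(A)) {
    u <- FF[, which.max(colSums(FF^2))]
    for (it in 1:500) {
      w <- crossprod(E, u); w <- w / sqrt(sum(w^2))
      tv <- E %*% w
      q <- crossprod(FF, tv) / sum(tv^2)
      unew <- FF %*% q / sum(q^2)
      if (sum((unew - u)^2) < 1e-14 * max(sum(u^2), 1e-300)) {
        u <- unew; break
      }
      u <- unew
    }
    p_ <- crossprod(E, tv) / sum(tv^2)
    E <- E - tv %*% t(p_)
    FF <- FF - tv %*% t(q)
    W <- cbind(W, w); P <- cbind(P, p_); Q <- cbind(Q, q)
    TT <- cbind(TT, tv)
  }
  list(B = W %*% solve(t(P) %*% W) %*% t(Q), scores = TT,
       xmean = colMeans(X), ymean = colMeans(Y))
}

onehot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  for (k in seq_along(classes)) Y[labels == classes[k], k] <- 1
  Y
}

## The printed cross-validation confusion matrix of the calibration study
## (rows predicted, columns actual).
studyConfusion <- function() {
  matrix(as.integer(c(494, 25, 69,
           23, 440, 36,
           76, 57, 658)),
         nrow = 3, byrow = TRUE,
         dimnames = list(predicted = c("HC", "RD", "SjD"),
                         actual = c("HC", "RD", "SjD")))
}
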