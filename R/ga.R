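#' Genetic-algorithm configuration for wavelength selection
#'
#' Defaults follow the study settings: population 62, per-gene mutation
#' rate 0.005, up to 100 generations per run, double crossover, ~30% of
#' windows switched on in random initial chromosomes, and 100 independent
#' runs whose best chromosomes are aggregated into per-variable selection
#' frequencies. Chromosomes address spectral windows (groups of
#' `window_width_points` adjacent variables), not single variables.
#'
#' @param population_size even number of chromosomes.
#' @param mutation_rate per-gene per-generation flip probability.
#' @param max_generations generation cap per run (0 = evaluate the initial
#'   population only).
#' @param window_fraction expected fraction of windows on in initial
#'   chromosomes.
#' @param window_width_points adjacent variables grouped per window/gene.
#' @param n_runs independent GA runs aggregated by selection frequency.
#' @param cv_folds venetian-blinds folds of the RMSECV fitness; folds are
#'   assigned at the *donor* level (all spectra of a donor share a fold),
#'   otherwise the fitness rewards windows that identify donors rather
#'   than classes.
#' @param inner_lv latent variables of the fitness PLS-DA model.
#' @param frequency_threshold a variable enters the final mask when its
#'   selection frequency across run-best chromosomes reaches this value.
#' @param convergence_tol stop a run early when the population fitness
#'   spread falls below this.
#' @param seed base seed; run r uses `seed + r`.
#' @return list of class `gaConfig`.
#' @export
gaConfig <- function(population_size = 62, mutation_rate = 0.005,
                     max_generations = 100, window_fraction = 0.30,
                     window_width_points = 15, n_runs = 100,
                     cv_folds = 10, inner_lv = 11,
                     frequency_threshold = 0.5, convergence_tol = 1e-6,
                     seed = 1L) {
  stopifnot(population_size >= 4, population_size %% 2 == 0,
            mutation_rate > 0, mutation_rate < 1,
            max_generations >= 0, window_fraction > 0,
            window_fraction < 1, window_width_points >= 1,
            n_runs >= 1, cv_folds >= 2, inner_lv >= 1,
            frequency_threshold > 0, frequency_threshold <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "gaConfig"
  cfg
}

## worst-possible fitness sentinel for empty / rank-deficient masks
.RMSECV_SENTINEL <- 1e6

.makeWindows <- function(p, width) {
  starts <- seq(1L, p, by = width)
  lapply(starts, function(s) s:min(s + width - 1L, p))
}

## Per-fold Gram matrices (stacked into arrays for the compiled fitness
## kernel) so that masked training cross-products are obtained by
## subsetting instead of refitting from raw data.
.gaPrecompute <- function(X, Y, folds, donors = NULL) {
  n <- nrow(X)
  p <- ncol(X)
  q <- ncol(Y)
  if (is.null(donors)) {
    fold <- .venetianFolds(n, folds)
  } else {
    ud <- unique(donors)
    folds <- min(folds, length(ud))
    fold <- .venetianFolds(length(ud), folds)[match(donors, ud)]
  }
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  sx <- colSums(X)
  sy <- colSums(Y)
  ## per-fold TRAINING cross-products (total minus held-out fold)
  XtXtr <- array(0, c(p, p, folds))
  XtYtr <- array(0, c(p, q, folds))
  sxtr <- matrix(0, p, folds)
  sytr <- matrix(0, q, folds)
  for (f in seq_len(folds)) {
    Xf <- X[fold == f, , drop = FALSE]
    Yf <- Y[fold == f, , drop = FALSE]
    XtXtr[, , f] <- XtX - crossprod(Xf)
    XtYtr[, , f] <- XtY - crossprod(Xf, Yf)
    sxtr[, f] <- sx - colSums(Xf)
    sytr[, f] <- sy - colSums(Yf)
  }
  list(X = X, Y = Y, fold = fold, folds = folds, n = n,
       XtXtr = XtXtr, XtYtr = XtYtr, sxtr = sxtr, sytr = sytr)
}

.maskFitnessPre <- function(pre, vars, nlv) {
  if (length(vars) == 0L) return(.RMSECV_SENTINEL)
  cpp_mask_rmsecv(pre$X, pre$Y, as.integer(pre$fold), pre$XtXtr,
                  pre$XtYtr, pre$sxtr, pre$sytr, as.integer(vars),
                  as.integer(nlv), .RMSECV_SENTINEL)
}

#' RMSECV fitness of a wavelength-window mask
#'
#' PLS-DA on the masked variables, venetian-blinds k-fold cross-validation
#' with donor-grouped fold assignment; RMSECV = sqrt(mean over held-out
#' spectra and indicator columns of (indicator - prediction)^2). An empty
#' or fully rank-deficient mask returns the declared worst-fitness
#' sentinel (1e6) instead of failing.
#'
#' @param x a labelled, preprocessed [RamanSet-class]
#' @param window_mask logical vector over the spectral windows implied by
#'   `cfg$window_width_points`.
#' @param cfg a [gaConfig()]
#' @return RMSECV scalar.
#' @export
rmsecvFitness <- function(x, window_mask, cfg = gaConfig()) {
  X <- spectraMatrix(x)
  Y <- .onehot(classLabels(x))
  windows <- .makeWindows(ncol(X), cfg$window_width_points)
  stopifnot(length(window_mask) == length(windows))
  pre <- .gaPrecompute(X, Y, cfg$cv_folds, donorIds(x))
  .maskFitnessPre(pre, unlist(windows[window_mask]), cfg$inner_lv)
}

.doubleCrossover <- function(a, b) {
  ng <- length(a)
  cuts <- sort(sample.int(ng - 1L, 2L))
  mid <- (cuts[1] + 1L):cuts[2]
  c1 <- a; c1[mid] <- b[mid]
  c2 <- b; c2[mid] <- a[mid]
  rbind(c1, c2)
}

#' Run the genetic-algorithm wavelength selection
#'
#' Per run: a random initial population (each chromosome switches on
#' ~`window_fraction` of the windows) is evaluated by RMSECV fitness,
#' ranked, the top half retained, offspring bred from random survivor pairs
#' by double crossover (two cut points, middle segment swapped) and mutated
#' gene-wise; iterate to `max_generations` or until the population fitness
#' spread drops below `convergence_tol`. The best chromosome never leaves
#' the population, so best fitness is non-increasing. Across `n_runs`
#' independent runs, per-window selection frequencies over the run-best
#' chromosomes are aggregated; the final mask keeps variables whose window
#' frequency reaches `frequency_threshold`.
#'
#' @param x a labelled, preprocessed, outlier-free [RamanSet-class]
#' @param cfg a [gaConfig()]
#' @return a [GAResult-class]
#' @seealso [selectedBands()] to tabulate the mask as wavenumber intervals
#' @export
runGA <- function(x, cfg = gaConfig()) {
  X <- spectraMatrix(x)
  Y <- .onehot(classLabels(x))
  n <- nrow(X)
  if (n < cfg$cv_folds) stop("dataset smaller than the CV fold count")
  windows <- .makeWindows(ncol(X), cfg$window_width_points)
  ng <- length(windows)
  pre <- .gaPrecompute(X, Y, cfg$cv_folds, donorIds(x))
  cache <- new.env(parent = emptyenv())
  evalChrom <- function(chrom) {
    key <- rawToChar(as.raw(44L + chrom))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- .maskFitnessPre(pre, unlist(windows[as.logical(chrom)]),
                           cfg$inner_lv)
    cache[[key]] <- val
    val
  }
  half <- cfg$population_size %/% 2L
  runBest <- matrix(FALSE, cfg$n_runs, ng)
  runFitness <- numeric(cfg$n_runs)
  traces <- vector("list", cfg$n_runs)
  for (r in seq_len(cfg$n_runs)) {
    set.seed(cfg$seed + r)
    pop <- matrix(stats::runif(cfg$population_size * ng) <
                    cfg$window_fraction,
                  cfg$population_size, ng)
    none <- rowSums(pop) == 0L
    if (any(none))
      pop[cbind(which(none), sample.int(ng, sum(none), replace = TRUE))] <- TRUE
    fit <- apply(pop, 1, evalChrom)
    trace <- min(fit)
    for (gen in seq_len(cfg$max_generations)) {
      if (max(fit) - min(fit) < cfg$convergence_tol) break
      ord <- order(fit)
      surv <- pop[ord[seq_len(half)], , drop = FALSE]
      kids <- matrix(FALSE, 0L, ng)
      while (nrow(kids) < half) {
        pr <- sample.int(half, 2L, replace = half < 2L)
        kids <- rbind(kids, .doubleCrossover(surv[pr[1], ], surv[pr[2], ]))
      }
      kids <- kids[seq_len(half), , drop = FALSE]
      flips <- matrix(stats::runif(half * ng) < cfg$mutation_rate,
                      half, ng)
      kids <- xor(kids, flips)
      pop <- rbind(surv, kids)
      fit <- apply(pop, 1, evalChrom)
      trace <- c(trace, min(fit))
    }
    bi <- which.min(fit)
    runBest[r, ] <- pop[bi, ]
    runFitness[r] <- fit[bi]
    traces[[r]] <- trace
  }
  wfreq <- colMeans(runBest)
  vfreq <- numeric(ncol(X))
  for (w in seq_len(ng)) vfreq[windows[[w]]] <- wfreq[w]
  new("GAResult", windows = windows, runBest = runBest,
      runFitness = runFitness, windowFrequency = wfreq,
      variableFrequency = vfreq,
      mask = vfreq >= cfg$frequency_threshold,
      frequencyThreshold = cfg$frequency_threshold, traces = traces,
      wavenumbers = wavenumbers(x))
}

#' Selected wavenumber intervals
#'
#' Merges adjacent selected variables of the final GA mask into contiguous
#' intervals with center wavenumbers, for comparison against known band
#' positions.
#'
#' @param result a [GAResult-class] (or any object with `mask` +
#'   `wavenumbers` slots)
#' @return data.frame with columns `start_cm1`, `end_cm1`, `center_cm1`,
#'   `n_points` (zero rows for an empty mask).
#' @export
selectedBands <- function(result) {
  mask <- result@mask
  wn <- result@wavenumbers
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values
  data.frame(start_cm1 = wn[starts[sel]], end_cm1 = wn[ends[sel]],
             center_cm1 = (wn[starts[sel]] + wn[ends[sel]]) / 2,
             n_points = r$lengths[sel], row.names = NULL)
}
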