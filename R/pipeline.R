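#' Full-pipeline configuration
#'
#' Nests the per-stage configurations and derives every stage seed from one
#' global seed, so a pipeline run is reproducible end to end. The defaults
#' describe a complete synthetic study: simulate calibration and external
#' cohorts, preprocess, remove outlier donors by Hotelling T-squared, select
#' wavelengths by GA, train the SVM-DA classifier, cross-validate, vote
#' donors and externally validate.
#'
#' @param generator [generatorConfig()] for the calibration cohort (its
#'   `seed`/`donor_prefix` are overridden by the derived stage seeds).
#' @param n_external_per_class donors per class in the external cohort
#'   (generated with the same band structure, no injected outliers).
#' @param preprocess a [preprocessConfig()].
#' @param nlv latent variables of the outlier-screening PLS-DA model.
#' @param alpha significance level of the T-squared control limit.
#' @param ga a [gaConfig()]; `skip_ga = TRUE` replaces the GA mask by all
#'   variables (ablation path).
#' @param classifier a [classifierConfig()].
#' @param cv a [cvScheme()].
#' @param vote_threshold donor-vote threshold.
#' @param skip_ga skip wavelength selection.
#' @param seed global seed; all stage seeds derive from it.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(generator = generatorConfig(
                             outlier_donor_fraction = 0.06),
                           n_external_per_class = 3,
                           preprocess = preprocessConfig(),
                           nlv = 11, alpha = 0.01,
                           ga = gaConfig(n_runs = 10, max_generations = 30),
                           classifier = classifierConfig(),
                           cv = cvScheme(),
                           vote_threshold = 0.5,
                           skip_ga = FALSE,
                           seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipelineConfig"
  cfg
}

.stageSeed <- function(seed, k) (as.integer(seed) * 97L + k) %% 2147483629L

#' Run the complete workflow
#'
#' Executes the stages in order — simulate, preprocess, T-squared outlier
#' removal, GA wavelength selection, SVM-DA training, custom
#' cross-validation, donor voting, external validation — and collates a
#' summary. When `out_dir` is given, artifacts are written there:
#' `spectra/` and `external/` datasets, `qc_rejections.csv`, `t2_report.csv`,
#' `selection_frequency.csv`, `selected_bands.csv`, `confusion.csv`,
#' `metrics.csv`, `votes.csv`, `external_votes.csv` and `summary.json`.
#'
#' @param cfg a [pipelineConfig()]
#' @param out_dir optional run directory.
#' @return (invisibly) a list with the summary and every stage result.
#' @export
runPipeline <- function(cfg = pipelineConfig(), out_dir = NULL) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  gen <- cfg$generator
  gen$seed <- .stageSeed(cfg$seed, 1L)
  sim <- simulateSpectra(gen)

  ext <- NULL
  if (cfg$n_external_per_class > 0) {
    egen <- cfg$generator
    egen$n_donors[] <- cfg$n_external_per_class
    egen$outlier_donor_fraction <- 0
    egen$donor_prefix <- "EXT-"
    egen$seed <- .stageSeed(cfg$seed, 2L)
    ext <- simulateSpectra(egen)
  }

  cal <- preprocess(sim$dataset, cfg$preprocess)
  ext_pp <- if (!is.null(ext)) preprocess(ext$dataset, cfg$preprocess)

  plsda <- fitPLSDA(cal, cfg$nlv)
  t2 <- hotellingT2(plsda, cal, cfg$alpha)
  cal <- removeOutliers(cal, t2)

  if (cfg$skip_ga) {
    ga <- NULL
    mask <- rep(TRUE, nrow(cal))
  } else {
    gacfg <- cfg$ga
    gacfg$seed <- .stageSeed(cfg$seed, 3L)
    ga <- runGA(cal, gacfg)
    mask <- ga@mask
    if (!any(mask)) {
      warning("GA selected no variables; falling back to the full axis")
      mask <- rep(TRUE, nrow(cal))
    }
  }

  clf <- trainClassifier(cal, mask, cfg$classifier)
  clf_cfg <- cfg$classifier
  clf_cfg$svm_cost <- clf@cost
  clf_cfg$rbf_gamma <- clf@gamma

  cvs <- cfg$cv
  cvs$seed <- .stageSeed(cfg$seed, 4L)
  cvr <- crossValidate(cal, mask, clf_cfg, cvs)
  metrics <- confusionMetrics(cvr$confusion)
  vote <- voteDonors(cvr$predictions, cfg$vote_threshold)

  extres <- if (!is.null(ext_pp) && ncol(ext_pp))
    externalValidate(clf, ext_pp, cfg$vote_threshold)

  summary <- list(
    seed = cfg$seed,
    calibration = summarizeSpectra(cal),
    removed_donors = t2@removed,
    t2_threshold = t2@threshold,
    n_selected_variables = sum(mask),
    selected_bands = if (!is.null(ga)) selectedBands(ga),
    spectral_accuracy = sum(diag(cvr$confusion)) / sum(cvr$confusion),
    metrics = metrics,
    donor_accuracy = vote$accuracy,
    external_donor_accuracy = if (!is.null(extres)) extres$donor_accuracy,
    external_spectral_accuracy = if (!is.null(extres))
      extres$spectral_accuracy)

  result <- list(summary = summary, calibration = cal, truth = sim$truth,
                 t2 = t2, ga = ga, mask = mask, classifier = clf,
                 cv = cvr, vote = vote, external = extres)
  if (!is.null(out_dir)) .writeRunDir(result, out_dir)
  invisible(result)
}

.writeRunDir <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeSpectra(result$calibration, file.path(out_dir, "spectra"))
  utils::write.csv(rejectionLog(result$calibration),
                   file.path(out_dir, "qc_rejections.csv"),
                   row.names = FALSE)
  t2 <- result$t2
  utils::write.csv(data.frame(donor_id = names(t2@donorT2),
                              donor_t2 = unname(t2@donorT2),
                              removed = names(t2@donorT2) %in% t2@removed),
                   file.path(out_dir, "t2_report.csv"), row.names = FALSE)
  if (!is.null(result$ga)) {
    utils::write.csv(data.frame(
      wavenumber = result$ga@wavenumbers,
      frequency = result$ga@variableFrequency,
      selected = result$ga@mask),
      file.path(out_dir, "selection_frequency.csv"), row.names = FALSE)
    utils::write.csv(selectedBands(result$ga),
                     file.path(out_dir, "selected_bands.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(as.data.frame(result$cv$confusion),
                   file.path(out_dir, "confusion.csv"))
  utils::write.csv(result$summary$metrics,
                   file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(result$vote$votes, file.path(out_dir, "votes.csv"),
                   row.names = FALSE)
  if (!is.null(result$external))
    utils::write.csv(result$external$votes,
                     file.path(out_dir, "external_votes.csv"),
                     row.names = FALSE)
  s <- result$summary
  s$selected_bands <- NULL
  jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
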