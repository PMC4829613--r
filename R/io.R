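## Plain-text I/O for trial containers, feature tables and the pipeline
## driver. All numeric columns are written with 17 significant digits so a
## write/read round trip reproduces every double bit-identically.

.fmt <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

.writeTable <- function(df, path) {
  out <- as.data.frame(lapply(df, .fmt), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write an epoched trial container to a directory
#'
#' The container is a directory of delimited text files: \code{trials.tsv}
#' (per-trial metadata), \code{pre.tsv} and \code{post.tsv} (segment
#' matrices, one column per trial), \code{profiles.tsv} (ground-truth
#' simulation profiles, when present) and \code{container.dcf} (sampling
#' rate and dimensions). Values carry full double precision, so
#' [readTrialContainer()] reproduces the object bit-identically.
#'
#' @param trials an [EpochedTrialSet-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeTrialContainer <- function(trials, dir) {
  stopifnot(is(trials, "EpochedTrialSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeTable(trialData(trials), file.path(dir, "trials.tsv"))
  for (seg in c("pre", "post")) {
    m <- assay(trials, seg)
    utils::write.table(
      matrix(sprintf("%.17g", m), nrow = nrow(m)),
      file.path(dir, paste0(seg, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(profiles(trials)))
    .writeTable(profiles(trials), file.path(dir, "profiles.tsv"))
  write.dcf(data.frame(sampling_rate = sprintf("%.17g", samplingRate(trials)),
                       n_samples = nrow(trials), n_trials = ncol(trials)),
            file.path(dir, "container.dcf"))
  invisible(dir)
}

#' Read an epoched trial container
#'
#' @param dir directory written by [writeTrialContainer()] or conforming to
#'   its schema.
#' @return An [EpochedTrialSet-class].
#' @export
readTrialContainer <- function(dir) {
  meta_path <- file.path(dir, "trials.tsv")
  if (!file.exists(meta_path))
    stop(sprintf("no trial container at '%s' (trials.tsv missing)", dir))
  info <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (nrow(info) == 0L)
    stop("empty trial container: no trials in trials.tsv")
  need <- c("individual_id", "trial_index", "energy_J", "rating")
  miss <- setdiff(need, colnames(info))
  if (length(miss))
    stop(sprintf("trial container schema mismatch: column(s) %s missing from trials.tsv",
                 paste(sQuote(miss), collapse = ", ")))
  info$energy_J <- as.numeric(info$energy_J)
  dcf <- read.dcf(file.path(dir, "container.dcf"))
  pre <- as.matrix(utils::read.table(file.path(dir, "pre.tsv"), sep = "\t"))
  post <- as.matrix(utils::read.table(file.path(dir, "post.tsv"), sep = "\t"))
  dimnames(pre) <- dimnames(post) <- NULL
  prof_path <- file.path(dir, "profiles.tsv")
  prof <- if (file.exists(prof_path))
    utils::read.table(prof_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  if (!is.null(prof)) {
    num <- setdiff(names(prof), "individual_id")
    prof[num] <- lapply(prof[num], as.numeric)
  }
  EpochedTrialSet(pre, post, info,
                  sampling_rate = as.numeric(dcf[1, "sampling_rate"]),
                  profiles = prof)
}

#' Write or read a feature table
#'
#' Delimited text with a header row and full double precision; the feature
#' table is the interchange format between the signal-level and the
#' statistical stages.
#'
#' @param records a feature table data.frame.
#' @param path file path.
#' @return \code{writeFeatureTable}: \code{path}, invisibly;
#'   \code{readFeatureTable}: the table.
#' @export
writeFeatureTable <- function(records, path) {
  .writeTable(records, path)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("individual_id", "trial_index", "rating", "rms_s", "rms_p")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(sprintf("feature table schema mismatch: column(s) %s missing",
                 paste(sQuote(miss), collapse = ", ")))
  df
}

.stage <- function(name, verbose, expr) {
  if (verbose) message(sprintf("[%s] ...", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

# sub-analyses that legitimately starve on tiny cohorts (too few
# individuals for a paired test or variance ratio) degrade to NULL with a
# notice instead of aborting the whole run
.stageOpt <- function(name, verbose, expr) {
  if (verbose) message(sprintf("[%s] ...", name))
  tryCatch(expr, error = function(e) {
    message(sprintf("[%s] skipped (degenerate): %s", name,
                    conditionMessage(e)))
    NULL
  })
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) an epoched trial cohort, extracts RMS features,
#' normalizes them against each individual's spontaneous distribution, and
#' runs the three statistical stages: cross-individual magnitude
#' correlations and rating-response model comparison, inter-individual
#' variability (per-level ANOVA F and parameter variances), and the
#' two-stage leave-one-individual-out predictor under both raw and
#' normalized features. All result tables are returned and, when
#' \code{out_dir} is given, also written as delimited text together with a
#' manifest recording the configuration and seed.
#'
#' @param config a [CohortConfig-class] (used when \code{trials} is NULL).
#' @param trials optional [EpochedTrialSet-class]; skips simulation.
#' @param records optional precomputed feature table; skips simulation and
#'   feature extraction.
#' @param mode normalization mode (see [normalizeFeatures()]).
#' @param priors LDA priors (see [trainLda1d()]).
#' @param out_dir optional output directory for result tables.
#' @param verbose log one line per stage.
#' @return list with elements \code{features}, \code{correlations},
#'   \code{model_fits}, \code{model_comparison}, \code{anova_f},
#'   \code{variability}, \code{prediction_raw}, \code{prediction_norm},
#'   \code{prediction_summary}.
#' @export
runPipeline <- function(config = cohortConfig(), trials = NULL, records = NULL,
                        mode = "zscore", priors = "empirical",
                        out_dir = NULL, verbose = TRUE) {
  if (is.null(records)) {
    if (is.null(trials))
      trials <- .stage("simulate", verbose, simulateCohort(config))
    records <- .stage("features", verbose, buildFeatureTable(trials))
  }
  records <- .stage("normalize", verbose, normalizeFeatures(records, mode))

  correlations <- .stage("analyze", verbose,
                         correlateLevelSummaries(levelSummaries(records)))
  fits <- .stage("analyze", verbose, fitIndividualModels(records, "rms_p"))
  model_comparison <- .stageOpt("analyze", verbose, compareFitModels(fits))

  anova_f <- .stage("variability", verbose, rbind(
    cbind(feature = "rms_p", anovaFByLevel(records, "rms_p")),
    cbind(feature = "nrms_p", anovaFByLevel(records, "nrms_p"))))
  variability <- .stageOpt("variability", verbose,
                           parameterVariability(records))

  pred_raw <- .stage("predict", verbose, runTwoStage(records, "rms_p", priors))
  pred_norm <- .stage("predict", verbose, runTwoStage(records, "nrms_p", priors))
  pred_summary <- .stage("predict", verbose,
                         evaluateAndCompare(pred_raw, pred_norm))

  bundle <- list(features = records, correlations = correlations,
                 model_fits = fits,
                 model_comparison = model_comparison,
                 anova_f = anova_f,
                 variability = variability,
                 prediction_raw = pred_raw, prediction_norm = pred_norm,
                 prediction_summary = pred_summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeFeatureTable(records, file.path(out_dir, "features.tsv"))
    .writeTable(correlations, file.path(out_dir, "correlations.tsv"))
    .writeTable(fits, file.path(out_dir, "model_fits.tsv"))
    if (!is.null(model_comparison))
      .writeTable(as.data.frame(model_comparison),
                  file.path(out_dir, "model_comparison.tsv"))
    .writeTable(anova_f, file.path(out_dir, "anova_f.tsv"))
    if (!is.null(variability))
      .writeTable(variability$comparison,
                  file.path(out_dir, "variance_comparison.tsv"))
    .writeTable(pred_raw, file.path(out_dir, "prediction_raw.tsv"))
    .writeTable(pred_norm, file.path(out_dir, "prediction_norm.tsv"))
    .writeTable(pred_summary, file.path(out_dir, "prediction_summary.tsv"))
    write.dcf(data.frame(package_version = as.character(utils::packageVersion("lepnorm")),
                         seed = config@seed,
                         n_individuals = config@n_individuals,
                         sampling_rate = config@sampling_rate,
                         normalization_mode = mode,
                         lda_priors = priors),
              file.path(out_dir, "manifest.dcf"))
    if (verbose) message(sprintf("results written to %s", out_dir))
  }
  invisible(bundle)
}
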