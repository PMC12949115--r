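#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.CONDITIONS <- c("CS_TS", "TS_only", "CS_only")
.CHANNELS <- c("lFCR", "rFCR")

#' TrialSet: epoched bilateral EMG recordings
#'
#' A `TrialSet` holds a block of stimulation trials as a
#' [SummarizedExperiment::SummarizedExperiment]: two assays (`lFCR`, `rFCR`)
#' are samples-by-trials matrices of EMG values in microvolts, and the column
#' metadata carries, per trial, the participant and trial identifiers, the
#' condition label (`CS_TS`, `TS_only` or `CS_only`) and the stimulus times.
#'
#' All times are expressed in milliseconds relative to the test stimulus (TS);
#' sample 0 (the first matrix row) sits at `epochStart(x)` ms (default -500),
#' and consecutive rows are spaced by `1000 / samplingRate(x)` ms. Sample
#' indices in the interchange file format are 0-based.
#'
#' Validity requires: both channel matrices present with identical dimensions
#' and finite values; known condition labels; a positive sampling rate; and,
#' for every `CS_TS` trial, an inter-stimulus interval of exactly 10 ms
#' (conditioning stimulus 10 ms before the test stimulus).
#'
#' @seealso [TrialSet()] for construction, [readTrials()] / [writeTrials()]
#'   for the delimited interchange format, [extractFeatures()] for data
#'   reduction.
#' @name TrialSet-class
#' @aliases TrialSet-class
#' @exportClass TrialSet
setClass("TrialSet", contains = "SummarizedExperiment")

setValidity("TrialSet", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(.CHANNELS %in% an))
    return(sprintf("assays must include both channels: %s",
                   paste(.CHANNELS, collapse = ", ")))
  l <- SummarizedExperiment::assay(object, "lFCR")
  r <- SummarizedExperiment::assay(object, "rFCR")
  if (!identical(dim(l), dim(r)))
    msg <- c(msg, "channel matrices 'lFCR' and 'rFCR' must have identical dimensions")
  if (!all(is.finite(l)) || !all(is.finite(r)))
    msg <- c(msg, "all trace samples must be finite")
  cd <- SummarizedExperiment::colData(object)
  need <- c("participant", "trial", "condition", "t_CS_ms", "t_TS_ms")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(sprintf("colData is missing column(s): %s", paste(miss, collapse = ", ")))
  bad <- !(cd$condition %in% .CONDITIONS)
  if (any(bad))
    msg <- c(msg, sprintf("unknown condition label(s): %s",
                          paste(unique(cd$condition[bad]), collapse = ", ")))
  fs <- S4Vectors::metadata(object)$fs
  if (is.null(fs) || !is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    msg <- c(msg, "metadata()$fs must be a single positive number (Hz)")
  if (is.null(S4Vectors::metadata(object)$epoch_start_ms))
    msg <- c(msg, "metadata()$epoch_start_ms must be set")
  is_cst <- cd$condition == "CS_TS"
  if (any(is_cst)) {
    isi <- cd$t_TS_ms[is_cst] - cd$t_CS_ms[is_cst]
    off <- which(is.na(isi) | isi != 10)
    if (length(off))
      msg <- c(msg, sprintf(
        "CS_TS trial(s) with inter-stimulus interval != 10 ms: %s",
        paste(utils::head(cd$trial[is_cst][off], 5L), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Analysis configuration
#'
#' Bundle of tunable analysis parameters: pre-stimulus background-EMG window
#' durations (ms), the gap between the end of each background window and the
#' conditioning stimulus (ms), the MEP measurement window (ms after the
#' stimulus addressed to the muscle), the number of bootstrap resamples for
#' sample-level confidence intervals, a random seed, and the set of
#' covariate-adjustment methods to run (`"parametric"`, `"psr"`).
#'
#' Defaults reproduce the standard reduction: background windows of 100, 50
#' and 10 ms each ending 3 ms before the conditioning stimulus, and an MEP
#' window of 12.5-45 ms post-stimulus.
#'
#' @seealso [analysisConfig()], [loadConfig()], [saveConfig()]
#' @name AnalysisConfig-class
#' @aliases AnalysisConfig-class
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
  representation(
    backgroundWindows = "numeric",
    windowGap = "numeric",
    mepWindow = "numeric",
    bootstrapReps = "integer",
    seed = "integer",
    methods = "character"
  ),
  prototype(
    backgroundWindows = c(100, 50, 10),
    windowGap = 3,
    mepWindow = c(12.5, 45),
    bootstrapReps = 10000L,
    seed = 1L,
    methods = c("parametric", "psr")
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (!length(object@backgroundWindows) || any(object@backgroundWindows <= 0))
    msg <- c(msg, "background windows must be positive durations (ms)")
  if (length(object@windowGap) != 1L || object@windowGap < 0)
    msg <- c(msg, "window gap must be a single non-negative duration (ms)")
  if (length(object@mepWindow) != 2L || object@mepWindow[1] >= object@mepWindow[2])
    msg <- c(msg, "MEP window must be (start, end) with start < end")
  if (length(object@bootstrapReps) != 1L || is.na(object@bootstrapReps) ||
      object@bootstrapReps < 1L)
    msg <- c(msg, "bootstrap_reps must be >= 1")
  if (!all(object@methods %in% c("parametric", "psr")))
    msg <- c(msg, "adjustment methods must be a subset of {parametric, psr}")
  if (length(msg)) msg else TRUE
})

#' Synthetic-data generator configuration
#'
#' Parameters of the generative model for trial-level bilateral EMG data.
#' Per trial, a shared standard-Gaussian cortical excitability factor `c_t`
#' and a bivariate-Gaussian pair of log-background levels `(b_L, b_R)` with
#' correlation `rhoBg` and standard deviation `bgLogSd` drive log-normal MEP
#' amplitudes on each side:
#' `log amp = log M + sharedLoading * c_t + bgCoupling * b + noise`,
#' with per-participant log-scale heterogeneity and an overall scale `M`
#' calibrated so that the grand mean test-stimulus-alone amplitude equals
#' `ampMeanTs` (microvolts) and conditioned trials are suppressed by the
#' factor `suppression`. The per-trial background r.m.s. target is
#' `bgRmsMedian * exp(b)`.
#'
#' Slot defaults are the study conditions emulated by the package: 205
#' participants; 18 conditioned, 17 test-alone and 10 conditioning-alone
#' trials; 102 uV mean test-alone amplitude suppressed to 62/102 of that when
#' conditioned; 0.72 uV median background r.m.s.; and latent settings
#' (`sharedLoading` 0.32, `bgCoupling` 1.2, `rhoBg` 0.3, `bgLogSd` 0.35,
#' `noiseSd` 0.75) that induce a participant-level amplitude rank correlation
#' of about 0.17 with a small reduction under covariate adjustment.
#'
#' @seealso [syntheticConfig()], [generateDataset()], [simulateFeatures()]
#' @name SyntheticConfig-class
#' @aliases SyntheticConfig-class
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    nParticipants = "integer",
    trialsCsTs = "integer",
    trialsTsOnly = "integer",
    trialsCsOnly = "integer",
    rhoBg = "numeric",
    sharedLoading = "numeric",
    bgCoupling = "numeric",
    ampMeanTs = "numeric",
    suppression = "numeric",
    bgRmsMedian = "numeric",
    bgLogSd = "numeric",
    noiseSd = "numeric",
    participantSd = "numeric",
    fs = "numeric",
    seed = "integer"
  ),
  prototype(
    nParticipants = 205L,
    trialsCsTs = 18L,
    trialsTsOnly = 17L,
    trialsCsOnly = 10L,
    rhoBg = 0.3,
    sharedLoading = 0.32,
    bgCoupling = 1.2,
    ampMeanTs = 102,
    suppression = 62 / 102,
    bgRmsMedian = 0.72,
    bgLogSd = 0.35,
    noiseSd = 0.75,
    participantSd = 0.5,
    fs = 5000,
    seed = 1L
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  cnt <- c(object@nParticipants, object@trialsCsTs, object@trialsTsOnly,
           object@trialsCsOnly)
  if (any(is.na(cnt)) || any(cnt < 1L))
    msg <- c(msg, "participant and trial counts must be >= 1")
  if (abs(object@rhoBg) > 1)
    msg <- c(msg, "rhoBg must lie in [-1, 1]")
  pos <- c(ampMeanTs = object@ampMeanTs, suppression = object@suppression,
           bgRmsMedian = object@bgRmsMedian, fs = object@fs)
  if (any(pos <= 0))
    msg <- c(msg, "ampMeanTs, suppression, bgRmsMedian and fs must be > 0")
  nn <- c(object@bgLogSd, object@noiseSd, object@participantSd)
  if (any(nn < 0))
    msg <- c(msg, "standard deviations must be >= 0")
  if (length(msg)) msg else TRUE
})
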