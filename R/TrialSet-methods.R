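#' Construct a TrialSet
#'
#' Assemble epoched bilateral EMG trials into a [TrialSet]. Channel matrices
#' are samples-by-trials; columns of the two matrices correspond trial-for-
#' trial. Stimulus times default to the canonical protocol timing: the test
#' stimulus (TS) at 0 ms and the conditioning stimulus (CS) at -10 ms, with
#' the time absent (`NA`) when the corresponding stimulus is not delivered
#' (`t_TS_ms` on `CS_only` trials, `t_CS_ms` on `TS_only` trials).
#'
#' @param lFCR,rFCR numeric matrices (samples x trials) of EMG in microvolts
#'   for the left and right flexor carpi radialis channels.
#' @param participant,trial identifiers, one per trial (recycled if length 1).
#' @param condition character vector of condition labels, each one of
#'   `"CS_TS"`, `"TS_only"`, `"CS_only"`.
#' @param fs sampling rate in Hz (default 5000).
#' @param epochStartMs time of the first sample relative to the TS, in ms
#'   (default -500, i.e. the epoch spans 0.5 s before to 0.5 s after the TS
#'   at the default 5000-sample length).
#' @param tCSMs,tTSMs optional stimulus times (ms relative to TS); defaults
#'   follow the condition labels as described above.
#' @return a validated [TrialSet].
#' @examples
#' ts <- TrialSet(lFCR = matrix(0, 5000, 2), rFCR = matrix(0, 5000, 2),
#'                participant = "P01", trial = c("t1", "t2"),
#'                condition = c("CS_TS", "TS_only"))
#' ts
#' @export
TrialSet <- function(lFCR, rFCR, participant, trial, condition,
                     fs = 5000, epochStartMs = -500,
                     tCSMs = NULL, tTSMs = NULL) {
  lFCR <- as.matrix(lFCR)
  rFCR <- as.matrix(rFCR)
  n <- ncol(lFCR)
  condition <- as.character(condition)
  participant <- rep_len(as.character(participant), n)
  trial <- rep_len(as.character(trial), n)
  if (is.null(tCSMs))
    tCSMs <- ifelse(condition %in% c("CS_TS", "CS_only"), -10, NA_real_)
  if (is.null(tTSMs))
    tTSMs <- ifelse(condition == "CS_only", NA_real_, 0)
  cd <- S4Vectors::DataFrame(
    participant = participant, trial = trial, condition = condition,
    t_CS_ms = rep_len(as.numeric(tCSMs), n), t_TS_ms = rep_len(as.numeric(tTSMs), n)
  )
  rownames(cd) <- make.unique(paste(participant, trial, sep = "."))
  colnames(lFCR) <- colnames(rFCR) <- rownames(cd)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(lFCR = lFCR, rFCR = rFCR),
    colData = cd,
    metadata = list(fs = fs, epoch_start_ms = epochStartMs)
  )
  new("TrialSet", se)
}

#' @rdname mepcov-generics
#' @export
setMethod("samplingRate", "TrialSet", function(x, ...)
  S4Vectors::metadata(x)$fs)

#' @rdname mepcov-generics
#' @export
setMethod("epochStart", "TrialSet", function(x, ...)
  S4Vectors::metadata(x)$epoch_start_ms)

#' @rdname mepcov-generics
#' @export
setMethod("trialConditions", "TrialSet", function(x, ...)
  SummarizedExperiment::colData(x)$condition)

#' @rdname mepcov-generics
#' @export
setMethod("participants", "TrialSet", function(x, ...)
  unique(SummarizedExperiment::colData(x)$participant))

#' @rdname mepcov-generics
#' @param channel `"lFCR"` or `"rFCR"`
#' @export
setMethod("channelTraces", "TrialSet", function(x, channel = c("lFCR", "rFCR"), ...) {
  channel <- match.arg(channel)
  SummarizedExperiment::assay(x, channel)
})

setMethod("show", "TrialSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("TrialSet: %d trials x %d samples (%g Hz, epoch from %g ms)\n",
              ncol(object), nrow(object), samplingRate(object), epochStart(object)))
  cat(sprintf("  participants: %d | conditions: %s\n",
              length(unique(cd$participant)),
              paste(sprintf("%s=%d", names(table(cd$condition)),
                            as.integer(table(cd$condition))), collapse = ", ")))
})
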