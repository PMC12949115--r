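#' @importFrom stats sd cor quantile rnorm dnorm qlogis plogis dlogis pbeta
#' @importFrom stats optimize lm.fit
NULL

.datatable.aware <- TRUE

#' Convert a millisecond window to a sample-index range
#'
#' Window boundaries given in milliseconds relative to the epoch start are
#' mapped to the half-open 0-based sample range
#' `[round(start * fs / 1000), round(end * fs / 1000))`, where `round()` is
#' R's round-half-to-even. At 5000 Hz, 12.5 ms maps to sample 62. The
#' returned value is the equivalent 1-based R index vector.
#'
#' @param startMs,endMs window boundaries in ms relative to the epoch start;
#'   `startMs < endMs` required.
#' @param fs sampling rate in Hz.
#' @param nSamples optional trace length; when given, the window must lie
#'   inside `[0, nSamples)` or a bounds error is raised.
#' @return integer vector of 1-based sample indices (non-empty).
#' @examples
#' windowToIndices(0, 1, 5000)    # samples 0..4, returned as 1..5
#' @export
windowToIndices <- function(startMs, endMs, fs, nSamples = NULL) {
  if (!is.finite(startMs) || !is.finite(endMs) || startMs >= endMs)
    stop("bounds error: window start must precede window end (got ",
         startMs, ", ", endMs, " ms)")
  i0 <- round(startMs * fs / 1000)
  i1 <- round(endMs * fs / 1000)
  if (i1 <= i0)
    stop("bounds error: window (", startMs, ", ", endMs,
         ") ms contains no samples at ", fs, " Hz")
  if (!is.null(nSamples) && (i0 < 0 || i1 > nSamples))
    stop("bounds error: window (", startMs, ", ", endMs,
         ") ms extends outside the epoch (0..", nSamples - 1L, " samples)")
  seq.int(i0 + 1L, i1)
}

#' MEP peak-to-peak amplitude
#'
#' Absolute difference between the maximum and minimum EMG values in a window
#' (default 12.5-45 ms) following the stimulus addressed to the muscle.
#'
#' @param trace numeric vector of EMG samples (microvolts).
#' @param stimMs stimulus time in ms relative to the test stimulus.
#' @param fs sampling rate in Hz.
#' @param window measurement window in ms after the stimulus.
#' @param epochStartMs time of the first sample relative to the test
#'   stimulus, in ms.
#' @return peak-to-peak amplitude in microvolts (>= 0).
#' @export
peakToPeak <- function(trace, stimMs, fs, window = c(12.5, 45),
                       epochStartMs = -500) {
  idx <- windowToIndices(stimMs - epochStartMs + window[1],
                         stimMs - epochStartMs + window[2],
                         fs, nSamples = length(trace))
  seg <- trace[idx]
  max(seg) - min(seg)
}

#' MEP area
#'
#' Integral of the rectified (absolute-value) EMG trace over the measurement
#' window, computed as the mean rectified value times the nominal window
#' duration in ms. No baseline is subtracted (pre-stimulus levels are
#' sub-microvolt, so the induced bias is negligible).
#'
#' @inheritParams peakToPeak
#' @return MEP area in microvolt-milliseconds (>= 0).
#' @export
mepArea <- function(trace, stimMs, fs, window = c(12.5, 45),
                    epochStartMs = -500) {
  idx <- windowToIndices(stimMs - epochStartMs + window[1],
                         stimMs - epochStartMs + window[2],
                         fs, nSamples = length(trace))
  mean(abs(trace[idx])) * (window[2] - window[1])
}

#' Root-mean-square background EMG
#'
#' r.m.s. of the EMG over the pre-stimulus window
#' `[csMs - gapMs - durationMs, csMs - gapMs)`, i.e. a window of the given
#' duration ending `gapMs` ms (default 3) before the conditioning stimulus.
#'
#' @inheritParams peakToPeak
#' @param csMs conditioning-stimulus time in ms relative to the test
#'   stimulus (use the position the conditioning stimulus would occupy, -10,
#'   on test-alone trials).
#' @param durationMs window duration in ms (typically 100, 50 or 10).
#' @param gapMs gap before the conditioning stimulus in ms.
#' @return r.m.s. amplitude in microvolts (>= 0).
#' @export
rmsBackground <- function(trace, csMs, durationMs, fs, gapMs = 3,
                          epochStartMs = -500) {
  idx <- windowToIndices(csMs - gapMs - durationMs - epochStartMs,
                         csMs - gapMs - epochStartMs,
                         fs, nSamples = length(trace))
  sqrt(mean(trace[idx]^2))
}

#' Reduce trials to scalar features
#'
#' For every trial, computes the MEP peak-to-peak amplitude and MEP area per
#' muscle and the pre-stimulus background r.m.s. per muscle per window.
#'
#' Measurement geometry: the right-FCR MEP is measured in the window (default
#' 12.5-45 ms) after the test stimulus; the left-FCR MEP in the same window
#' after the conditioning stimulus (equivalently 2.5-35 ms after the test
#' stimulus on conditioned trials). MEP fields are `NA` for a muscle when no
#' stimulus addresses it (left FCR on `TS_only` trials, right FCR on
#' `CS_only` trials). Background windows for both channels end `windowGap` ms
#' before the conditioning stimulus; on `TS_only` trials they end at the same
#' absolute position, 13 ms before the test stimulus.
#'
#' @param trials a [TrialSet].
#' @param cfg an [AnalysisConfig-class]; defaults via [analysisConfig()].
#' @return a `data.frame` with one row per trial: `participant`, `trial`,
#'   `condition`, `mep_amp_rFCR`, `mep_amp_lFCR`, `mep_area_rFCR`,
#'   `mep_area_lFCR`, and `rms_<channel>_<window>` columns, one per
#'   background window.
#' @export
setMethod("extractFeatures", "TrialSet", function(trials, cfg = analysisConfig()) {
  methods::validObject(trials)
  methods::validObject(cfg)
  fs <- samplingRate(trials)
  e0 <- epochStart(trials)
  cd <- SummarizedExperiment::colData(trials)
  lmat <- SummarizedExperiment::assay(trials, "lFCR")
  rmat <- SummarizedExperiment::assay(trials, "rFCR")
  n <- ncol(trials)
  wins <- cfg@backgroundWindows
  out <- data.frame(
    participant = cd$participant, trial = cd$trial, condition = cd$condition,
    mep_amp_rFCR = NA_real_, mep_amp_lFCR = NA_real_,
    mep_area_rFCR = NA_real_, mep_area_lFCR = NA_real_,
    stringsAsFactors = FALSE
  )
  for (ch in .CHANNELS) for (w in wins)
    out[[sprintf("rms_%s_%g", ch, w)]] <- NA_real_
  for (j in seq_len(n)) {
    cond <- cd$condition[j]
    tCS <- cd$t_CS_ms[j]
    tTS <- cd$t_TS_ms[j]
    # anchor for background windows: the CS position, or -10 ms relative to
    # the TS when no CS is delivered (same absolute position in the epoch)
    csRef <- if (!is.na(tCS)) tCS else tTS - 10
    if (cond != "CS_only") {
      out$mep_amp_rFCR[j] <- peakToPeak(rmat[, j], tTS, fs, cfg@mepWindow, e0)
      out$mep_area_rFCR[j] <- mepArea(rmat[, j], tTS, fs, cfg@mepWindow, e0)
    }
    if (cond != "TS_only") {
      out$mep_amp_lFCR[j] <- peakToPeak(lmat[, j], tCS, fs, cfg@mepWindow, e0)
      out$mep_area_lFCR[j] <- mepArea(lmat[, j], tCS, fs, cfg@mepWindow, e0)
    }
    for (w in wins) {
      out[[sprintf("rms_lFCR_%g", w)]][j] <-
        rmsBackground(lmat[, j], csRef, w, fs, cfg@windowGap, e0)
      out[[sprintf("rms_rFCR_%g", w)]][j] <-
        rmsBackground(rmat[, j], csRef, w, fs, cfg@windowGap, e0)
    }
  }
  out
})

#' Write / read a feature table
#'
#' One row per trial, tab-separated, column names exactly as produced by
#' [extractFeatures()]; values at full precision.
#'
#' @param features a feature `data.frame`.
#' @param path destination file.
#' @export
writeFeatures <- function(features, path) {
  data.table::fwrite(data.table::as.data.table(features), path, sep = "\t")
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  as.data.frame(data.table::fread(
    path, sep = "\t",
    colClasses = list(character = c("participant", "trial"))))
}
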