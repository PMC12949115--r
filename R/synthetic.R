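# Synthetic trial-level bilateral EMG generator with ground-truth bookkeeping.

#' Create a synthetic-data configuration
#'
#' See [SyntheticConfig-class] for the generative model and the meaning and
#' default of every parameter.
#'
#' @param ... named overrides of any slot, e.g. `nParticipants`, `seed`,
#'   `sharedLoading`, `bgCoupling`, `rhoBg`.
#' @return a validated [SyntheticConfig-class] object.
#' @export
syntheticConfig <- function(...) {
  args <- list(...)
  intSlots <- c("nParticipants", "trialsCsTs", "trialsTsOnly", "trialsCsOnly",
                "seed")
  for (s in intersect(names(args), intSlots)) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("SyntheticConfig"), args))
}

#' Sample per-trial latent variables
#'
#' Draws, for each trial, a standard-Gaussian shared cortical excitability
#' factor `c` and a bivariate-Gaussian pair of log-background deviations
#' `(bL, bR)` with correlation `rhoBg` and standard deviation `bgLogSd`
#' (Gaussian copula for the log-normal background scale). Uses the current
#' RNG stream unless `seed` is given.
#'
#' @param nTrials number of trials.
#' @param rhoBg latent left/right log-background correlation, in `[-1, 1]`.
#' @param bgLogSd standard deviation of the log-background deviations.
#' @param seed optional integer seed.
#' @return `data.frame` with columns `c`, `bL`, `bR`.
#' @export
sampleLatents <- function(nTrials, rhoBg, bgLogSd = 0.35, seed = NULL) {
  if (!is.finite(rhoBg) || abs(rhoBg) > 1) stop("rhoBg must lie in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)
  cfac <- rnorm(nTrials)
  z1 <- rnorm(nTrials)
  z2 <- rnorm(nTrials)
  bL <- bgLogSd * z1
  bR <- bgLogSd * (rhoBg * z1 + sqrt(1 - rhoBg^2) * z2)
  data.frame(c = cfac, bL = bL, bR = bR)
}

#' Generate a band-limited background-EMG trace
#'
#' Zero-mean Gaussian noise band-pass filtered to 100-1000 Hz (4th-order
#' Butterworth applied forward and backward) and rescaled so that the r.m.s.
#' over `scaleWindow` — by default the whole trace — equals `targetRms`
#' exactly. Passing the analysis window as `scaleWindow` pins the measured
#' covariate to the target.
#'
#' @param targetRms target r.m.s. in microvolts (>= 0; 0 yields silence).
#' @param durationMs trace duration in ms.
#' @param fs sampling rate in Hz.
#' @param scaleWindow optional `(start, end)` ms (relative to trace start)
#'   over which the r.m.s. is pinned to the target.
#' @param band filter pass band in Hz.
#' @return numeric vector of `round(durationMs * fs / 1000)` samples.
#' @export
makeBackgroundTrace <- function(targetRms, durationMs, fs,
                                scaleWindow = NULL, band = c(100, 1000)) {
  if (targetRms < 0) stop("targetRms must be >= 0")
  n <- round(durationMs * fs / 1000)
  if (targetRms == 0) return(numeric(n))
  pad <- round(0.05 * fs)                     # 50 ms padding absorbs filter edges
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, rnorm(n + 2 * pad))
  y <- y[(pad + 1):(pad + n)]
  idx <- if (is.null(scaleWindow)) seq_len(n)
         else windowToIndices(scaleWindow[1], scaleWindow[2], fs, nSamples = n)
  y * targetRms / sqrt(mean(y[idx]^2))
}

#' Biphasic MEP waveform
#'
#' A Hann-windowed single-cycle sinusoid of the given support (default
#' 15 ms), scaled so its sampled peak-to-peak amplitude equals `ampPp`
#' exactly; the deflection is zero outside the support. The onset latency
#' must place the whole support inside the MEP measurement window.
#'
#' @param ampPp target peak-to-peak amplitude in microvolts (>= 0).
#' @param latencyMs onset latency in ms after the stimulus.
#' @param fs sampling rate in Hz.
#' @param durMs support duration in ms (<= 25).
#' @param mepWindow measurement window the deflection must lie inside.
#' @return list with `wave` (numeric vector of the support samples) and
#'   `latencyMs`.
#' @export
makeMepWaveform <- function(ampPp, latencyMs, fs, durMs = 15,
                            mepWindow = c(12.5, 45)) {
  if (ampPp < 0) stop("ampPp must be >= 0")
  if (durMs > 25) stop("support must be at most 25 ms")
  if (latencyMs < mepWindow[1] || latencyMs + durMs > mepWindow[2])
    stop("bounds error: deflection support [", latencyMs, ", ",
         latencyMs + durMs, "] ms lies outside the measurement window")
  n <- round(durMs * fs / 1000)
  t <- seq_len(n) / n
  tmpl <- sin(2 * pi * t) * sin(pi * t)^2
  pp <- max(tmpl) - min(tmpl)
  list(wave = if (ampPp == 0) numeric(n) else tmpl * (ampPp / pp),
       latencyMs = latencyMs)
}

# short biphasic stimulus artefact, dissipating well before 12.5 ms
.artefactSpike <- function(fs, ampUv = 150, durMs = 1.2) {
  n <- max(2L, round(durMs * fs / 1000))
  t <- seq_len(n) / n
  ampUv * sin(2 * pi * t) * exp(-3 * t)
}

.ampScale <- function(cfg) {
  # grand-mean correction so that E[amp | TS alone] = ampMeanTs
  tot <- cfg@sharedLoading^2 + (cfg@bgCoupling * cfg@bgLogSd)^2 +
    cfg@noiseSd^2 + cfg@participantSd^2
  cfg@ampMeanTs / exp(tot / 2)
}

#' Generate one synthetic trial
#'
#' Composes background noise (r.m.s. pinned on the 100 ms analysis window to
#' the per-trial target), stimulus artefact spikes strictly before 12.5 ms
#' post-stimulus, and biphasic MEP deflections per the condition contract:
#' `CS_TS` trials carry a right-FCR MEP 12.5-45 ms after the test stimulus
#' and a left-FCR MEP 12.5-45 ms after the conditioning stimulus; `TS_only`
#' trials have no left-FCR MEP; `CS_only` trials no right-FCR MEP.
#'
#' @param condition one of `"CS_TS"`, `"TS_only"`, `"CS_only"`.
#' @param latents one row of [sampleLatents()] output.
#' @param pp participant parameters: list with `uR`, `uL` (log-scale
#'   offsets) and `bgMedR`, `bgMedL` (background medians in microvolts).
#' @param cfg a [SyntheticConfig-class].
#' @param latencyMs MEP onset latency (ms post-stimulus).
#' @param epochMs epoch duration in ms.
#' @param epochStartMs epoch start relative to the test stimulus.
#' @return list with `lFCR`, `rFCR` (trace vectors) and `truth` (one-row
#'   `data.frame`: condition, latents, true amplitudes and background
#'   r.m.s. targets per side).
#' @export
generateTrial <- function(condition, latents, pp, cfg, latencyMs = 18,
                          epochMs = 1000, epochStartMs = -500) {
  stopifnot(condition %in% .CONDITIONS)
  fs <- cfg@fs
  M <- .ampScale(cfg)
  eps <- rnorm(2, sd = cfg@noiseSd)
  meanR <- if (condition == "CS_TS") M * cfg@suppression else M
  ampR <- meanR * exp(cfg@sharedLoading * latents$c +
                        cfg@bgCoupling * latents$bR + pp$uR + eps[1])
  ampL <- M * exp(cfg@sharedLoading * latents$c +
                    cfg@bgCoupling * latents$bL + pp$uL + eps[2])
  rmsR <- pp$bgMedR * exp(latents$bR)
  rmsL <- pp$bgMedL * exp(latents$bL)

  tCS <- if (condition != "TS_only") -10 else NA_real_
  tTS <- if (condition != "CS_only") 0 else NA_real_
  csRef <- if (!is.na(tCS)) tCS else -10
  # 100 ms analysis window, in ms relative to trace start
  sw <- c(csRef - 3 - 100, csRef - 3) - epochStartMs
  n <- round(epochMs * fs / 1000)

  addAt <- function(trace, wave, atMs) {
    i0 <- round((atMs - epochStartMs) * fs / 1000)
    ii <- i0 + seq_along(wave)
    ii <- ii[ii >= 1 & ii <= n]
    trace[ii] <- trace[ii] + wave[seq_along(ii)]
    trace
  }
  spk <- .artefactSpike(fs)
  mkChannel <- function(rms, mepAmp, stimMs) {
    tr <- makeBackgroundTrace(rms, epochMs, fs, scaleWindow = sw)
    if (!is.na(tCS)) tr <- addAt(tr, spk, tCS)
    if (!is.na(tTS)) tr <- addAt(tr, spk, tTS)
    if (!is.na(mepAmp) && !is.na(stimMs)) {
      mw <- makeMepWaveform(mepAmp, latencyMs, fs)
      tr <- addAt(tr, mw$wave, stimMs + mw$latencyMs)
    }
    tr
  }
  rTrace <- mkChannel(rmsR, if (condition != "CS_only") ampR else NA, tTS)
  lTrace <- mkChannel(rmsL, if (condition != "TS_only") ampL else NA, tCS)
  truth <- data.frame(
    condition = condition, c = latents$c, bL = latents$bL, bR = latents$bR,
    amp_rFCR = if (condition != "CS_only") ampR else NA_real_,
    amp_lFCR = if (condition != "TS_only") ampL else NA_real_,
    rms_rFCR = rmsR, rms_lFCR = rmsL, stringsAsFactors = FALSE)
  list(lFCR = lTrace, rFCR = rTrace, truth = truth)
}

.participantParams <- function(cfg) {
  list(uR = rnorm(1, sd = cfg@participantSd),
       uL = rnorm(1, sd = cfg@participantSd),
       bgMedR = cfg@bgRmsMedian * exp(rnorm(1, sd = 0.2)),
       bgMedL = cfg@bgRmsMedian * exp(rnorm(1, sd = 0.2)))
}

.conditionVector <- function(cfg) {
  sample(c(rep("CS_TS", cfg@trialsCsTs), rep("TS_only", cfg@trialsTsOnly),
           rep("CS_only", cfg@trialsCsOnly)))
}

#' Generate a full trace-level synthetic dataset
#'
#' Deterministic under the configured seed. Memory scales with
#' `nParticipants * nTrials * epoch samples`; for large parameter-recovery
#' runs use the feature-level path [simulateFeatures()] instead, which draws
#' from the identical generative model without synthesizing traces.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param epochMs,epochStartMs epoch geometry (defaults 1000 ms starting
#'   -500 ms before the test stimulus).
#' @return list with `trials` (a [TrialSet]) and `truth` (a `data.frame`
#'   aligned row-for-row with the trials, carrying the latent draws, true
#'   amplitudes and background targets).
#' @export
generateDataset <- function(cfg = syntheticConfig(), epochMs = 1000,
                            epochStartMs = -500) {
  methods::validObject(cfg)
  set.seed(cfg@seed)
  nS <- round(epochMs * cfg@fs / 1000)
  lmats <- list(); rmats <- list(); meta <- list(); truths <- list()
  for (p in seq_len(cfg@nParticipants)) {
    pid <- sprintf("P%03d", p)
    pp <- .participantParams(cfg)
    conds <- .conditionVector(cfg)
    nT <- length(conds)
    lat <- sampleLatents(nT, cfg@rhoBg, cfg@bgLogSd)
    lmat <- matrix(0, nS, nT)
    rmat <- matrix(0, nS, nT)
    tr <- vector("list", nT)
    for (j in seq_len(nT)) {
      g <- generateTrial(conds[j], lat[j, ], pp, cfg,
                         epochMs = epochMs, epochStartMs = epochStartMs)
      lmat[, j] <- g$lFCR
      rmat[, j] <- g$rFCR
      tr[[j]] <- g$truth
    }
    lmats[[p]] <- lmat; rmats[[p]] <- rmat
    meta[[p]] <- data.frame(participant = pid,
                            trial = sprintf("T%02d", seq_len(nT)),
                            condition = conds, stringsAsFactors = FALSE)
    tt <- do.call(rbind, tr)
    tt$participant <- pid
    tt$trial <- meta[[p]]$trial
    truths[[p]] <- tt
  }
  md <- do.call(rbind, meta)
  trials <- TrialSet(lFCR = do.call(cbind, lmats), rFCR = do.call(cbind, rmats),
                     participant = md$participant, trial = md$trial,
                     condition = md$condition, fs = cfg@fs,
                     epochStartMs = epochStartMs)
  list(trials = trials, truth = do.call(rbind, truths))
}

#' Simulate a feature table directly from the generative model
#'
#' Fast path for calibration and parameter-recovery studies: draws the same
#' latent structure as [generateDataset()] and emits the per-trial scalar
#' features analytically — true MEP amplitudes, areas (a fixed multiple of
#' amplitude, rank-equivalent to the trace-level area), and the per-trial
#' background r.m.s. target for every configured window (the trace-level
#' pipeline pins the 100 ms window to this target; shorter windows differ
#' only by band-limited sampling noise).
#'
#' @param cfg a [SyntheticConfig-class].
#' @param windows background windows to emit columns for.
#' @return list with `features` (a `data.frame` shaped like
#'   [extractFeatures()] output) and `truth` (latent draws per trial).
#' @export
simulateFeatures <- function(cfg = syntheticConfig(), windows = c(100, 50, 10)) {
  methods::validObject(cfg)
  set.seed(cfg@seed)
  M <- .ampScale(cfg)
  feats <- list(); truths <- list()
  areaK <- 0.35 * 32.5 / 2     # nominal rectified-area factor, uV*ms per uV
  for (p in seq_len(cfg@nParticipants)) {
    pid <- sprintf("P%03d", p)
    pp <- .participantParams(cfg)
    conds <- .conditionVector(cfg)
    nT <- length(conds)
    lat <- sampleLatents(nT, cfg@rhoBg, cfg@bgLogSd)
    eps <- matrix(rnorm(2 * nT, sd = cfg@noiseSd), ncol = 2)
    meanR <- ifelse(conds == "CS_TS", M * cfg@suppression, M)
    ampR <- meanR * exp(cfg@sharedLoading * lat$c +
                          cfg@bgCoupling * lat$bR + pp$uR + eps[, 1])
    ampL <- M * exp(cfg@sharedLoading * lat$c +
                      cfg@bgCoupling * lat$bL + pp$uL + eps[, 2])
    ampR[conds == "CS_only"] <- NA
    ampL[conds == "TS_only"] <- NA
    rmsR <- pp$bgMedR * exp(lat$bR)
    rmsL <- pp$bgMedL * exp(lat$bL)
    f <- data.frame(participant = pid, trial = sprintf("T%02d", seq_len(nT)),
                    condition = conds,
                    mep_amp_rFCR = ampR, mep_amp_lFCR = ampL,
                    mep_area_rFCR = ampR * areaK, mep_area_lFCR = ampL * areaK,
                    stringsAsFactors = FALSE)
    for (w in windows) {
      f[[sprintf("rms_rFCR_%g", w)]] <- rmsR
      f[[sprintf("rms_lFCR_%g", w)]] <- rmsL
    }
    feats[[p]] <- f
    truths[[p]] <- cbind(data.frame(participant = pid, trial = f$trial,
                                    condition = conds,
                                    stringsAsFactors = FALSE), lat)
  }
  list(features = do.call(rbind, feats), truth = do.call(rbind, truths))
}
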