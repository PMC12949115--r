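# Fixtures are built in code; no binary data ships with the package.

# A TrialSet of flat (all-zero or constant) traces with canonical timing.
flatTrialSet <- function(conditions = "CS_TS", value = 0, nSamples = 5000,
                         fs = 5000, participant = "P1") {
  n <- length(conditions)
  m <- matrix(value, nSamples, n)
  TrialSet(lFCR = m, rFCR = m, participant = participant,
           trial = sprintf("t%d", seq_len(n)), condition = conditions, fs = fs)
}

# Insert a waveform into a trace at a given time (ms relative to TS).
insertAt <- function(trace, wave, atMs, fs = 5000, epochStartMs = -500) {
  i0 <- round((atMs - epochStartMs) * fs / 1000)
  trace[i0 + seq_along(wave)] <- trace[i0 + seq_along(wave)] + wave
  trace
}

# Small trace-level synthetic configuration used across tests.
smallSynthConfig <- function(seed = 101L, nParticipants = 3L) {
  syntheticConfig(nParticipants = nParticipants, trialsCsTs = 6L,
                  trialsTsOnly = 4L, trialsCsOnly = 3L, seed = seed)
}

# Feature-level participant series: lognormal responses and covariates with
# optional shared factor and background coupling (local null oracle for the
# semi-partial estimators).
simulateSeries <- function(n = 18, shared = 0, coupling = 0, rhoBg = 0,
                           noiseSd = 0.75, bgLogSd = 0.35) {
  cf <- rnorm(n)
  z1 <- rnorm(n); z2 <- rnorm(n)
  bL <- bgLogSd * z1
  bR <- bgLogSd * (rhoBg * z1 + sqrt(1 - rhoBg^2) * z2)
  list(x = exp(shared * cf + coupling * bR + rnorm(n, sd = noiseSd)),
       y = exp(shared * cf + coupling * bL + rnorm(n, sd = noiseSd)),
       cx = exp(bR), cy = exp(bL))
}
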