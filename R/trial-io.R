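#' Read trial-level EMG recordings from the long-format interchange file
#'
#' The canonical interchange format is a delimited UTF-8 text file with a
#' header row and exactly the columns `participant`, `trial`, `condition`,
#' `channel` (one of `lFCR`, `rFCR`), `sample_index` (0-based within each
#' trace) and `value_uV`. Two optional leading comment lines,
#' `# fs_hz=<rate>` and `# epoch_start_ms=<ms>`, carry the sampling rate and
#' epoch origin; the defaults (5000 Hz, -500 ms) apply when absent.
#'
#' @param path file to read.
#' @param format only `"long"` (the delimited long format) is supported.
#' @return a validated [TrialSet], trials ordered by participant then trial.
#' @seealso [writeTrials()]
#' @export
readTrials <- function(path, format = c("long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 4L)
  meta <- grep("^#", hdr, value = TRUE)
  fs <- 5000
  epochStartMs <- -500
  for (ln in meta) {
    kv <- sub("^#\\s*", "", ln)
    if (grepl("^fs_hz=", kv)) fs <- as.numeric(sub("^fs_hz=", "", kv))
    if (grepl("^epoch_start_ms=", kv))
      epochStartMs <- as.numeric(sub("^epoch_start_ms=", "", kv))
  }
  dt <- data.table::fread(path, skip = length(meta), sep = "\t",
                          colClasses = list(character = c("participant", "trial")))
  req <- c("participant", "trial", "condition", "channel", "sample_index", "value_uV")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  badc <- setdiff(unique(dt$condition), .CONDITIONS)
  if (length(badc))
    stop("validation error: unknown condition label(s): ",
         paste(badc, collapse = ", "))
  badch <- setdiff(unique(dt$channel), .CHANNELS)
  if (length(badch))
    stop("format error: unknown channel label(s): ", paste(badch, collapse = ", "))

  data.table::setorderv(dt, c("participant", "trial", "channel", "sample_index"))
  key <- paste(dt$participant, dt$trial, sep = "\r")
  counts <- dt[, .N, by = .(participant, trial, channel)]
  wide <- data.table::dcast(counts, participant + trial ~ channel, value.var = "N",
                            fill = 0L)
  for (ch in .CHANNELS) if (!ch %in% names(wide)) wide[[ch]] <- 0L
  off <- wide[wide$lFCR != wide$rFCR | wide$lFCR == 0L, ]
  if (nrow(off))
    stop("validation error: trace length mismatch between channels for trial(s): ",
         paste(utils::head(paste(off$participant, off$trial, sep = "/"), 5L),
               collapse = ", "))
  lens <- unique(wide$lFCR)
  if (length(lens) != 1L)
    stop("validation error: all trials in one set must share the same epoch length; ",
         "found lengths ", paste(lens, collapse = ", "))
  L <- lens[1]

  ldt <- dt[dt$channel == "lFCR", ]
  rdt <- dt[dt$channel == "rFCR", ]
  if (!all(ldt$sample_index == rep.int(0:(L - 1L), nrow(ldt) / L)) ||
      !all(rdt$sample_index == rep.int(0:(L - 1L), nrow(rdt) / L)))
    stop("validation error: sample_index must cover 0..", L - 1L,
         " exactly once per trace")
  lmat <- matrix(ldt$value_uV, nrow = L)
  rmat <- matrix(rdt$value_uV, nrow = L)
  info <- ldt[seq(1L, nrow(ldt), by = L),
              c("participant", "trial", "condition")]
  TrialSet(lFCR = lmat, rFCR = rmat,
           participant = info$participant, trial = info$trial,
           condition = info$condition, fs = fs, epochStartMs = epochStartMs)
}

#' Write trial-level EMG recordings to the long-format interchange file
#'
#' Values are written with 17 significant digits so that a write/read round
#' trip reproduces every sample bit-for-bit.
#'
#' @param trials a non-empty [TrialSet].
#' @param path destination file (tab-separated text).
#' @param format only `"long"` is supported.
#' @return invisibly, `path`.
#' @export
writeTrials <- function(trials, path, format = c("long")) {
  format <- match.arg(format)
  stopifnot(is(trials, "TrialSet"))
  if (ncol(trials) == 0L)
    stop("validation error: empty trial collection; nothing written")
  methods::validObject(trials)
  cd <- SummarizedExperiment::colData(trials)
  L <- nrow(trials)
  n <- ncol(trials)
  blk <- function(ch) {
    v <- as.vector(SummarizedExperiment::assay(trials, ch))
    data.table::data.table(
      participant = rep(cd$participant, each = L),
      trial = rep(cd$trial, each = L),
      condition = rep(cd$condition, each = L),
      channel = ch,
      sample_index = rep.int(0:(L - 1L), n),
      value_uV = sprintf("%.17g", v)
    )
  }
  out <- data.table::rbindlist(lapply(.CHANNELS, blk))
  data.table::setorderv(out, c("participant", "trial", "channel", "sample_index"))
  writeLines(c(sprintf("# fs_hz=%.17g", samplingRate(trials)),
               sprintf("# epoch_start_ms=%.17g", epochStart(trials))), path)
  data.table::fwrite(out, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Create an analysis configuration
#'
#' @param backgroundWindows background-EMG window durations in ms
#'   (default `c(100, 50, 10)`).
#' @param windowGap gap in ms between the end of each background window and
#'   the conditioning stimulus (default 3).
#' @param mepWindow MEP measurement window in ms after the stimulus
#'   (default `c(12.5, 45)`).
#' @param bootstrapReps bootstrap resamples for sample-level confidence
#'   intervals (default 10000).
#' @param seed random seed used for the bootstrap (default 1).
#' @param methods covariate-adjustment methods to run; subset of
#'   `c("parametric", "psr")`.
#' @return an [AnalysisConfig-class] object.
#' @export
analysisConfig <- function(backgroundWindows = c(100, 50, 10),
                           windowGap = 3,
                           mepWindow = c(12.5, 45),
                           bootstrapReps = 10000L,
                           seed = 1L,
                           methods = c("parametric", "psr")) {
  new("AnalysisConfig",
      backgroundWindows = as.numeric(backgroundWindows),
      windowGap = as.numeric(windowGap),
      mepWindow = as.numeric(mepWindow),
      bootstrapReps = as.integer(bootstrapReps),
      seed = as.integer(seed),
      methods = methods)
}

#' Load / save an analysis configuration
#'
#' The configuration file is a plain-text YAML key-value document with keys
#' `background_windows_ms`, `window_gap_ms`, `mep_window_ms`,
#' `bootstrap_reps`, `rng_seed` and `adjustment_methods`; absent keys take
#' their documented defaults, so an empty file yields the default
#' configuration.
#'
#' @param path configuration file.
#' @return [loadConfig()] returns a validated [AnalysisConfig-class];
#'   [saveConfig()] invisibly returns `path`.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  pick <- function(key, default) if (!is.null(vals[[key]])) vals[[key]] else default
  analysisConfig(
    backgroundWindows = pick("background_windows_ms", c(100, 50, 10)),
    windowGap = pick("window_gap_ms", 3),
    mepWindow = pick("mep_window_ms", c(12.5, 45)),
    bootstrapReps = pick("bootstrap_reps", 10000L),
    seed = pick("rng_seed", 1L),
    methods = unlist(pick("adjustment_methods", c("parametric", "psr")))
  )
}

#' @rdname loadConfig
#' @param cfg an [AnalysisConfig-class] object.
#' @export
saveConfig <- function(cfg, path) {
  stopifnot(is(cfg, "AnalysisConfig"))
  methods::validObject(cfg)
  yaml::write_yaml(list(
    background_windows_ms = cfg@backgroundWindows,
    window_gap_ms = cfg@windowGap,
    mep_window_ms = cfg@mepWindow,
    bootstrap_reps = cfg@bootstrapReps,
    rng_seed = cfg@seed,
    adjustment_methods = cfg@methods
  ), path)
  invisible(path)
}
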