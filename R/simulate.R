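#' Simulation configuration for the synthetic EEG cohort
#'
#' Bundles every parameter of the forward simulation: cohort size, sampling,
#' epoch window, sensor count, the condition-dependent tuning gains, the
#' injected tuning profile, the signal time course (envelope), noise levels
#' and between-subject variability.
#'
#' The defaults encode the study conditions the pipeline is meant to
#' emulate: 15 subjects, 64 sensors at 256 Hz, epochs -0.5 to 1.25 s around
#' the first Gabor with the second Gabor at +600 ms SOA, tuning gain 0.41
#' for expected and 0.67 for unexpected stimuli (arbitrary units), and an
#' orientation-selective signal that is absent before ~50 ms after the
#' second Gabor, peaks between 120 and 250 ms, and decays to zero by 470 ms.
#'
#' @slot nSubjects cohort size.
#' @slot sampleRate Hz.
#' @slot epochWindow numeric(2), epoch start/end in seconds relative to
#'   first-Gabor onset.
#' @slot nSensors sensor count.
#' @slot gains named numeric, tuning gain per condition (a.u.).
#' @slot tuningProfile `"basis"` (inject the encoder's half-cosine^8
#'   channel activation; ground truth exactly recoverable) or `"gaussian"`
#'   (Gaussian channel profile of width `tuningWidthDeg`).
#' @slot tuningWidthDeg width of the Gaussian profile, degrees (used when
#'   `tuningProfile = "gaussian"`).
#' @slot topography base unit-norm sensor weight profile; `numeric(0)`
#'   means a deterministic smooth occipital-like bump is constructed.
#' @slot envelope numeric(4): signal onset, rise end, fall start, offset in
#'   seconds relative to second-Gabor onset (half-cosine ramps between).
#' @slot noiseSdUV white sensor noise SD, microvolts.
#' @slot pinkNoiseSdUV 1/f sensor noise SD, microvolts.
#' @slot intersubjectGainSd SD of the log-normal per-subject gain multiplier.
#' @slot soa second-Gabor onset, seconds after the first.
#' @slot seed master seed; all randomness derives from it.
#' @seealso [simulateEpochs()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
  slots = c(
    nSubjects = "integer", sampleRate = "numeric", epochWindow = "numeric",
    nSensors = "integer", gains = "numeric", tuningProfile = "character",
    tuningWidthDeg = "numeric", topography = "numeric", envelope = "numeric",
    noiseSdUV = "numeric", pinkNoiseSdUV = "numeric",
    intersubjectGainSd = "numeric", soa = "numeric", seed = "integer"
  ),
  prototype = list(
    nSubjects = 15L, sampleRate = 256, epochWindow = c(-0.5, 1.25),
    nSensors = 64L,
    gains = c(expected_repeat = 0.41, unexpected_repeat = 0.67,
              expected_alternate = 0.41, unexpected_alternate = 0.67),
    tuningProfile = "basis", tuningWidthDeg = 27,
    topography = numeric(0),
    envelope = c(0.05, 0.12, 0.25, 0.47),
    noiseSdUV = 1.5, pinkNoiseSdUV = 1.0,
    intersubjectGainSd = 0.1, soa = 0.6, seed = 1L
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be positive")
  if (length(object@epochWindow) != 2L ||
      diff(object@epochWindow) <= 0)
    msg <- c(msg, "epochWindow must be increasing numeric(2)")
  if (any(c(object@noiseSdUV, object@pinkNoiseSdUV,
            object@intersubjectGainSd) < 0))
    msg <- c(msg, "noise and variability SDs must be >= 0")
  if (length(object@topography) &&
      abs(sqrt(sum(object@topography^2)) - 1) > 1e-8)
    msg <- c(msg, "topography must have unit Euclidean norm")
  if (length(object@envelope) != 4L || is.unsorted(object@envelope))
    msg <- c(msg, "envelope must be 4 non-decreasing breakpoints")
  if (!object@tuningProfile %in% c("basis", "gaussian"))
    msg <- c(msg, "tuningProfile must be 'basis' or 'gaussian'")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig-class Constructor; any slot can be
#'   overridden by name.
#' @param ... slot values overriding the defaults.
#' @export
SimulationConfig <- function(...) {
  args <- list(...)
  for (nm in c("nSubjects", "nSensors", "seed"))
    if (nm %in% names(args)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("SimulationConfig"), args))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d subject(s), %d sensors @ %g Hz, epoch %g..%g s\n",
    object@nSubjects, object@nSensors, object@sampleRate,
    object@epochWindow[1L], object@epochWindow[2L]))
  cat("  gains:", paste(sprintf("%s=%g", names(object@gains), object@gains),
                        collapse = ", "), "\n")
  cat(sprintf("  noise: white %g uV, pink %g uV; subject gain sd %g; seed %d\n",
              object@noiseSdUV, object@pinkNoiseSdUV,
              object@intersubjectGainSd, object@seed))
  invisible(NULL)
})

#' Read/write a simulation configuration as JSON
#'
#' All slots are serialised; on reading, absent fields keep their defaults.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param path JSON file path.
#' @export
writeSimulationConfig <- function(config, path) {
  sl <- slotNames(config)
  vals <- lapply(sl, function(s) slot(config, s))
  names(vals) <- sl
  vals$gains <- as.list(vals$gains)   # keep condition names in JSON
  jsonlite::write_json(vals, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeSimulationConfig
#' @export
readSimulationConfig <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  numSlots <- c("sampleRate", "epochWindow", "tuningWidthDeg", "topography",
                "envelope", "noiseSdUV", "pinkNoiseSdUV",
                "intersubjectGainSd", "soa")
  for (nm in intersect(numSlots, names(vals)))
    vals[[nm]] <- as.numeric(unlist(vals[[nm]]))
  if (!is.null(vals$gains)) {
    g <- unlist(vals$gains)
    vals$gains <- stats::setNames(as.numeric(g), names(g))
  }
  if (!is.null(vals$tuningProfile))
    vals$tuningProfile <- as.character(unlist(vals$tuningProfile))
  do.call(SimulationConfig, vals)
}

# Smooth signal envelope: 0 before onset, half-cosine rise, plateau at 1,
# half-cosine fall, 0 after offset. `tau` is time relative to second-Gabor
# onset, seconds.
signalEnvelope <- function(tau, breaks) {
  on <- breaks[1L]; riseEnd <- breaks[2L]
  fallStart <- breaks[3L]; off <- breaks[4L]
  e <- numeric(length(tau))
  up <- tau > on & tau < riseEnd
  e[up] <- 0.5 * (1 - cos(pi * (tau[up] - on) / max(riseEnd - on, 1e-9)))
  e[tau >= riseEnd & tau <= fallStart] <- 1
  dn <- tau > fallStart & tau < off
  e[dn] <- 0.5 * (1 + cos(pi * (tau[dn] - fallStart) / max(off - fallStart, 1e-9)))
  e
}

# Deterministic smooth unit-norm base topography (occipital-like bump).
defaultTopography <- function(nSensors) {
  x <- seq_len(nSensors)
  w <- exp(-(x - 0.8 * nSensors)^2 / (2 * (nSensors / 12)^2))
  w / sqrt(sum(w^2))
}

# Forward model: each of the 9 orientation channels projects to the sensors
# through a circular shift of the base topography, giving a full-column-rank
# sensors x channels matrix with unit-norm columns.
forwardModelMatrix <- function(topography, nChannels = 9L) {
  nS <- length(topography)
  step <- max(1L, nS %/% nChannels)
  W0 <- vapply(seq_len(nChannels) - 1L, function(k) {
    idx <- ((seq_len(nS) - 1L - k * step) %% nS) + 1L
    topography[idx]
  }, numeric(nS))
  W0
}

# Injected channel activation for one orientation.
injectedProfile <- function(orientation, config, basis) {
  if (config@tuningProfile == "basis") {
    drop(evalBasis(basis, orientation))
  } else {
    d <- orientationDistance(basis@centers, orientation)
    exp(-d^2 / (2 * config@tuningWidthDeg^2))
  }
}

# 1/f-amplitude noise, one column per trace, unit SD overall; chunked FFT.
pinkNoiseMatrix <- function(n, m, chunk = 4096L) {
  if (m == 0L || n == 0L) return(matrix(0, n, m))
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)            # two-sided frequency index
  amp <- ifelse(f > 0, 1 / sqrt(f), 0)
  out <- matrix(0, n, m)
  for (start in seq(1L, m, by = chunk)) {
    cols <- start:min(start + chunk - 1L, m)
    w <- matrix(stats::rnorm(n * length(cols)), n)
    sp <- stats::mvfft(w) * amp
    out[, cols] <- Re(stats::mvfft(sp, inverse = TRUE)) / n
  }
  out / stats::sd(out)
}

# Deterministic fan-out of the master seed to per-subject seeds (< 2^31).
subjectSeed <- function(seed, subjectId) {
  as.integer((as.numeric(seed) * 48271 + 77003 * subjectId) %% 2147483629)
}

#' Simulate epoched EEG for one subject
#'
#' Generates sensor-level epochs for a session design by pushing a known,
#' orientation-tuned channel activation through a fixed spatial forward
#' model. For a trial with second-Gabor orientation theta and condition
#' gain g, the noiseless signal is
#' `g * envelope(t - soa) * W0 %*% profile(theta)`, with `W0` the
#' sensors-by-channels forward model (circular shifts of the base
#' topography) and `profile` the injected channel activation (the encoder's
#' own half-cosine basis by default, so recovery is exact). White and 1/f
#' sensor noise are added on top. Everything is a deterministic function of
#' the config seed and the subject id.
#'
#' @param design a session design from [generateSessionDesign()].
#' @param config a \linkS4class{SimulationConfig}.
#' @param subjectId integer id; determines the subject's seed and gain
#'   multiplier.
#' @return a list with elements `epochs` (an \linkS4class{EpochsArray}) and
#'   `truth` (a `GroundTruth` list: injected per-condition gains after the
#'   subject multiplier, the multiplier, forward model, envelope
#'   breakpoints, injected per-orientation channel profiles, and the seed).
#'   The analysis stages never read `truth`; it exists to score recovery.
#' @export
simulateEpochs <- function(design, config, subjectId = 1L) {
  if (nrow(design) == 0L) stop("empty design")
  if (config@sampleRate <= 0) stop("non-positive sample rate")
  validObject(config)

  rate <- config@sampleRate
  nSamp <- as.integer(round(diff(config@epochWindow) * rate))
  t0 <- config@epochWindow[1L]
  tim <- t0 + (seq_len(nSamp) - 1L) / rate
  nTr <- nrow(design)
  nS <- config@nSensors

  basis <- makeBasis()
  topo <- if (length(config@topography)) config@topography else
    defaultTopography(nS)
  W0 <- forwardModelMatrix(topo, length(basis@centers))
  env <- signalEnvelope(tim - config@soa, config@envelope)

  seed <- subjectSeed(config@seed, subjectId)
  withSeed(seed, {
    mult <- exp(stats::rnorm(1L, 0, config@intersubjectGainSd))
    gains <- config@gains * mult
    profiles <- vapply(ORIENTATION_GRID,
                       function(o) injectedProfile(o, config, basis),
                       numeric(length(basis@centers)))
    colnames(profiles) <- as.character(ORIENTATION_GRID)

    g <- gains[design$condition]
    A <- profiles[, as.character(design$orientation_second), drop = FALSE]
    S <- W0 %*% sweep(A, 2L, g, "*")        # sensors x trials
    dat <- array(0, dim = c(nTr, nS, nSamp))
    tS <- t(S)
    for (s in seq_len(nSamp)) if (env[s] != 0) dat[, , s] <- tS * env[s]
    if (config@noiseSdUV > 0)
      dat <- dat + stats::rnorm(length(dat), 0, config@noiseSdUV)
    if (config@pinkNoiseSdUV > 0) {
      pk <- pinkNoiseMatrix(nSamp, nTr * nS) * config@pinkNoiseSdUV
      dat <- dat + aperm(array(pk, dim = c(nSamp, nTr, nS)), c(2L, 3L, 1L))
    }

    epochs <- new("EpochsArray", data = dat, sampleRate = rate, t0 = t0,
                  channelLabels = sprintf("S%02d", seq_len(nS)),
                  design = design, rejected = rep(FALSE, nTr))
    # The encoder's regression is scale-invariant: training trials carry the
    # same gain/envelope factor as test trials, so what is recoverable is
    # the gain relative to the trial-mean gain, not the absolute gain.
    trialMeanGain <- mean(g)
    truth <- structure(list(
      subjectId = subjectId, gains = gains, gainMultiplier = mult,
      trialMeanGain = trialMeanGain,
      relativeGains = if (trialMeanGain > 0) gains / trialMeanGain else
        gains * 0,
      topography = topo, forwardModel = W0,
      envelopeBreaks = config@envelope,
      injectedProfiles = profiles, tuningProfile = config@tuningProfile,
      seed = seed), class = "GroundTruth")
    list(epochs = epochs, truth = truth)
  })
}

#' Simulate a multi-subject cohort
#'
#' Draws independent per-subject sessions: each subject gets a fresh design
#' (same block structure, subject-specific seed) and epochs from
#' [simulateEpochs()]. The master seed fans out deterministically, so the
#' same config yields a bit-identical cohort.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param nBlocks,trialsPerBlock session structure per subject.
#' @return a list of length `nSubjects`; each element as in
#'   [simulateEpochs()].
#' @export
simulateCohort <- function(config, nBlocks = 20L, trialsPerBlock = 135L) {
  if (config@nSubjects < 1L) stop("nSubjects must be >= 1")
  lapply(seq_len(config@nSubjects), function(sid) {
    des <- generateSessionDesign(
      nBlocks, trialsPerBlock,
      startBlockType = if (sid %% 2L == 1L) "repeating" else "alternating",
      seed = subjectSeed(config@seed, 100000L + sid), sessionId = sid,
      soa = config@soa)
    simulateEpochs(des, config, subjectId = sid)
  })
}
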