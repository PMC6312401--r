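# Short polynomial hash of a string; stamps the config into logs and errors.
configHash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# "Occipital-like" sensor subset: the fixed posterior fifth of the montage,
# where the simulated visual topography lives (chosen a priori, as an
# occipito-parietal electrode grouping would be on a real cap).
occipitalSubset <- function(labels) {
  n <- length(labels)
  labels[seq(max(1L, round(0.7 * n)), min(n, round(0.9 * n)))]
}

#' Assemble a full-pipeline run configuration
#'
#' Collects every stage's parameters with scaled-down desk defaults
#' (5 subjects, 6 blocks of 135 trials, 1000 / 500 permutations) so a full
#' run completes in minutes; `fullScale = TRUE` switches to the full study
#' conditions (15 subjects, 20 blocks, 50,000 / 5,000 permutations,
#' leave-one-out cross-validation).
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param nSubjects,nBlocks,trialsPerBlock cohort and session structure.
#' @param fullScale use the full-scale study settings.
#' @param simulation named list overriding \linkS4class{SimulationConfig}
#'   slots.
#' @param preprocessing list: `baselineAnchor`, `baselineWindow`,
#'   `rejectUV`, `highpassHz` (NULL to skip), `erpBand` (c(low, high) Hz).
#' @param encoding list: `windowMs`, `stepMs`, `cv`, `k`, `timePad`
#'   (seconds analysed around the second stimulus).
#' @param tuning list: `kernelMs`, `window` (seconds post second stimulus).
#' @param decoding list: `stepMs`, `peakWindowS`.
#' @param stats list: `nPerm`, `nPermGen`, `thresholdP`, `clusterAlpha`.
#' @param doGeneralisation compute the cross-temporal map (the slowest
#'   stage).
#' @param saveEpochs write per-subject epochs containers into the run
#'   directory (large; off by default at desk scale).
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(seed = 1L, nSubjects = 5L, nBlocks = 6L,
                      trialsPerBlock = 135L, fullScale = FALSE,
                      simulation = list(),
                      preprocessing = list(), encoding = list(),
                      tuning = list(), decoding = list(), stats = list(),
                      doGeneralisation = TRUE, saveEpochs = FALSE) {
  if (fullScale) {
    nSubjects <- 15L; nBlocks <- 20L
  }
  merge <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    seed = as.integer(seed), nSubjects = as.integer(nSubjects),
    nBlocks = as.integer(nBlocks),
    trialsPerBlock = as.integer(trialsPerBlock),
    fullScale = fullScale,
    simulation = simulation,
    preprocessing = merge(list(baselineAnchor = "second_gabor",
                               baselineWindow = c(-0.1, 0),
                               rejectUV = 100, highpassHz = NULL,
                               erpBand = c(2, 40)), preprocessing),
    encoding = merge(list(windowMs = 16, stepMs = if (fullScale) 4 else 8,
                          cv = if (fullScale) "loo" else "kfold", k = 10L,
                          timePad = c(-0.1, 0.5)), encoding),
    tuning = merge(list(kernelMs = 16, window = c(0.079, 0.185)), tuning),
    decoding = merge(list(stepMs = if (fullScale) 4 else 8,
                          peakWindowS = 0.6), decoding),
    stats = merge(list(nPerm = if (fullScale) 50000L else 1000L,
                       nPermGen = if (fullScale) 5000L else 500L,
                       thresholdP = 0.05, clusterAlpha = 0.05), stats),
    doGeneralisation = doGeneralisation, saveEpochs = saveEpochs)
  class(cfg) <- "RunConfig"
  cfg
}

clusterSummary <- function(ct, times) {
  list(
    tcrit = ct$tcrit, n_perm = ct$nPerm, tail = ct$tail,
    clusters = lapply(ct$clusters, function(cl) {
      out <- list(indices = cl$indices, mass = cl$mass,
                  p_value = cl$p_value)
      if (!is.null(times)) {
        out$time_start_s <- times[min(cl$indices)]
        out$time_end_s <- times[max(cl$indices)]
      }
      out
    }))
}

significantCluster <- function(ct, alpha) {
  length(ct$clusters) > 0L &&
    any(vapply(ct$clusters, `[[`, numeric(1), "p_value") < alpha)
}

filterTraceBand <- function(x, rate, band, order = 4L) {
  filt <- signal::butter(order, band / (rate / 2), type = "pass")
  signal::filtfilt(filt, x)
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> encode -> fit -> decode -> stats
#' into a run directory: per-subject tuning-fit, decoding and ERP tables
#' (CSV), group cluster tests for the expectation and repetition contrasts
#' on the fitted amplitude and width (JSON), P1/N1 component measures with
#' paired tests, cross-temporal generalisation maps, a ground-truth
#' recovery table, and a markdown report. Every numeric output is a
#' deterministic function of the config. Analysis stages never read the
#' simulator's ground truth; only the recovery-scoring step does.
#'
#' @param config a `RunConfig` from [runConfig()].
#' @param outDir output directory (created; must not pre-exist unless
#'   empty).
#' @return the run directory path, invisibly.
#' @export
runFullAnalysis <- function(config, outDir) {
  stopifnot(inherits(config, "RunConfig"))
  cfgJson <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null", pretty = TRUE)
  cfgHash <- configHash(as.character(cfgJson))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "subjects"), showWarnings = FALSE)
  dir.create(file.path(outDir, "group"), showWarnings = FALSE)
  writeLines(as.character(cfgJson), file.path(outDir, "config.json"))

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed (config ", cfgHash, "): ",
           conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] stage %-12s %6.1f s (config %s)",
                    "encodeEEG", name,
                    proc.time()[["elapsed"]] - t0, cfgHash))
    res
  }

  simArgs <- c(list(nSubjects = config$nSubjects, seed = config$seed),
               config$simulation)
  simCfg <- do.call(SimulationConfig, simArgs)
  cohort <- stage("simulate",
                  simulateCohort(simCfg, config$nBlocks,
                                 config$trialsPerBlock))

  soa <- simCfg@soa
  enc <- config$encoding
  timeRange <- soa + enc$timePad
  tun <- config$tuning
  fitWindow <- soa + tun$window

  perSubject <- stage("analyse", lapply(seq_along(cohort), function(si) {
    ep <- cohort[[si]]$epochs
    pp <- config$preprocessing
    if (!is.null(pp$highpassHz)) ep <- filterEpochs(ep, pp$highpassHz)
    ep <- rereferenceCommonAverage(ep)
    ep <- baselineCorrect(ep, pp$baselineWindow, pp$baselineAnchor)
    ep <- rejectThreshold(ep, pp$rejectUV)

    occ <- occipitalSubset(channelLabels(ep))
    erpRep <- conditionERP(ep, "repetition", occ)
    erpExp <- conditionERP(ep, "expectation", occ)

    tensor <- centerResponses(encodeTimecourse(
      ep, windowMs = enc$windowMs, stepMs = enc$stepMs,
      cvScheme = enc$cv, k = enc$k, timeRange = timeRange))
    fitsT <- rbind(
      selectivityTimecourse(tensor, "expectation", kernelMs = tun$kernelMs),
      selectivityTimecourse(tensor, "repetition", kernelMs = tun$kernelMs))
    fitsW <- windowAverageFit(tensor, fitWindow, "condition")
    fitsWm <- rbind(windowAverageFit(tensor, fitWindow, "expectation"),
                    windowAverageFit(tensor, fitWindow, "repetition"))

    dec <- decodeTimecourse(ep, windowMs = enc$windowMs,
                            stepMs = config$decoding$stepMs,
                            cvScheme = enc$cv, k = enc$k,
                            timeRange = timeRange)
    peaks <- peakAccuracy(dec, config$decoding$peakWindowS, "expectation")

    gen <- if (config$doGeneralisation)
      crossTemporalGeneralise(ep, windowMs = enc$windowMs, stepMs = 24,
                              cvScheme = enc$cv, k = enc$k,
                              timeRange = timeRange) else NULL

    stem <- file.path(outDir, "subjects", sprintf("sub-%02d", si))
    fitsT$subject <- si; fitsW$subject <- si; fitsWm$subject <- si
    utils::write.csv(fitsT, paste0(stem, "_fits_timecourse.csv"),
                     row.names = FALSE)
    utils::write.csv(rbind(fitsW, fitsWm), paste0(stem, "_fits_window.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(subject = si, time = dec$times, accuracy = dec$accuracy),
      paste0(stem, "_decoding.csv"), row.names = FALSE)
    if (config$saveEpochs) writeEpochs(ep, stem, dtype = "float32")
    list(fitsT = fitsT, fitsW = fitsW, fitsWm = fitsWm,
         erpRep = erpRep, erpExp = erpExp, dec = dec, peaks = peaks,
         gen = gen, rate = sampleRate(ep))
  }))

  group <- stage("stats", {
    st <- config$stats
    times <- sort(unique(perSubject[[1L]]$fitsT$time))
    contrastMatrix <- function(param, grouping, hi, lo) {
      t(vapply(perSubject, function(ps) {
        f <- ps$fitsT
        f[f$group == hi, param][order(f$time[f$group == hi])] -
          f[f$group == lo, param][order(f$time[f$group == lo])]
      }, numeric(length(times))))
    }
    ampExp <- contrastMatrix("A", "expectation", "unexpected", "expected")
    ampRep <- contrastMatrix("A", "repetition", "repeat", "alternate")
    sigExp <- contrastMatrix("sigma", "expectation", "unexpected", "expected")
    # the expectation contrast is directional (prediction error increases
    # selectivity), and a one-sided sign-flip test is the only one with
    # attainable p < 0.05 at small cohort sizes (2^n flip patterns)
    ctAmpExp <- clusterTest(ampExp, st$nPerm, st$thresholdP,
                            tail = "greater", seed = config$seed + 11L)
    ctAmpRep <- clusterTest(ampRep, st$nPerm, st$thresholdP,
                            seed = config$seed + 12L)
    ctSigExp <- clusterTest(sigExp, st$nPerm, st$thresholdP,
                            seed = config$seed + 13L)

    # ERP components: filter subject ERPs to the ERP band, then peak-pick.
    rate <- perSubject[[1L]]$rate
    erpBand <- config$preprocessing$erpBand
    erpOf <- function(which, level) t(vapply(perSubject, function(ps) {
      tr <- ps[[which]]$erp[level, ]
      filterTraceBand(tr, rate, erpBand)
    }, numeric(ncol(perSubject[[1L]]$erpRep$erp))))
    erpTime <- perSubject[[1L]]$erpRep$time
    compRep <- list(rep = erpPeakComponents(erpOf("erpRep", "repeat"),
                                            erpTime, soa),
                    alt = erpPeakComponents(erpOf("erpRep", "alternate"),
                                            erpTime, soa))
    compExp <- list(exp = erpPeakComponents(erpOf("erpExp", "expected"),
                                            erpTime, soa),
                    unexp = erpPeakComponents(erpOf("erpExp", "unexpected"),
                                              erpTime, soa))
    erpTests <- list(
      p1_repetition = pairedT(compRep$rep$p1_amplitude,
                              compRep$alt$p1_amplitude),
      n1_repetition = pairedT(compRep$rep$n1_amplitude,
                              compRep$alt$n1_amplitude),
      p1_expectation = pairedT(compExp$exp$p1_amplitude,
                               compExp$unexp$p1_amplitude),
      n1_expectation = pairedT(compExp$exp$n1_amplitude,
                               compExp$unexp$n1_amplitude))

    # window-averaged amplitude paired test (the follow-up analysis)
    wa <- do.call(rbind, lapply(perSubject, `[[`, "fitsWm"))
    ampBy <- function(g) wa$A[wa$group == g][order(wa$subject[wa$group == g])]
    windowTests <- list(
      amplitude_expectation = pairedT(ampBy("unexpected"), ampBy("expected")),
      width_expectation = {
        sg <- function(g) wa$sigma[wa$group == g][order(wa$subject[wa$group == g])]
        pairedT(sg("unexpected"), sg("expected"))
      },
      amplitude_repetition = pairedT(ampBy("repeat"), ampBy("alternate")))

    genTest <- NULL
    if (config$doGeneralisation) {
      gt <- perSubject[[1L]]$gen@trainTimes
      genArr <- array(0, dim = c(length(perSubject), length(gt), length(gt)))
      for (si in seq_along(perSubject))
        genArr[si, , ] <- perSubject[[si]]$gen@selectivity
      ctGen <- clusterTest(genArr, st$nPermGen, st$thresholdP,
                           tail = "greater", seed = config$seed + 14L)
      genTest <- clusterSummary(ctGen, NULL)
      meanMap <- new("GeneralizationMap",
                     selectivity = apply(genArr, c(2L, 3L), mean),
                     trainTimes = gt, testTimes = gt)
      writeGeneralizationMap(meanMap,
                             file.path(outDir, "group",
                                       "generalisation_mean.csv"))
    }

    statsOut <- list(
      config_hash = cfgHash,
      cluster_alpha = st$clusterAlpha,
      amplitude_expectation = clusterSummary(ctAmpExp, times),
      amplitude_expectation_significant =
        significantCluster(ctAmpExp, st$clusterAlpha),
      amplitude_repetition = clusterSummary(ctAmpRep, times),
      amplitude_repetition_significant =
        significantCluster(ctAmpRep, st$clusterAlpha),
      sigma_expectation = clusterSummary(ctSigExp, times),
      sigma_expectation_significant =
        significantCluster(ctSigExp, st$clusterAlpha),
      window_tests = windowTests,
      erp_tests = erpTests,
      generalisation = genTest)
    jsonlite::write_json(statsOut, file.path(outDir, "group", "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    comps <- rbind(
      cbind(condition = "repeat", compRep$rep),
      cbind(condition = "alternate", compRep$alt),
      cbind(condition = "expected", compExp$exp),
      cbind(condition = "unexpected", compExp$unexp))
    utils::write.csv(comps, file.path(outDir, "group",
                                      "erp_components.csv"),
                     row.names = FALSE)
    peaks <- do.call(rbind, lapply(seq_along(perSubject), function(si)
      cbind(subject = si, perSubject[[si]]$peaks)))
    utils::write.csv(peaks, file.path(outDir, "group",
                                      "decoding_peaks.csv"),
                     row.names = FALSE)
    statsOut
  })

  stage("recovery", {
    # scoring only: ground truth may be read here. The encoder recovers
    # gains relative to the trial-mean training gain (scale invariance of
    # the regression), so the recoverable amplitude per condition is
    # relative_gain x Gaussian-fit amplitude of the injected profile.
    rows <- lapply(seq_along(cohort), function(si) {
      truth <- cohort[[si]]$truth
      # the profile of the mid-axis orientation is already centred on the
      # -80..80 offset axis
      profFit <- fitTuningCurve(truth$injectedProfiles[, "80"])
      fw <- perSubject[[si]]$fitsW
      data.frame(subject = si, condition = fw$group,
                 injected_gain = unname(truth$gains[fw$group]),
                 injected_amplitude =
                   unname(truth$relativeGains[fw$group]) * profFit$A,
                 recovered_amplitude = fw$A,
                 recovered_sigma = fw$sigma,
                 injected_sigma = profFit$sigma,
                 stringsAsFactors = FALSE)
    })
    rec <- do.call(rbind, rows)
    rec$relative_error <- (rec$recovered_amplitude - rec$injected_amplitude) /
      rec$injected_amplitude
    utils::write.csv(rec, file.path(outDir, "group", "recovery.csv"),
                     row.names = FALSE)
    rec
  })

  stage("report", reportRun(outDir))
  invisible(outDir)
}

#' Render the markdown report of a completed run
#'
#' Deterministically renders `report.md` (plus PNG figures) from the CSV
#' and JSON artefacts of a run directory; nothing is recomputed. Calling
#' it twice on the same directory yields identical markdown.
#'
#' @param runDir a directory produced by [runFullAnalysis()].
#' @param figures also render PNG figures under `figures/`.
#' @return the path of the markdown report, invisibly.
#' @export
reportRun <- function(runDir, figures = TRUE) {
  need <- c("config.json", file.path("group", "stats.json"),
            file.path("group", "erp_components.csv"),
            file.path("group", "decoding_peaks.csv"),
            file.path("group", "recovery.csv"))
  missing <- need[!file.exists(file.path(runDir, need))]
  if (length(missing))
    stop("run directory is missing artefact(s): ",
         paste(missing, collapse = ", "))
  st <- jsonlite::read_json(file.path(runDir, "group", "stats.json"),
                            simplifyVector = FALSE)
  comps <- utils::read.csv(file.path(runDir, "group", "erp_components.csv"))
  peaks <- utils::read.csv(file.path(runDir, "group", "decoding_peaks.csv"))
  rec <- utils::read.csv(file.path(runDir, "group", "recovery.csv"))

  fmtClusters <- function(cs) {
    if (length(cs$clusters) == 0L) return("none")
    paste(vapply(cs$clusters, function(cl) {
      win <- if (!is.null(cl$time_start_s))
        sprintf(" (%.3f-%.3f s)", cl$time_start_s, cl$time_end_s) else ""
      sprintf("mass %.2f%s, p = %.4g", cl$mass, win, cl$p_value)
    }, character(1)), collapse = "; ")
  }
  mdTable <- function(df, digits = 4) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, digits))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1L, function(r)
      paste0("| ", paste(trimws(r), collapse = " | "), " |"))
    c(header, sep, rows)
  }

  aggComp <- stats::aggregate(
    cbind(p1_amplitude, p1_latency_ms, n1_amplitude, n1_latency_ms) ~
      condition, data = comps, FUN = mean)
  aggPeaks <- stats::aggregate(peak_accuracy ~ group, data = peaks,
                               FUN = mean)
  aggRec <- stats::aggregate(
    cbind(injected_amplitude, recovered_amplitude, relative_error) ~
      condition, data = rec, FUN = mean)

  lines <- c(
    "# Synthetic repetition/expectation encoding analysis",
    "",
    sprintf("Config hash: `%s`", st$config_hash),
    "",
    "## Orientation-selectivity contrasts (fitted Gaussian amplitude)",
    "",
    sprintf("- Expectation (unexpected - expected): clusters: %s; significant: %s",
            fmtClusters(st$amplitude_expectation),
            st$amplitude_expectation_significant),
    sprintf("- Repetition (repeat - alternate): clusters: %s; significant: %s",
            fmtClusters(st$amplitude_repetition),
            st$amplitude_repetition_significant),
    sprintf("- Tuning width, expectation: clusters: %s; significant: %s",
            fmtClusters(st$sigma_expectation),
            st$sigma_expectation_significant),
    "",
    "## Window-averaged paired tests",
    "",
    sprintf("- Amplitude, unexpected vs expected: t = %.3f, df = %d, p = %.4g",
            st$window_tests$amplitude_expectation$t,
            as.integer(st$window_tests$amplitude_expectation$df),
            st$window_tests$amplitude_expectation$p),
    sprintf("- Width, unexpected vs expected: t = %.3f, df = %d, p = %.4g",
            st$window_tests$width_expectation$t,
            as.integer(st$window_tests$width_expectation$df),
            st$window_tests$width_expectation$p),
    sprintf("- Amplitude, repeat vs alternate: t = %.3f, df = %d, p = %.4g",
            st$window_tests$amplitude_repetition$t,
            as.integer(st$window_tests$amplitude_repetition$df),
            st$window_tests$amplitude_repetition$p),
    "",
    "## ERP components (P1 / N1, condition means)",
    "",
    mdTable(aggComp),
    "",
    sprintf("Paired tests: P1 repetition p = %.4g; N1 repetition p = %.4g; P1 expectation p = %.4g; N1 expectation p = %.4g",
            st$erp_tests$p1_repetition$p, st$erp_tests$n1_repetition$p,
            st$erp_tests$p1_expectation$p, st$erp_tests$n1_expectation$p),
    "",
    "## Peak decoding accuracy (chance = 1/9)",
    "",
    mdTable(aggPeaks),
    "",
    "## Ground-truth recovery",
    "",
    mdTable(aggRec),
    "")
  if (!is.null(st$generalisation))
    lines <- c(lines,
               sprintf("## Cross-temporal generalisation\n\nClusters: %s\n",
                       fmtClusters(st$generalisation)))

  if (figures) {
    figDir <- file.path(runDir, "figures")
    dir.create(figDir, showWarnings = FALSE)
    subFiles <- list.files(file.path(runDir, "subjects"),
                           pattern = "_fits_timecourse\\.csv$",
                           full.names = TRUE)
    if (length(subFiles)) {
      fits <- do.call(rbind, lapply(subFiles, utils::read.csv))
      agg <- stats::aggregate(A ~ group + time, data = fits, FUN = mean)
      grDevices::png(file.path(figDir, "amplitude_timecourse.png"),
                     width = 800, height = 500)
      groups <- sort(unique(agg$group))
      cols <- grDevices::hcl.colors(length(groups), "Dark 3")
      plot(range(agg$time), range(agg$A), type = "n",
           xlab = "time (s, first-stimulus anchored)",
           ylab = "fitted amplitude A (a.u.)",
           main = "Orientation selectivity over time")
      for (gi in seq_along(groups)) {
        sub <- agg[agg$group == groups[gi], ]
        graphics::lines(sub$time, sub$A, col = cols[gi], lwd = 2)
      }
      graphics::legend("topright", legend = groups, col = cols, lwd = 2)
      grDevices::dev.off()
    }
    genFile <- file.path(runDir, "group", "generalisation_mean.csv")
    if (file.exists(genFile)) {
      hdr <- readLines(genFile, n = 2L)
      tt <- as.numeric(strsplit(sub("^# train_times_s: ", "", hdr[1L]),
                                ",")[[1L]])
      m <- as.matrix(utils::read.csv(genFile, comment.char = "#",
                                     header = FALSE))
      grDevices::png(file.path(figDir, "generalisation.png"),
                     width = 600, height = 550)
      graphics::image(tt, tt, m, xlab = "training time (s)",
                      ylab = "test time (s)",
                      main = "Cross-temporal generalisation",
                      col = grDevices::hcl.colors(64, "Viridis"))
      grDevices::dev.off()
    }
  }
  out <- file.path(runDir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
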