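DESIGN_COLUMNS <- c("session_id", "block_id", "block_type", "trial_type",
                    "condition", "orientation_first", "orientation_second",
                    "is_target", "onset_second_s")

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate a factorial repetition/expectation session design
#'
#' Builds one session of the paired-Gabor paradigm: blocks alternate between
#' a *repeating* context (80\% of trials repeat the first Gabor's
#' orientation, 20\% alternate) and an *alternating* context (contingencies
#' reversed). Crossing trial type with block context yields the 2x2 design:
#' expected/unexpected x repeat/alternate. Orientations live on the
#' 9-value grid 0, 20, ..., 160 degrees; second-Gabor orientations are
#' balanced across the grid within every block x trial-type cell (exact
#' when the cell size divides by 9, otherwise within one trial). 10\% of
#' the session's trials are flagged as coloured targets, placed uniformly
#' at random across the session.
#'
#' Contingencies are enforced by exact counts, not Bernoulli draws, so a
#' repeating block of 135 trials always contains 108 repeats and 27
#' alternates. On alternate trials the first Gabor's orientation is drawn
#' from the 8 grid values that differ from the second Gabor's.
#'
#' @param nBlocks number of blocks (even, so block types balance).
#' @param trialsPerBlock trials per block; must be divisible by 5 (exact
#'   80/20 split).
#' @param startBlockType `"repeating"` or `"alternating"`; the first
#'   block's context (alternates thereafter).
#' @param seed integer seed; the design is a deterministic function of it.
#' @param sessionId integer session identifier stored on each trial.
#' @param soa stimulus onset asynchrony between the two Gabors, seconds.
#' @return A `data.frame` with one row per trial and columns
#'   `session_id`, `block_id`, `block_type`, `trial_type`, `condition`,
#'   `orientation_first`, `orientation_second`, `is_target`,
#'   `onset_second_s`, in that order.
#' @examples
#' des <- generateSessionDesign(4, 45, seed = 1)
#' table(des$block_type, des$trial_type)
#' @export
generateSessionDesign <- function(nBlocks = 20L, trialsPerBlock = 135L,
                                  startBlockType = c("repeating", "alternating"),
                                  seed = 1L, sessionId = 1L, soa = 0.6) {
  startBlockType <- match.arg(startBlockType)
  nBlocks <- as.integer(nBlocks)
  trialsPerBlock <- as.integer(trialsPerBlock)
  if (nBlocks < 2L || nBlocks %% 2L != 0L)
    stop("configuration error: nBlocks must be even (>= 2) so block types balance, got ",
         nBlocks)
  if (trialsPerBlock %% 5L != 0L)
    stop("configuration error: trialsPerBlock must be divisible by 5 for an exact 80/20 split, got ",
         trialsPerBlock)
  nTotal <- nBlocks * trialsPerBlock
  if (nTotal %% 10L != 0L)
    stop("configuration error: session trial count must be divisible by 10 for exact 10% targets, got ",
         nTotal)

  grid <- ORIENTATION_GRID
  withSeed(seed, {
    blockType <- rep(c(startBlockType,
                       setdiff(c("repeating", "alternating"), startBlockType)),
                     length.out = nBlocks)
    blocks <- lapply(seq_len(nBlocks), function(b) {
      bt <- blockType[b]
      nMaj <- as.integer(round(0.8 * trialsPerBlock))
      nMin <- trialsPerBlock - nMaj
      majType <- if (bt == "repeating") "repeat" else "alternate"
      minType <- if (bt == "repeating") "alternate" else "repeat"
      # balanced second-Gabor orientations within each trial-type cell
      oriMaj <- sample(rep_len(grid, nMaj))
      oriMin <- sample(rep_len(grid, nMin))
      tt <- c(rep(majType, nMaj), rep(minType, nMin))
      ori2 <- c(oriMaj, oriMin)
      ord <- sample.int(trialsPerBlock)
      tt <- tt[ord]; ori2 <- ori2[ord]
      ori1 <- ifelse(tt == "repeat", ori2, NA_real_)
      alt <- which(tt == "alternate")
      ori1[alt] <- vapply(ori2[alt],
                          function(o) sample(setdiff(grid, o), 1L),
                          numeric(1))
      cond <- ifelse(tt == majType,
                     paste0("expected_", tt), paste0("unexpected_", tt))
      data.frame(session_id = as.integer(sessionId),
                 block_id = b, block_type = bt, trial_type = tt,
                 condition = cond,
                 orientation_first = ori1, orientation_second = ori2,
                 is_target = FALSE, onset_second_s = soa,
                 stringsAsFactors = FALSE)
    })
    des <- do.call(rbind, blocks)
    des$is_target[sample.int(nTotal, nTotal %/% 10L)] <- TRUE
    rownames(des) <- NULL
    des[DESIGN_COLUMNS]
  })
}

#' Validate a session design table
#'
#' Checks the structural invariants of a design table: column set, exact
#' per-block contingency fractions, orientation grid membership, the
#' repeat/orientation consistency rule, the 10\% target fraction, and
#' within-cell orientation balance.
#'
#' @param design a design `data.frame` as from [generateSessionDesign()].
#' @return invisibly `TRUE`; errors describe the violated invariant.
#' @export
validateDesign <- function(design) {
  miss <- setdiff(DESIGN_COLUMNS, names(design))
  if (length(miss))
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(design$orientation_second %in% ORIENTATION_GRID) ||
      !all(design$orientation_first %in% ORIENTATION_GRID))
    stop("orientations must lie on the 9-value grid 0,20,...,160")
  rep_ok <- (design$trial_type == "repeat") ==
    (design$orientation_first == design$orientation_second)
  if (!all(rep_ok))
    stop("trial_type 'repeat' must coincide with matching orientations")
  for (b in unique(design$block_id)) {
    blk <- design[design$block_id == b, ]
    maj <- if (blk$block_type[1L] == "repeating") "repeat" else "alternate"
    frac <- mean(blk$trial_type == maj)
    if (abs(frac - 0.8) > 1e-12)
      stop(sprintf("block %s: majority trial fraction %.4f != 0.80", b, frac))
  }
  if (abs(mean(design$is_target) - 0.1) > 1e-12)
    stop(sprintf("target fraction %.4f != 0.10", mean(design$is_target)))
  for (cond in unique(design$condition)) {
    tab <- table(factor(design$orientation_second[design$condition == cond],
                        levels = ORIENTATION_GRID))
    if (diff(range(tab)) > 1L)
      stop("condition ", cond,
           ": second-Gabor orientations unbalanced beyond one trial")
  }
  invisible(TRUE)
}

#' Read/write a design table as CSV
#'
#' The design CSV has a mandatory header row and the trial columns in the
#' fixed order documented in [generateSessionDesign()].
#'
#' @param design design `data.frame`.
#' @param path file path.
#' @return `writeDesignCsv` the path, invisibly; `readDesignCsv` the design.
#' @export
writeDesignCsv <- function(design, path) {
  miss <- setdiff(DESIGN_COLUMNS, names(design))
  if (length(miss))
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(design[DESIGN_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDesignCsv
#' @export
readDesignCsv <- function(path) {
  des <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(DESIGN_COLUMNS, names(des))
  if (length(miss))
    stop("design CSV is missing column(s): ", paste(miss, collapse = ", "))
  des$is_target <- as.logical(des$is_target)
  des[DESIGN_COLUMNS]
}
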