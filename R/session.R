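#' Construct a hyperscanning session
#'
#' A session co-registers one recording per participant on a shared session
#' clock together with the experimental design (performance segments with
#' their active-participant sets), the eyes-open/eyes-closed baseline blocks,
#' timed event annotations and an optional missing-data mask. All intervals
#' are half-open `[start, end)` in seconds from recording start.
#'
#' @param recordings named list of [new_recording()] objects, one per
#'   participant; all must share sampling rate and duration.
#' @param design data.frame with columns `trial`, `segment`, `start`, `end`
#'   and a list-column `active` of participant-label character vectors.
#' @param baselines data.frame with columns `phase` (`"pre"`/`"post"`),
#'   `condition` (`"EO"`/`"EC"`), `start`, `end`.
#' @param annotations data.frame with columns `event_type` (e.g. `"SP_1"`),
#'   `type` (`"SP"`/`"DP"`), `time` (session seconds) and `label`.
#' @param mask data.frame with columns `start`, `end`: spans flagged invalid.
#' @param provenance list of per-stage processing log entries.
#' @return an object of class `hyperscan_session`.
#' @export
new_session <- function(recordings, design, baselines = empty_baselines(),
                        annotations = empty_annotations(),
                        mask = empty_mask(), provenance = list()) {
  if (length(recordings) < 2L)
    stop("a hyperscanning session needs at least two participants")
  ids <- vapply(recordings, function(r) r$participant_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate participant ids")
  names(recordings) <- ids
  fs <- vapply(recordings, function(r) r$fs, numeric(1))
  if (length(unique(fs)) != 1L)
    stop("all recordings must share one sampling rate")
  ns <- vapply(recordings, function(r) ncol(r$data), numeric(1))
  if (length(unique(ns)) != 1L)
    stop("all recordings must have equal duration")
  validate_design(design)
  if (nrow(design) > 1L) {
    o <- order(design$start)
    if (any(design$start[o][-1] < design$end[o][-nrow(design)]))
      stop("design segments overlap")
  }
  structure(
    list(recordings = recordings,
         design = design,
         baselines = baselines,
         annotations = annotations,
         mask = mask,
         provenance = provenance),
    class = "hyperscan_session")
}

validate_design <- function(design) {
  need <- c("trial", "segment", "start", "end", "active")
  if (!is.data.frame(design) || !all(need %in% names(design)))
    stop("format error: design table must have columns ",
         paste(need, collapse = ", "))
  if (!is.list(design$active))
    stop("format error: design$active must be a list-column of label vectors")
  if (any(design$end <= design$start))
    stop("format error: design intervals must have end > start")
  invisible(design)
}

empty_baselines <- function() {
  data.frame(phase = character(), condition = character(),
             start = numeric(), end = numeric())
}

empty_annotations <- function() {
  data.frame(event_type = character(), type = character(),
             time = numeric(), label = character())
}

empty_mask <- function() data.frame(start = numeric(), end = numeric())

#' @export
print.hyperscan_session <- function(x, ...) {
  cat(sprintf("<hyperscan_session> %d participants (%s), %.1f s @ %g Hz\n",
              length(x$recordings),
              paste(names(x$recordings), collapse = ", "),
              session_duration(x), session_fs(x)))
  cat(sprintf("  %d design segments, %d baselines, %d annotations, %d masked spans\n",
              nrow(x$design), nrow(x$baselines), nrow(x$annotations),
              nrow(x$mask)))
  invisible(x)
}

#' Sampling rate of a session
#' @param session a `hyperscan_session`.
#' @return sampling frequency in Hz.
#' @export
session_fs <- function(session) session$recordings[[1]]$fs

#' Duration of a session in seconds
#' @param session a `hyperscan_session`.
#' @return duration in seconds.
#' @export
session_duration <- function(session) rec_duration(session$recordings[[1]])

#' All participant dyads of a session
#' @param session a `hyperscan_session`.
#' @return list of length-2 character vectors (participant id pairs) in the
#'   fixed order P1-P2, P1-P3, P2-P3, ... The order within a dyad matters:
#'   the adopted cross-bispectrum convention is asymmetric in the two roles.
#' @export
session_dyads <- function(session) {
  ids <- names(session$recordings)
  cmb <- utils::combn(ids, 2L)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
}

#' Interval of one (trial, segment)
#' @param session a `hyperscan_session`.
#' @param trial trial index.
#' @param segment segment index within the trial.
#' @return numeric `c(start, end)` in session seconds.
#' @export
segment_interval <- function(session, trial, segment) {
  i <- which(session$design$trial == trial & session$design$segment == segment)
  if (length(i) != 1L)
    stop("no such (trial, segment): (", trial, ", ", segment, ")")
  c(session$design$start[i], session$design$end[i])
}

#' Baseline interval of a session
#' @param session a `hyperscan_session`.
#' @param phase `"pre"` or `"post"`.
#' @param condition `"EO"` (eyes open) or `"EC"` (eyes closed).
#' @return numeric `c(start, end)` in session seconds.
#' @export
baseline_interval <- function(session, phase = "pre", condition = "EO") {
  b <- session$baselines
  i <- which(b$phase == phase & b$condition == condition)
  if (length(i) != 1L)
    stop("no ", phase, " ", condition, " baseline in session")
  c(b$start[i], b$end[i])
}

#' Number of active participants in a segment
#' @param session a `hyperscan_session`.
#' @param trial,segment design indices.
#' @return integer count of active participants.
#' @export
n_active <- function(session, trial, segment) {
  i <- which(session$design$trial == trial & session$design$segment == segment)
  if (length(i) != 1L) stop("no such (trial, segment)")
  length(session$design$active[[i]])
}

#' Performance condition of a dyad at a time point
#'
#' Conditions follow the staggered-entry design: `"passive-passive"` when
#' neither dyad member is performing, `"passive-active"` when exactly one is,
#' `"active-active"` when both are. Times outside any design segment (e.g.
#' inter-trial pauses, baselines) are unassigned (`NA`).
#'
#' @param session a `hyperscan_session`.
#' @param dyad length-2 character vector of participant ids.
#' @param time session time in seconds.
#' @return one of `"passive-passive"`, `"passive-active"`, `"active-active"`
#'   or `NA_character_`.
#' @export
dyad_condition <- function(session, dyad, time) {
  d <- session$design
  i <- which(d$start <= time & time < d$end)
  if (length(i) != 1L) return(NA_character_)
  k <- sum(dyad %in% d$active[[i]])
  c("passive-passive", "passive-active", "active-active")[k + 1L]
}

#' Flag a session interval as missing
#'
#' Samples inside the masked half-open interval are excluded downstream:
#' analysis windows overlapping a masked span are dropped, and annotated
#' events inside a masked span are excluded from event analyses. An empty
#' interval is a no-op.
#'
#' @param session a `hyperscan_session`.
#' @param interval numeric `c(start, end)` in session seconds.
#' @return the session with the mask extended.
#' @export
mask_missing <- function(session, interval) {
  stopifnot(length(interval) == 2L)
  if (interval[2] <= interval[1]) return(session)
  session$mask <- rbind(session$mask,
                        data.frame(start = interval[1], end = interval[2]))
  session
}

#' Is a time point inside a masked span?
#' @param session a `hyperscan_session`.
#' @param time session time in seconds.
#' @return logical.
#' @export
is_masked <- function(session, time) {
  m <- session$mask
  nrow(m) > 0L && any(m$start <= time & time < m$end)
}

#' Bookkeeping of the full statistical scan
#'
#' The discovery scan runs one right-tailed test per ordered scalp-channel
#' combination of a dyad, within each (trial, segment, dyad, band) family.
#' With the default 60 analysis channels this is 60^2 = 3600 tests per family
#' and, over 3 trials x 3 segments x 3 dyads x 5 bands, 486000 tests in all.
#'
#' @param n_channels analysis channels per participant (default 60).
#' @param n_trials,n_segments,n_dyads,n_bands design multiplicities.
#' @return list with `per_family` and `total` test counts.
#' @export
count_scan_tests <- function(n_channels = 60, n_trials = 3, n_segments = 3,
                             n_dyads = 3, n_bands = 5) {
  per_family <- n_channels^2
  list(per_family = per_family,
       total = per_family * n_trials * n_segments * n_dyads * n_bands)
}
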