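#' Assign annotated events to dyad performance conditions
#'
#' Each (event, dyad) pair gets exactly one condition from the active set at
#' the event time (`passive-passive`, `passive-active`, `active-active`);
#' events outside any design segment are unassigned (`NA`), and events
#' inside masked spans are flagged excluded.
#'
#' @param session a `hyperscan_session`.
#' @param annotations data.frame with at least `type` and `time` (session
#'   seconds); defaults to the session's own annotations.
#' @param dyads list of dyads (default all).
#' @return data.frame with one row per (event, dyad): `event_type`, `type`,
#'   `time`, `dyad`, `condition`, `excluded`.
#' @export
split_by_condition <- function(session, annotations = session$annotations,
                               dyads = session_dyads(session)) {
  rows <- list()
  for (i in seq_len(nrow(annotations))) {
    for (dy in dyads) {
      rows[[length(rows) + 1L]] <- data.frame(
        event_type = annotations$event_type[i] %||% annotations$type[i],
        type = annotations$type[i],
        time = annotations$time[i],
        dyad = paste(dy, collapse = "-"),
        condition = dyad_condition(session, dy, annotations$time[i]),
        excluded = is_masked(session, annotations$time[i]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Extract an event-locked trace segment
#'
#' Cuts a `[-pre, +post]` second window out of a temporal bispectrum trace,
#' with the annotated event time as the 0 s mark, interpolated onto the
#' common relative 1-s grid. Events whose window exceeds the trace span (or
#' crosses a trace gap) are skipped (`NULL` with a message).
#'
#' @param trace a `bispectrum_trace` (see [temporal_series()]).
#' @param event_time event time in session seconds.
#' @param pre,post window extent in seconds (default 60/60: 121 points).
#' @param event_type,condition metadata carried into the result.
#' @return an object of class `event_locked_trace` (list with `rel_time`,
#'   `values`, `event_time`, `event_type`, `condition`, plus trace
#'   metadata), or `NULL` if the event had to be skipped.
#' @export
extract_peri_event <- function(trace, event_time, pre = 60, post = 60,
                               event_type = NA_character_,
                               condition = NA_character_) {
  rel <- seq(-pre, post, by = attr(trace, "step_s") %||% 1)
  grid <- event_time + rel
  if (min(grid) < min(trace$time) || max(grid) > max(trace$time)) {
    message("event at ", event_time, " s skipped: peri-event window ",
            "exceeds trace span")
    return(NULL)
  }
  ## a gap (masked windows) larger than one step makes interpolation invalid
  tt <- trace$time[trace$time >= min(grid) - 1 & trace$time <= max(grid) + 1]
  if (length(tt) < 2L || max(diff(tt)) > 2 * (attr(trace, "step_s") %||% 1)) {
    message("event at ", event_time, " s skipped: trace gap inside window")
    return(NULL)
  }
  v <- approx(trace$time, trace$value, xout = grid)$y
  structure(list(rel_time = rel, values = v, event_time = event_time,
                 event_type = event_type, condition = condition,
                 dyad = attr(trace, "dyad"),
                 channel_pair = attr(trace, "channel_pair"),
                 band = attr(trace, "band")),
            class = "event_locked_trace")
}

#' Baseline-correct an event-locked trace
#'
#' Subtracts the mean over the pre-event `[-60, 0)` period from the whole
#' trace, leaving the pre-event mean at zero. Idempotent. Values remain
#' relative normalized-bispectrum points; multiply by 100 to display as
#' "BS change (%)".
#'
#' @param elt an `event_locked_trace`.
#' @return the corrected trace.
#' @export
baseline_correct <- function(elt) {
  pre <- elt$rel_time < 0
  v <- elt$values[pre]
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    stop("invalid event: no valid samples in the pre-event baseline")
  elt$values <- elt$values - mean(v)
  elt
}

traces_matrix <- function(traces) {
  if (length(traces) == 0L) return(NULL)
  t(vapply(traces, function(e) e$values, numeric(length(traces[[1]]$rel_time))))
}

#' Compare synchronized vs desynchronized event groups
#'
#' Per-timepoint unpaired rank-sum test of the SP group against the DP group
#' along the relative time grid, one-sided (SP > DP), with a pointwise
#' significance mask at `alpha` (uncorrected). Group sizes naturally differ,
#' which is why the unpaired test is the well-defined choice. Groups with
#' fewer than two traces give a degenerate no-comparison result.
#'
#' @param sp_traces,dp_traces lists of (baseline-corrected)
#'   `event_locked_trace` objects on a common grid.
#' @param alpha pointwise significance level.
#' @return an object of class `group_comparison`: list with `rel_time`, `p`,
#'   `mask`, `n_sp`, `n_dp`, `alpha`, `degenerate`.
#' @export
compare_groups <- function(sp_traces, dp_traces, alpha = 0.05) {
  n_sp <- length(sp_traces); n_dp <- length(dp_traces)
  if (n_sp == 0L || n_dp == 0L)
    stop("no comparison: a group is empty (n_sp = ", n_sp,
         ", n_dp = ", n_dp, ")")
  rel <- sp_traces[[1]]$rel_time
  if (n_sp < 2L || n_dp < 2L)
    return(structure(list(rel_time = rel, p = NULL, mask = NULL,
                          n_sp = n_sp, n_dp = n_dp, alpha = alpha,
                          degenerate = TRUE),
                     class = "group_comparison"))
  SP <- traces_matrix(sp_traces)
  DP <- traces_matrix(dp_traces)
  p <- vapply(seq_along(rel), function(i)
    suppressWarnings(wilcox.test(SP[, i], DP[, i], alternative = "greater",
                                 exact = FALSE)$p.value), numeric(1))
  structure(list(rel_time = rel, p = p, mask = p < alpha,
                 n_sp = n_sp, n_dp = n_dp, alpha = alpha,
                 degenerate = FALSE),
            class = "group_comparison")
}

#' Earliest sustained significant timepoint
#'
#' Returns the relative time at which the earliest run of at least
#' `min_run` consecutive significant timepoints begins. Pointwise masks at
#' alpha = 0.05 over a 121-point grid produce isolated false positives with
#' near-certainty; a sustained run at the temporal smoothing scale of the
#' 4-s analysis window (plus one) separates a real onset from such noise.
#'
#' @param gc a `group_comparison`.
#' @param min_run minimum consecutive significant points.
#' @return relative time in seconds, or `NA` if no such run exists.
#' @export
earliest_sustained <- function(gc, min_run = 5) {
  if (isTRUE(gc$degenerate) || is.null(gc$mask)) return(NA_real_)
  r <- rle(gc$mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_run)
  if (length(hit) == 0L) return(NA_real_)
  gc$rel_time[starts[hit[1]]]
}

#' Event-locked SP/DP analysis for one dyad
#'
#' Convenience wrapper: builds the dyad's temporal trace at the given
#' channel combination, cuts and baseline-corrects peri-event traces for all
#' assigned SP/DP events in the requested condition, and compares the
#' groups.
#'
#' @param session a `hyperscan_session`.
#' @param dyad,channel_pair,band see [temporal_series()].
#' @param condition performance condition to analyze.
#' @param pre,post peri-event extent (s).
#' @param alpha pointwise level.
#' @return list with `comparison` (a `group_comparison`), `sp`, `dp` (trace
#'   lists) and `events` (the condition assignment table).
#' @export
event_locked_analysis <- function(session, dyad, channel_pair,
                                  band = "gamma",
                                  condition = "active-active",
                                  pre = 60, post = 60, alpha = 0.05) {
  ev <- split_by_condition(session, dyads = list(dyad))
  ev <- ev[!is.na(ev$condition) & ev$condition == condition & !ev$excluded, ,
           drop = FALSE]
  trace <- temporal_series(session, dyad, channel_pair, band)
  cut1 <- function(type) {
    sel <- ev[ev$type == type, , drop = FALSE]
    out <- list()
    for (i in seq_len(nrow(sel))) {
      e <- extract_peri_event(trace, sel$time[i], pre, post,
                              event_type = sel$event_type[i],
                              condition = condition)
      if (!is.null(e)) out[[length(out) + 1L]] <- baseline_correct(e)
    }
    out
  }
  sp <- cut1("SP"); dp <- cut1("DP")
  list(comparison = compare_groups(sp, dp, alpha), sp = sp, dp = dp,
       events = ev)
}
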