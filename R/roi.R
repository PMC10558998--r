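#' The 13 scalp regions of interest
#'
#' Anterior frontal (AF), left/midline/right fronto-central (LFC, MFC, RFC),
#' left/midline/right centro-parietal (LCP, MCP, RCP), left/middle/right
#' parieto-occipital (LPO, MPO, RPO), left/right temporal (LT, RT) and
#' occipital (O).
#'
#' @return character vector of 13 region codes.
#' @export
roi_regions <- function() {
  c("AF", "LFC", "MFC", "RFC", "LCP", "MCP", "RCP",
    "LPO", "MPO", "RPO", "LT", "RT", "O")
}

#' Default electrode-to-region membership table
#'
#' Partitions the 10-20/10-10 montage labels into the 13 regions by
#' geometric scalp sector. Shipped as an editable CSV
#' (`extdata/roi_membership.csv`); pass your own table to override.
#'
#' @param path optional CSV path with columns `label`, `region`.
#' @return data.frame of class `roi_map` with columns `label`, `region`.
#' @export
default_roi_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "roi_membership.csv", package = "hyperbis")
  m <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  if (!all(c("label", "region") %in% names(m)))
    stop("format error: ROI table needs columns label, region")
  bad <- setdiff(unique(m$region), roi_regions())
  if (length(bad) > 0L)
    stop("format error: unknown ROI region '", bad[1], "'")
  if (anyDuplicated(m$label))
    stop("format error: electrode '", m$label[duplicated(m$label)][1],
         "' mapped to more than one region")
  class(m) <- c("roi_map", "data.frame")
  m
}

#' Region of one electrode
#'
#' @param channel_label electrode label.
#' @param roi_map membership table (default [default_roi_map()]).
#' @return region code.
#' @export
assign_roi <- function(channel_label, roi_map = default_roi_map()) {
  i <- match(channel_label, roi_map$label)
  if (any(is.na(i)))
    stop("missing channel: '", channel_label[which(is.na(i))[1]],
         "' not in the ROI membership table")
  roi_map$region[i]
}

#' Aggregate significant combinations into an ROI synchronization map
#'
#' Each significant channel combination increments the cell for (region of
#' chan_a, region of chan_b), pooled across dyads and trials. Between-region
#' counts are pooled symmetrically (undirected); within-region counts sit on
#' the diagonal. Shading is the count normalized by the maximum cell count.
#'
#' @param results a `significance_results` data.frame (see
#'   [scan_combinations()]).
#' @param roi_map membership table.
#' @param condition optional performance condition filter; requires
#'   `session` to derive each row's condition from the design.
#' @param band optional band filter.
#' @param session needed when filtering by condition.
#' @return an object of class `roi_sync_map`: list with `counts` (13 x 13
#'   symmetric matrix; unordered pairs counted once, mirrored for display),
#'   `shading` (`counts / max`), `total`, `condition`, `band`.
#' @export
aggregate_roi <- function(results, roi_map = default_roi_map(),
                          condition = NULL, band = NULL, session = NULL) {
  sig <- results[results$significant, , drop = FALSE]
  if (!is.null(band)) sig <- sig[sig$band %in% band, , drop = FALSE]
  if (!is.null(condition)) {
    if (is.null(session))
      stop("condition filtering requires the session design")
    cond <- vapply(seq_len(nrow(sig)), function(i) {
      dy <- strsplit(sig$dyad[i], "-")[[1]]
      iv <- segment_interval(session, sig$trial[i], sig$segment[i])
      dyad_condition(session, dy, iv[1])
    }, character(1))
    sig <- sig[!is.na(cond) & cond == condition, , drop = FALSE]
  }
  regions <- roi_regions()
  counts <- matrix(0L, 13L, 13L, dimnames = list(regions, regions))
  for (i in seq_len(nrow(sig))) {
    r1 <- match(assign_roi(sig$chan_a[i], roi_map), regions)
    r2 <- match(assign_roi(sig$chan_b[i], roi_map), regions)
    lo <- min(r1, r2); hi <- max(r1, r2)   # unordered pooling
    counts[lo, hi] <- counts[lo, hi] + 1L
  }
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  mx <- max(counts)
  structure(list(counts = counts,
                 shading = if (mx > 0) counts / mx else counts * 0,
                 total = roi_total_from(counts),
                 condition = condition %||% "all", band = band %||% "all"),
            class = "roi_sync_map")
}

roi_total_from <- function(counts) {
  sum(counts[upper.tri(counts, diag = TRUE)])
}

#' Total combinations aggregated in an ROI map
#'
#' Sum over the map's cells (each unordered region pair counted once);
#' equals the number of significant combinations that entered the map.
#'
#' @param map an `roi_sync_map`.
#' @return integer count.
#' @export
roi_total <- function(map) map$total

#' Long-format export of an ROI map
#'
#' @param map an `roi_sync_map`.
#' @return data.frame with `region_a`, `region_b` (unordered pairs,
#'   within-region on `region_a == region_b`), `count`, `shading`.
#' @export
roi_map_to_df <- function(map) {
  regions <- rownames(map$counts)
  idx <- which(upper.tri(map$counts, diag = TRUE), arr.ind = TRUE)
  data.frame(region_a = regions[idx[, 1]], region_b = regions[idx[, 2]],
             count = map$counts[idx], shading = map$shading[idx],
             condition = map$condition, band = map$band,
             stringsAsFactors = FALSE)
}
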