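## Readers reject rather than guess: malformed headers name the offending
## field, truncated payloads abort without returning a partial recording.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width)
    stop("field too wide for EDF header: '", x, "'")
  formatC(x, width = width, flag = "-")
}

## render a number into at most `width` ascii chars, dropping precision as
## needed; returns the string (its parsed value is what the file then means)
num_field <- function(v, width = 8) {
  for (d in 7:1) {
    s <- formatC(signif(v, d), format = "g", digits = d)
    if (nchar(s, type = "bytes") <= width) return(s)
  }
  stop("cannot render ", v, " in ", width, " characters")
}

#' Write a recording as EDF
#'
#' Minimal European Data Format writer (16-bit samples). Channel kind is
#' carried in the per-signal transducer field (`"EOG"` for ocular channels),
#' since EDF has no dedicated kind field and kinds must not be inferred from
#' montage labels. Data are padded with zeros to a whole number of records.
#'
#' @param recording an `eeg_recording`.
#' @param path output file path.
#' @param record_duration data record length in seconds; `fs *
#'   record_duration` must be an integer.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, record_duration = 1) {
  ns <- length(recording$labels)
  spr <- recording$fs * record_duration
  if (abs(spr - round(spr)) > 1e-9)
    stop("fs * record_duration must be an integer sample count")
  spr <- as.integer(round(spr))
  n <- ncol(recording$data)
  n_rec <- as.integer(ceiling(n / spr))
  x <- recording$data
  if (n_rec * spr > n)
    x <- cbind(x, matrix(0, nrow(x), n_rec * spr - n))
  pmin_ <- apply(x, 1L, min)
  pmax_ <- apply(x, 1L, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmax_[flat] <- pmin_[flat] + 1
  ## the header stores limited-precision ascii; use the stored values for
  ## scaling so writer and reader agree exactly
  pmin_s <- vapply(pmin_, num_field, character(1))
  pmax_s <- vapply(pmax_, num_field, character(1))
  pmin_ <- as.numeric(pmin_s)
  pmax_ <- as.numeric(pmax_s)
  over <- x < pmin_[row(x)] ; x[over] <- pmin_[row(x)][over]
  over <- x > pmax_[row(x)] ; x[over] <- pmax_[row(x)][over]
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wc <- function(s) writeChar(s, con, nchars = nchar(s, type = "bytes"),
                              eos = NULL)
  wc(pad_field("0", 8))
  wc(pad_field(recording$participant_id, 80))
  wc(pad_field("hyperbis", 80))
  wc(pad_field("01.01.26", 8))
  wc(pad_field("00.00.00", 8))
  wc(pad_field(256L * (1L + ns), 8))
  wc(pad_field("", 44))
  wc(pad_field(n_rec, 8))
  wc(pad_field(format(record_duration), 8))
  wc(pad_field(ns, 4))
  for (lab in recording$labels) wc(pad_field(lab, 16))
  for (k in recording$kinds) wc(pad_field(k, 80))
  for (i in seq_len(ns)) wc(pad_field("uV", 8))
  for (i in seq_len(ns)) wc(pad_field(pmin_s[i], 8))
  for (i in seq_len(ns)) wc(pad_field(pmax_s[i], 8))
  for (i in seq_len(ns)) wc(pad_field(dmin, 8))
  for (i in seq_len(ns)) wc(pad_field(dmax, 8))
  for (i in seq_len(ns)) wc(pad_field("", 80))
  for (i in seq_len(ns)) wc(pad_field(spr, 8))
  for (i in seq_len(ns)) wc(pad_field("", 32))
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns)) {
      dig <- round((x[i, cols] - pmin_[i]) / scale[i] + dmin)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

edf_num <- function(s, field) {
  v <- suppressWarnings(as.numeric(trimws(s)))
  if (is.na(v)) stop("format error in EDF header field '", field, "': '",
                     trimws(s), "'")
  v
}

read_edf <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 256) stop("format error: file too short for an EDF header")
  con <- file(path, "rb")
  on.exit(close(con))
  rc <- function(k) readChar(con, k, useBytes = TRUE)
  rc(8)                       # version
  patient <- trimws(rc(80))
  rc(80); rc(8); rc(8)
  header_bytes <- edf_num(rc(8), "header bytes")
  rc(44)
  n_rec <- edf_num(rc(8), "number of records")
  rec_dur <- edf_num(rc(8), "record duration")
  ns <- as.integer(edf_num(rc(4), "signal count"))
  if (ns < 1L) stop("format error in EDF header field 'signal count'")
  if (sz < header_bytes) stop("format error: truncated EDF header")
  labels <- trimws(vapply(seq_len(ns), function(i) rc(16), character(1)))
  transducer <- trimws(vapply(seq_len(ns), function(i) rc(80), character(1)))
  vapply(seq_len(ns), function(i) rc(8), character(1))   # phys dim
  pmin_ <- vapply(seq_len(ns), function(i) edf_num(rc(8), "physical minimum"),
                  numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) edf_num(rc(8), "physical maximum"),
                  numeric(1))
  dmin <- vapply(seq_len(ns), function(i) edf_num(rc(8), "digital minimum"),
                 numeric(1))
  dmax <- vapply(seq_len(ns), function(i) edf_num(rc(8), "digital maximum"),
                 numeric(1))
  vapply(seq_len(ns), function(i) rc(80), character(1))  # prefilter
  spr <- vapply(seq_len(ns), function(i)
    as.integer(edf_num(rc(8), "samples per record")), integer(1))
  vapply(seq_len(ns), function(i) rc(32), character(1))
  if (length(unique(spr)) != 1L)
    stop("format error: signals with differing sampling rates are unsupported")
  spr <- spr[1]
  expected <- n_rec * ns * spr
  raw <- readBin(con, "integer", n = expected, size = 2L, endian = "little")
  if (length(raw) < expected)
    stop("format error: truncated EDF data (expected ", expected,
         " samples, found ", length(raw), ")")
  data <- matrix(0, nrow = ns, ncol = n_rec * spr)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  dim(raw) <- c(spr, ns, n_rec)
  for (i in seq_len(ns))
    data[i, ] <- as.vector(raw[, i, ]) * scale[i] + pmin_[i] -
      dmin[i] * scale[i]
  kinds <- ifelse(grepl("EOG", transducer, ignore.case = TRUE), "EOG", "EEG")
  new_recording(data, labels, kinds, fs = spr / rec_dur,
                participant_id = if (nzchar(patient)) patient else "P1")
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `<base>.vhdr`, `<base>.vmrk` and `<base>.eeg` (binary multiplexed
#' IEEE float32). The online reference (if recorded in `meta$reference`) and
#' the EOG channel set are written as `Reference=` / `EOGChannels=` keys in
#' the `[Common Infos]` section -- a writer extension, since the base format
#' has no field for either.
#'
#' @param recording an `eeg_recording`.
#' @param path path of the `.vhdr` file to write.
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(recording, path) {
  if (!grepl("\\.vhdr$", path)) path <- paste0(path, ".vhdr")
  base <- sub("\\.vhdr$", "", basename(path))
  dir <- dirname(path)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", length(recording$labels)),
    paste0("SamplingInterval=", format(1e6 / recording$fs)),
    if (!is.null(recording$meta$reference))
      paste0("Reference=", recording$meta$reference),
    if (any(recording$kinds == "EOG"))
      paste0("EOGChannels=",
             paste(recording$labels[recording$kinds == "EOG"],
                   collapse = ",")),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    vapply(seq_along(recording$labels), function(i)
      sprintf("Ch%d=%s,,1,uV", i, recording$labels[i]), character(1)))
  writeLines(hdr, path)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]", paste0("DataFile=", base, ".eeg"),
               "[Marker Infos]", "Mk1=New Segment,,1,1,0,0"),
             file.path(dir, paste0(base, ".vmrk")))
  con <- file(file.path(dir, paste0(base, ".eeg")), "wb")
  on.exit(close(con))
  writeBin(as.numeric(recording$data), con, size = 4L, endian = "little")
  invisible(path)
}

bv_key <- function(lines, key, required = TRUE) {
  hit <- grep(paste0("^", key, "="), lines, value = TRUE)
  if (length(hit) == 0L) {
    if (required) stop("format error in BrainVision header: missing field '",
                       key, "'")
    return(NULL)
  }
  sub(paste0("^", key, "="), "", hit[1])
}

read_brainvision <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  data_file <- bv_key(lines, "DataFile")
  fmt <- bv_key(lines, "DataFormat")
  if (!identical(fmt, "BINARY"))
    stop("unsupported format: BrainVision DataFormat '", fmt, "'")
  orientation <- bv_key(lines, "DataOrientation")
  if (!orientation %in% c("MULTIPLEXED", "VECTORIZED"))
    stop("format error in BrainVision header: DataOrientation '",
         orientation, "'")
  nch <- suppressWarnings(as.integer(bv_key(lines, "NumberOfChannels")))
  if (is.na(nch) || nch < 1L)
    stop("format error in BrainVision header: NumberOfChannels")
  si <- suppressWarnings(as.numeric(bv_key(lines, "SamplingInterval")))
  if (is.na(si) || si <= 0)
    stop("format error in BrainVision header: SamplingInterval")
  bin_fmt <- bv_key(lines, "BinaryFormat")
  if (!bin_fmt %in% c("IEEE_FLOAT_32", "INT_16"))
    stop("unsupported format: BinaryFormat '", bin_fmt, "'")
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  if (length(ch_lines) != nch)
    stop("format error in BrainVision header: expected ", nch,
         " channel info lines, found ", length(ch_lines))
  ord <- order(as.integer(sub("^Ch([0-9]+)=.*", "\\1", ch_lines)))
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines[ord]), ",")
  labels <- vapply(parts, `[`, character(1), 1L)
  res <- vapply(parts, function(p) {
    r <- if (length(p) >= 3L) suppressWarnings(as.numeric(p[3])) else 1
    if (is.na(r) || !nzchar(if (length(p) >= 3L) p[3] else "")) 1 else r
  }, numeric(1))
  eeg_path <- file.path(dirname(path), data_file)
  if (!file.exists(eeg_path))
    stop("format error: data file '", data_file, "' not found")
  bytes <- if (bin_fmt == "IEEE_FLOAT_32") 4L else 2L
  sz <- file.size(eeg_path)
  if (sz %% (bytes * nch) != 0)
    stop("format error: truncated BrainVision data file")
  n <- sz %/% (bytes * nch)
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  raw <- if (bytes == 4L)
    readBin(con, "numeric", n = n * nch, size = 4L, endian = "little")
  else
    readBin(con, "integer", n = n * nch, size = 2L, endian = "little")
  if (length(raw) < n * nch)
    stop("format error: truncated BrainVision data file")
  data <- if (orientation == "MULTIPLEXED")
    matrix(raw, nrow = nch, ncol = n)
  else
    t(matrix(raw, nrow = n, ncol = nch))
  data <- data * res
  eog <- bv_key(lines, "EOGChannels", required = FALSE)
  kinds <- rep("EEG", nch)
  if (!is.null(eog))
    kinds[labels %in% strsplit(eog, ",")[[1]]] <- "EOG"
  meta <- list()
  ref <- bv_key(lines, "Reference", required = FALSE)
  if (!is.null(ref)) meta$reference <- ref
  new_recording(data, labels, kinds, fs = 1e6 / si, meta = meta)
}

#' Read a multichannel recording
#'
#' @param path file path (`.edf`, or a BrainVision `.vhdr`).
#' @param dialect `"edf"` or `"brainvision"`.
#' @return an `eeg_recording` with labels, kinds, sampling rate and
#'   microvolt-scaled data.
#' @export
read_recording <- function(path, dialect = c("edf", "brainvision")) {
  if (length(dialect) == 1L && !dialect %in% c("edf", "brainvision"))
    stop("unsupported format: dialect '", dialect, "'")
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect, edf = read_edf(path), brainvision = read_brainvision(path))
}

#' Write / read the session container
#'
#' The container is a single serialized file holding all recordings, the
#' design and baseline tables, annotations, mask and provenance; the
#' round-trip is lossless for every field.
#'
#' @param session a `hyperscan_session`.
#' @param path container file path.
#' @return `write_session()`: `path`, invisibly. `read_session()`: the
#'   session.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "hyperscan_session"))
  saveRDS(list(format = "hyperbis_session", version = 1L, payload = session),
          path)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(readRDS(path),
                error = function(e) stop("format error: unreadable container: ",
                                         conditionMessage(e)))
  if (!is.list(x) || !identical(x$format, "hyperbis_session"))
    stop("format error: not a session container")
  if (!identical(x$version, 1L))
    stop("format error: container version mismatch (found ", x$version, ")")
  s <- x$payload
  if (is.null(s$annotations)) {
    warning("container has no annotations block; using an empty list")
    s$annotations <- empty_annotations()
  }
  validate_design(s$design)
  s
}

parse_event_time <- function(s, row = NA) {
  s <- trimws(s)
  where <- if (is.na(row)) "" else paste0(" at row ", row)
  if (grepl("^[0-9]+:[0-5][0-9](\\.[0-9]+)?$", s)) {
    p <- strsplit(s, ":")[[1]]
    return(as.numeric(p[1]) * 60 + as.numeric(p[2]))
  }
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("format error: unparseable time '", s, "'", where)
  v
}

#' Read SP/DP event annotations
#'
#' Expects a CSV with columns `event_type` (codes like `SP_1`, `DP_3`),
#' `time` (either `mm:ss` or plain seconds) and a free-text annotation
#' column (`annotation` or `label`). Times are converted to seconds and file
#' order is preserved. Times in this dialect are anchored to trial start;
#' [annotations_to_session_clock()] converts them via the design table.
#'
#' @param path CSV file path.
#' @return data.frame with columns `event_type`, `type`, `time`, `label`.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  if (!all(c("event_type", "time") %in% names(df)))
    stop("format error: annotation CSV needs columns event_type, time")
  lab <- if ("annotation" %in% names(df)) df$annotation
         else if ("label" %in% names(df)) df$label
         else rep("", nrow(df))
  type <- sub("_.*$", "", trimws(df$event_type))
  bad <- which(!type %in% c("SP", "DP"))
  if (length(bad) > 0L)
    stop("format error: unknown event type '", df$event_type[bad[1]],
         "' at row ", bad[1])
  times <- vapply(seq_len(nrow(df)),
                  function(i) parse_event_time(df$time[i], i), numeric(1))
  data.frame(event_type = trimws(df$event_type), type = type, time = times,
             label = lab, stringsAsFactors = FALSE)
}

#' Convert trial-anchored annotation times to the session clock
#'
#' @param annotations data.frame as returned by [read_annotations()].
#' @param session a `hyperscan_session`.
#' @param trial trial index whose start anchors the annotation times.
#' @return the annotations with `time` on the session clock.
#' @export
annotations_to_session_clock <- function(annotations, session, trial) {
  d <- session$design[session$design$trial == trial, ]
  if (nrow(d) == 0L) stop("no such trial: ", trial)
  annotations$time <- annotations$time + min(d$start)
  annotations
}

#' Export a session's annotations in the trial-anchored mm:ss dialect
#'
#' @param session a `hyperscan_session`.
#' @param trial trial index; only events inside this trial's span are
#'   exported, with times relative to trial start.
#' @return data.frame with columns `event_type`, `time` (mm:ss), `annotation`.
#' @export
annotations_table <- function(session, trial) {
  d <- session$design[session$design$trial == trial, ]
  if (nrow(d) == 0L) stop("no such trial: ", trial)
  t0 <- min(d$start); t1 <- max(d$end)
  a <- session$annotations
  a <- a[a$time >= t0 & a$time < t1, , drop = FALSE]
  rel <- round(a$time - t0)
  data.frame(event_type = a$event_type,
             time = sprintf("%d:%02d", rel %/% 60, rel %% 60),
             annotation = a$label, stringsAsFactors = FALSE)
}
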