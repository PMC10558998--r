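#' Construct a multichannel EEG/EOG recording
#'
#' A recording holds one participant's time-aligned data block: a channels x
#' samples matrix in microvolts, the montage labels, the per-channel kind
#' (`"EEG"` or `"EOG"` -- kinds are metadata, never inferred from labels,
#' because caps may repurpose scalp positions for ocular electrodes), the
#' sampling rate and the start time on the session clock (seconds, 0-based).
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param labels character vector of unique channel labels (one per row).
#' @param kinds character vector, `"EEG"` or `"EOG"` per channel. Defaults to
#'   all-EEG.
#' @param fs sampling frequency in Hz (> 0).
#' @param participant_id participant label.
#' @param start_time recording start on the session clock, in seconds.
#' @param meta named list of free-form metadata (e.g. `reference`).
#' @return an object of class `eeg_recording`.
#' @export
new_recording <- function(data, labels, kinds = NULL, fs,
                          participant_id = "P1", start_time = 0,
                          meta = list()) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (length(labels) != nrow(data))
    stop("label count (", length(labels), ") does not match data rows (",
         nrow(data), ")")
  if (anyDuplicated(labels))
    stop("channel labels must be unique")
  if (is.null(kinds)) kinds <- rep("EEG", length(labels))
  if (length(kinds) != length(labels) || !all(kinds %in% c("EEG", "EOG")))
    stop("`kinds` must be 'EEG' or 'EOG', one per channel")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  rownames(data) <- labels
  structure(
    list(participant_id = participant_id,
         labels = as.character(labels),
         kinds = as.character(kinds),
         fs = as.numeric(fs),
         data = data,
         start_time = as.numeric(start_time),
         meta = meta),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels (%d EEG, %d EOG), %.1f s @ %g Hz\n",
              x$participant_id, length(x$labels),
              sum(x$kinds == "EEG"), sum(x$kinds == "EOG"),
              ncol(x$data) / x$fs, x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return duration in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Extract one channel's samples by label
#' @param rec an `eeg_recording`.
#' @param channel channel label.
#' @return numeric vector of samples.
#' @export
rec_channel <- function(rec, channel) {
  i <- match(channel, rec$labels)
  if (is.na(i)) stop("missing channel: '", channel, "' not in recording ",
                     rec$participant_id)
  rec$data[i, ]
}

#' Labels of analysis (EEG-kind) channels
#' @param rec an `eeg_recording`.
#' @return character vector of labels with kind `"EEG"`.
#' @export
eeg_channels <- function(rec) rec$labels[rec$kinds == "EEG"]

#' Labels of ocular (EOG-kind) channels
#' @param rec an `eeg_recording`.
#' @return character vector of labels with kind `"EOG"`.
#' @export
eog_channels <- function(rec) rec$labels[rec$kinds == "EOG"]

#' Standard 64-channel actiCAP montage labels
#'
#' The 64 recorded positions of the 10-20/10-10 extended actiCAP layout with
#' FCz as (unrecorded) online reference. Four of these positions (`TP9`,
#' `TP10`, `PO9`, `PO10`) are conventionally repurposed as EOG electrodes in
#' mobile setups, leaving 60 scalp analysis channels.
#' @return character vector of 64 labels.
#' @export
acticap64_labels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10",
    "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
    "FT9", "FT7", "FC3", "FC4", "FT8", "FT10",
    "C5", "C1", "C2", "C6", "TP7", "CP3", "CPz", "CP4", "TP8",
    "P5", "P1", "P2", "P6", "PO7", "PO3", "POz", "PO4", "PO8")
}

#' Default EOG-repurposed channel labels
#'
#' `TP9`/`TP10` sit on the temples (horizontal eye movement) and `PO9`/`PO10`
#' above and below the right eye (vertical movement / blinks) in the emulated
#' setup.
#' @return character vector of 4 labels.
#' @export
default_eog_labels <- function() c("TP9", "TP10", "PO9", "PO10")

#' A 16-channel desk-scale montage profile
#'
#' Subset of the 64-channel montage spanning most scalp regions; intended for
#' reduced-size simulation studies where full 60-channel scans are
#' unnecessarily heavy.
#' @return character vector of 16 labels.
#' @export
desk16_labels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "Cz", "T7", "T8",
    "P3", "P4", "Pz", "P7", "P8", "O1", "O2")
}
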