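# Reading and writing single-channel EEG segments in the Bonn ASCII dialect
# (one amplitude per line) and assembling labelled datasets from a manifest.

BONN_FS <- 173.61
BONN_SEGMENT_LENGTH <- 4097L

#' Construct an EEG segment
#'
#' A segment is a fixed-length single-channel amplitude series (nominally in
#' microvolts) with sampling-rate metadata and an optional class label. The
#' Bonn corpus uses segments of 4097 samples at 173.61 Hz (about 23.6 s).
#'
#' @param samples numeric vector of amplitudes, length >= 2, all finite.
#' @param fs sampling rate in Hz (> 0). Default 173.61, the Bonn rate.
#' @param segment_id character identifier.
#' @param label class tag (e.g. one of `"A"`..`"E"` for Bonn subsets, or
#'   `"normal"`/`"ictal"` for synthetic data); `NA` if unlabelled.
#' @return an object of class `eeg_segment`.
#' @export
#' @examples
#' s <- eeg_segment(sin(seq(0, 10, length.out = 256)), fs = 100, label = "normal")
#' s
eeg_segment <- function(samples, fs = BONN_FS, segment_id = "segment",
                        label = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop_validation("a segment needs at least 2 samples")
  if (!all(is.finite(samples))) stop_validation("all samples must be finite")
  assert_number(fs, "fs", lower = .Machine$double.eps)
  structure(list(samples = samples, fs = fs,
                 segment_id = as.character(segment_id),
                 label = as.character(label)),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment '%s'> %d samples @ %.2f Hz (%.1f s)%s\n",
              x$segment_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (is.na(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

#' Read a Bonn-dialect EEG segment file
#'
#' Parses an ASCII file with one amplitude per line (blank lines ignored,
#' integer and decimal tokens accepted).
#'
#' @param path file path.
#' @param expected_length if non-`NULL`, the file must contain exactly this
#'   many samples (dialect check); the Bonn files have 4097.
#' @param fs sampling rate recorded in the segment metadata.
#' @param segment_id identifier; defaults to the file name without extension.
#' @param label optional class tag.
#' @return an [eeg_segment()].
#' @export
read_segment <- function(path, expected_length = NULL, fs = BONN_FS,
                         segment_id = NULL, label = NA_character_) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad <- keep[which(is.na(vals))[1L]]
    stop_validation(sprintf("non-numeric value at line %d of '%s': '%s'",
                            bad, path, lines[bad]))
  }
  if (!is.null(expected_length) && length(vals) != expected_length)
    stop_validation(sprintf(
      "dialect error: '%s' has %d samples, expected %d",
      path, length(vals), as.integer(expected_length)))
  if (is.null(segment_id))
    segment_id <- sub("\\.[^.]*$", "", basename(path))
  eeg_segment(vals, fs = fs, segment_id = segment_id, label = label)
}

#' Write an EEG segment in the Bonn ASCII dialect
#'
#' One sample per line; integer amplitudes are written without a decimal
#' point, real amplitudes with full precision so that a write/read round-trip
#' is lossless.
#'
#' @param segment an [eeg_segment()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_segment <- function(segment, path) {
  stopifnot(inherits(segment, "eeg_segment"))
  v <- segment$samples
  txt <- ifelse(v == round(v), sprintf("%.0f", v), sprintf("%.17g", v))
  writeLines(txt, path)
  invisible(path)
}

#' Construct a labelled EEG dataset
#'
#' @param segments list of [eeg_segment()]s, each with exactly one non-`NA`
#'   label; all segments must have the same length.
#' @return an object of class `eeg_dataset` with a `class_index` mapping each
#'   label to the segment ids carrying it (manifest/input order preserved).
#' @export
eeg_dataset <- function(segments) {
  stopifnot(is.list(segments))
  if (length(segments)) {
    ok <- vapply(segments, inherits, logical(1), "eeg_segment")
    if (!all(ok)) stop_validation("all elements must be eeg_segment objects")
    labs <- vapply(segments, function(s) s$label, character(1))
    if (anyNA(labs)) stop_validation("every segment must carry a label")
    lens <- vapply(segments, function(s) length(s$samples), integer(1))
    if (length(unique(lens)) != 1L)
      stop_validation("dialect error: mixed segment lengths ",
                      paste(unique(lens), collapse = ", "))
    ids <- vapply(segments, function(s) s$segment_id, character(1))
    class_index <- split(ids, labs)
  } else {
    class_index <- list()
  }
  structure(list(segments = segments, class_index = class_index),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("<eeg_dataset> %d segments", length(x$segments)))
  if (length(x$class_index)) {
    cnt <- vapply(x$class_index, length, integer(1))
    cat(": ", paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Segment labels of a dataset
#' @param dataset an [eeg_dataset()].
#' @return character vector of per-segment labels, in dataset order.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$segments, function(s) s$label, character(1))
}

#' Load a labelled dataset from a manifest
#'
#' @param manifest data frame with columns `path` and `label`, or the path of
#'   a CSV file with those columns.
#' @param labels optional declared label set; labels outside it are rejected.
#' @param expected_length per-file length check passed to [read_segment()]
#'   (`NULL` disables it; equal lengths across files are always enforced).
#' @param fs sampling rate for the loaded segments.
#' @return an [eeg_dataset()]. Duplicate paths are loaded twice and receive
#'   distinct segment ids.
#' @export
load_labeled_dataset <- function(manifest, labels = NULL,
                                 expected_length = NULL, fs = BONN_FS) {
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(manifest)))
    stop_validation("manifest needs 'path' and 'label' columns")
  if (nrow(manifest) == 0L) return(eeg_dataset(list()))
  if (!is.null(labels) && !all(manifest$label %in% labels))
    stop_validation("unknown label(s): ",
                    paste(setdiff(manifest$label, labels), collapse = ", "))
  ids <- make.unique(sub("\\.[^.]*$", "", basename(manifest$path)), sep = "_")
  segs <- lapply(seq_len(nrow(manifest)), function(i)
    read_segment(manifest$path[i], expected_length = expected_length, fs = fs,
                 segment_id = ids[i], label = manifest$label[i]))
  eeg_dataset(segs)
}

#' Write a dataset as Bonn-dialect files plus a manifest
#'
#' @param dataset an [eeg_dataset()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly. A `manifest.csv` with columns
#'   `path,label` is written next to the segment files.
#' @export
export_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset$segments, function(s) {
    p <- file.path(dir, paste0(s$segment_id, ".txt"))
    write_segment(s, p)
    data.frame(path = p, label = s$label, stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  write.csv(man, mp, row.names = FALSE)
  invisible(mp)
}
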