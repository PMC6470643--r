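#' Read a recording from a delimited-text matrix plus sidecar
#'
#' The matrix file holds one channel per row, samples in columns, whitespace
#' or tab delimited. The plain-text sidecar supplies the metadata the matrix
#' cannot carry, as `key=value` lines with keys `fs` (required, Hz),
#' `labels` (comma-separated channel names), `subject_id` and `label`
#' (0/1 class).
#'
#' @param path path to the matrix file.
#' @param metaPath path to the sidecar; default `<path>.meta`.
#' @return An [EEGRecording-class].
#' @seealso [writeRecording()]
#' @export
readRecording <- function(path, metaPath = paste0(path, ".meta")) {
  if (!file.exists(path)) stop("matrix file does not exist: ", path)
  if (!file.exists(metaPath)) {
    stop("sidecar file does not exist: ", metaPath,
         " (required: the matrix format cannot carry the sampling rate)")
  }
  meta <- readSidecar(metaPath)
  if (is.null(meta$fs)) stop("sidecar ", metaPath, " is missing the 'fs' key")
  dat <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(dat) <- NULL
  labels <- if (!is.null(meta$labels)) {
    trimws(strsplit(meta$labels, ",")[[1L]])
  } else {
    paste0("ch", seq_len(nrow(dat)))
  }
  if (length(labels) != nrow(dat)) {
    stop(sprintf(
      "sidecar lists %d channel labels but the matrix has %d rows",
      length(labels), nrow(dat)
    ))
  }
  EEGRecording(
    data = dat, fs = as.numeric(meta$fs), channelLabels = labels,
    subjectId = if (is.null(meta$subject_id)) basename(path) else meta$subject_id,
    label = if (is.null(meta$label)) NA else as.integer(meta$label)
  )
}

readSidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) == 2L) out[[trimws(p[[1L]])]] <- trimws(p[[2L]])
  }
  out
}

#' Write a recording as delimited text plus sidecar
#'
#' @param rec an [EEGRecording-class].
#' @param path output matrix path; the sidecar is written to `<path>.meta`.
#' @param digits significant digits kept in the text matrix.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, digits = 8) {
  utils::write.table(
    signif(rec@data, digits), path,
    row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  meta <- c(
    sprintf("fs=%.10g", rec@fs),
    sprintf("labels=%s", paste(rec@channelLabels, collapse = ",")),
    sprintf("subject_id=%s", rec@subjectId)
  )
  if (!is.na(rec@label)) meta <- c(meta, sprintf("label=%d", rec@label))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Write a cohort of recordings with a manifest
#'
#' Writes one matrix + sidecar pair per subject and a tab-separated
#' `manifest.tsv` (subject_id, label, fs, n_channels, file).
#'
#' @param recordings list of [EEGRecording-class] objects.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeCohort <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(recordings, function(rec) {
    file <- paste0(rec@subjectId, ".tsv")
    writeRecording(rec, file.path(dir, file))
    data.frame(
      subject_id = rec@subjectId, label = rec@label, fs = rec@fs,
      n_channels = nrow(rec@data), file = file, stringsAsFactors = FALSE
    )
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' Read a cohort previously written with [writeCohort()]
#'
#' @param dir directory containing `manifest.tsv`.
#' @return A list of [EEGRecording-class] objects, in manifest order.
#' @export
readCohort <- function(dir) {
  mp <- file.path(dir, "manifest.tsv")
  if (!file.exists(mp)) stop("no manifest.tsv in ", dir)
  manifest <- utils::read.table(mp, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    readRecording(file.path(dir, manifest$file[i]))
  })
}
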