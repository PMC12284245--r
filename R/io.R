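# Text-based interchange: BrainVision (ASCII data format) recordings,
# CSV study/connectivity tables, JSON processing logs.

#' Write a recording as BrainVision (ASCII data format)
#'
#' Writes the `.vhdr` header, `.vmrk` marker file and a multiplexed ASCII
#' `.dat` data file (values in microvolts).
#'
#' @param rec an `eeg_recording`
#' @param basename path without extension
#' @return invisibly, the header path
#' @export
write_brainvision <- function(rec, basename) {
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  dat <- paste0(basename, ".dat")
  nm <- basename(basename)
  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "", "[Common Infos]",
    paste0("DataFile=", nm, ".dat"),
    paste0("MarkerFile=", nm, ".vmrk"),
    "DataFormat=ASCII",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$sfreq, scientific = FALSE)),
    "", "[ASCII Infos]", "DecimalSymbol=.", "SkipLines=0", "SkipColumns=0",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_along(rec$labels), rec$labels))
  writeLines(hdr, vhdr)
  writeLines(c("BrainVision Data Exchange Marker File, Version 1.0",
               "", "[Common Infos]", paste0("DataFile=", nm, ".dat"),
               "", "[Marker Infos]",
               "Mk1=New Segment,,1,1,0"), vmrk)
  utils::write.table(format(t(rec$data) * 1e6, digits = 8, trim = TRUE),
                     dat, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(vhdr)
}

#' Read a BrainVision (ASCII data format) recording
#'
#' @param vhdr path to the `.vhdr` header
#' @param roles optional channel roles (default: `eog_v`/`eog_h` inferred
#'   from VEOG/HEOG labels, `eeg` otherwise)
#' @return an `eeg_recording`
#' @export
read_brainvision <- function(vhdr, roles = NULL) {
  lines <- readLines(vhdr)
  get1 <- function(key) {
    v <- grep(paste0("^", key, "="), lines, value = TRUE)[1L]
    sub(paste0("^", key, "="), "", v)
  }
  if (!identical(get1("DataFormat"), "ASCII"))
    stop("only the ASCII data format is supported")
  sfreq <- 1e6 / as.numeric(get1("SamplingInterval"))
  chlines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", chlines), ","),
                   `[[`, character(1L), 1L)
  datfile <- file.path(dirname(vhdr), get1("DataFile"))
  x <- unname(as.matrix(utils::read.table(datfile)))
  if (is.null(roles))
    roles <- ifelse(labels == "VEOG", "eog_v",
                    ifelse(labels == "HEOG", "eog_h", "eeg"))
  structure(list(data = t(x) / 1e6, sfreq = sfreq, labels = labels,
                 roles = roles, bad = character(0),
                 log = list(stages = "read")),
            class = "eeg_recording")
}

#' Write / read a study table as CSV
#'
#' @param table a `study_table`
#' @param path CSV path
#' @export
write_study_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("study_table", "data.frame")
  out
}

#' Write a processing log as JSON
#'
#' @param rec an `eeg_recording` (its `log` is written) or a plain list
#' @param path output path
#' @export
write_processing_log <- function(rec, path) {
  log <- if (inherits(rec, "eeg_recording")) rec$log else rec
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
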