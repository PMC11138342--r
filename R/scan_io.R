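#' @importFrom stats median sd cor pt rnorm rpois rbinom rgeom rlnorm runif
#' @importFrom utils head tail
NULL

#' Canonical DiFC channel table
#'
#' A two-color DiFC scan always carries four photodetector channels: two fiber
#' probes (1 and 2, separated along the blood vessel) times two emission bands
#' (green for GFP, orange for tdTomato).
#'
#' @return A data.frame with columns `channel`, `probe` (1 or 2) and `color`
#'   ("green" or "orange"), one row per channel in canonical order.
#' @export
difc_channels <- function() {
  data.frame(
    channel = c("p1_green", "p1_orange", "p2_green", "p2_orange"),
    probe = c(1L, 1L, 2L, 2L),
    color = c("green", "orange", "green", "orange"),
    stringsAsFactors = FALSE
  )
}

.difc_colors <- c("green", "orange")
.difc_classifications <- c("single_1FP", "cluster_1FP", "cluster_2FP",
                           "indeterminate")
.difc_flags <- c("saturated", "artifact")

#' Construct a DiFC scan object
#'
#' A scan is a uniformly sampled four-channel fluorescence time series in mV
#' (PMT output) plus probe geometry. Time is implicit: sample `i` is at
#' `(i - 1) / sampling_rate` seconds.
#'
#' @param signal data.frame or matrix with numeric columns `p1_green`,
#'   `p1_orange`, `p2_green`, `p2_orange` (mV per sample). All columns must
#'   have equal length.
#' @param sampling_rate samples per second (> 0).
#' @param probe_separation distance between the two fiber probes along the
#'   vessel, in mm (default 3).
#' @param metadata named list of free-form scan metadata (scan id, subject id,
#'   scenario tag, ...).
#' @return An object of class `difc_scan`.
#' @export
difc_scan <- function(signal, sampling_rate, probe_separation = 3,
                      metadata = list()) {
  signal <- as.data.frame(signal)
  chans <- difc_channels()$channel
  missing <- setdiff(chans, names(signal))
  if (length(missing) > 0) {
    stop("scan signal is missing channel(s): ", paste(missing, collapse = ", "))
  }
  signal <- signal[chans]
  for (ch in chans) {
    if (!is.numeric(signal[[ch]])) stop("channel ", ch, " is not numeric")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a positive scalar")
  }
  if (!is.numeric(probe_separation) || length(probe_separation) != 1 ||
      probe_separation <= 0) {
    stop("probe_separation must be a positive scalar (mm)")
  }
  structure(
    list(
      signal = signal,
      sampling_rate = as.numeric(sampling_rate),
      probe_separation = as.numeric(probe_separation),
      metadata = metadata
    ),
    class = "difc_scan"
  )
}

#' @export
print.difc_scan <- function(x, ...) {
  n <- nrow(x$signal)
  cat(sprintf(
    "difc_scan: %d samples x 4 channels, %.1f s at %g Hz, probes %g mm apart\n",
    n, n / x$sampling_rate, x$sampling_rate, x$probe_separation
  ))
  if (length(x$metadata) > 0) {
    cat("metadata:", paste(names(x$metadata), unlist(x$metadata),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Scan duration in seconds
#' @param scan a `difc_scan`.
#' @return duration in seconds (`n_samples / sampling_rate`).
#' @export
scan_duration <- function(scan) {
  stopifnot(inherits(scan, "difc_scan"))
  nrow(scan$signal) / scan$sampling_rate
}

#' Time base of a scan
#' @param scan a `difc_scan`.
#' @return numeric vector of sample times in seconds.
#' @export
scan_times <- function(scan) {
  stopifnot(inherits(scan, "difc_scan"))
  (seq_len(nrow(scan$signal)) - 1) / scan$sampling_rate
}

# serialize doubles losslessly (17 significant digits round-trips IEEE754)
.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a scan to a columnar text file
#'
#' The format is a comma-separated table with header
#' `time_s,p1_green_mV,p1_orange_mV,p2_green_mV,p2_orange_mV`, preceded by a
#' `# key: value` metadata block carrying `sampling_rate`,
#' `probe_separation_mm` and any scalar metadata entries. Values are written
#' with 17 significant digits so the round trip through [read_scan()] is
#' lossless.
#'
#' @param scan a valid `difc_scan`; signals containing NA/NaN/Inf are refused.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "difc_scan"))
  for (ch in names(scan$signal)) {
    if (anyNA(scan$signal[[ch]]) || any(!is.finite(scan$signal[[ch]]))) {
      stop("channel ", ch, " contains non-finite samples; refusing to write")
    }
  }
  meta <- c(
    list(difc_scan_format = "1",
         sampling_rate = scan$sampling_rate,
         probe_separation_mm = scan$probe_separation),
    scan$metadata
  )
  hdr <- vapply(names(meta), function(k) {
    sprintf("# %s: %s", k, as.character(meta[[k]]))
  }, character(1))
  n <- nrow(scan$signal)
  cols <- c("time_s", "p1_green_mV", "p1_orange_mV", "p2_green_mV",
            "p2_orange_mV")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(cols, collapse = ","), con)
  if (n > 0) {
    t <- (seq_len(n) - 1) / scan$sampling_rate
    body <- paste(.fmt_num(t),
                  .fmt_num(scan$signal$p1_green),
                  .fmt_num(scan$signal$p1_orange),
                  .fmt_num(scan$signal$p2_green),
                  .fmt_num(scan$signal$p2_orange),
                  sep = ",")
    writeLines(body, con)
  }
  invisible(path)
}

.read_meta_block <- function(path) {
  meta <- list()
  n_meta <- 0L
  con <- file(path, open = "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0) break
    if (!startsWith(line, "#")) break
    n_meta <- n_meta + 1L
    kv <- sub("^#\\s*", "", line)
    sep <- regexpr(":", kv, fixed = TRUE)
    if (sep > 0) {
      key <- trimws(substr(kv, 1, sep - 1))
      val <- trimws(substr(kv, sep + 1, nchar(kv)))
      meta[[key]] <- val
    }
  }
  list(meta = meta, skip = n_meta)
}

#' Read a scan written by [write_scan()]
#'
#' All four channels must be present. `sampling_rate` defaults to 2000
#' samples/s and `probe_separation_mm` to 3 mm when the metadata block does
#' not state them. If a `time_s` column is present it is validated against
#' the implicit index/`sampling_rate` time base; deviations beyond one sample
#' period are a format error.
#'
#' @param path file path.
#' @param default_sampling_rate sampling rate (Hz) assumed when the file does
#'   not declare one.
#' @return a `difc_scan`.
#' @export
read_scan <- function(path, default_sampling_rate = 2000) {
  if (!file.exists(path)) stop("no such file: ", path)
  mb <- .read_meta_block(path)
  tab <- data.table::fread(path, skip = mb$skip, header = TRUE,
                           sep = ",", data.table = FALSE,
                           colClasses = "numeric")
  col_map <- c(p1_green = "p1_green_mV", p1_orange = "p1_orange_mV",
               p2_green = "p2_green_mV", p2_orange = "p2_orange_mV")
  missing <- col_map[!(col_map %in% names(tab))]
  if (length(missing) > 0) {
    stop("scan file is missing channel column(s): ",
         paste(missing, collapse = ", "))
  }
  fs <- if (!is.null(mb$meta$sampling_rate)) {
    as.numeric(mb$meta$sampling_rate)
  } else {
    default_sampling_rate
  }
  sep_mm <- if (!is.null(mb$meta$probe_separation_mm)) {
    as.numeric(mb$meta$probe_separation_mm)
  } else {
    3
  }
  if ("time_s" %in% names(tab) && nrow(tab) > 0) {
    expected <- (seq_len(nrow(tab)) - 1) / fs
    if (max(abs(tab$time_s - expected)) > 1 / fs) {
      stop("time_s column is not uniform at the declared sampling rate")
    }
  }
  sig <- data.frame(
    p1_green = tab$p1_green_mV, p1_orange = tab$p1_orange_mV,
    p2_green = tab$p2_green_mV, p2_orange = tab$p2_orange_mV
  )
  meta <- mb$meta
  meta$difc_scan_format <- NULL
  meta$sampling_rate <- NULL
  meta$probe_separation_mm <- NULL
  difc_scan(sig, sampling_rate = fs, probe_separation = sep_mm,
            metadata = meta)
}

#' Write a detection-record table
#'
#' Detection records are the pipeline's final per-event output: time, color,
#' direction, amplitudes (mV and noise-sigma units), width, 1FP/2FP
#' classification, estimated per-color cell counts and curation flags.
#' Flags are serialized as a semicolon-joined set (e.g. `"saturated"` or
#' `"saturated;artifact"`, empty when unflagged).
#'
#' @param records data.frame of detection records (see [read_detections()]
#'   for the column set).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(records, path) {
  records <- as.data.frame(records)
  cols <- c("time_s", "color", "direction", "amplitude_mV", "amplitude_sigma",
            "width_s", "classification", "n_green", "n_orange", "flags")
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0) {
    stop("detection table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- !(records$classification %in% .difc_classifications)
  if (any(bad)) {
    stop("unknown classification label(s): ",
         paste(unique(records$classification[bad]), collapse = ", "))
  }
  out <- records[cols]
  for (nc in c("time_s", "amplitude_mV", "amplitude_sigma", "width_s")) {
    out[[nc]] <- .fmt_num(out[[nc]])
  }
  data.table::fwrite(out, path, sep = ",", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a detection-record table written by [write_detections()]
#'
#' @param path file path.
#' @return data.frame with columns `time_s`, `color`, `direction`,
#'   `amplitude_mV`, `amplitude_sigma`, `width_s`, `classification`,
#'   `n_green`, `n_orange`, `flags`.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- data.table::fread(path, sep = ",", header = TRUE,
                           data.table = FALSE, na.strings = "NA",
                           colClasses = list(character = "flags"))
  tab$flags <- as.character(tab$flags)
  tab$flags[is.na(tab$flags)] <- ""
  bad <- !(tab$classification %in% .difc_classifications)
  if (any(bad)) {
    stop("unknown classification label(s): ",
         paste(unique(tab$classification[bad]), collapse = ", "))
  }
  flag_tokens <- unlist(strsplit(tab$flags[nzchar(tab$flags)], ";",
                                 fixed = TRUE))
  if (length(flag_tokens) > 0 && !all(flag_tokens %in% .difc_flags)) {
    stop("unknown flag label(s): ",
         paste(setdiff(unique(flag_tokens), .difc_flags), collapse = ", "))
  }
  tab
}

#' Load a structured configuration file
#'
#' Reads a YAML key/value document of pipeline and simulator settings
#' (window lengths, detection threshold, matching tolerances, bleed ratios,
#' reference amplitudes, saturation limit, ...). Returned as a named list;
#' pass entries to the corresponding functions.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_difc_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must contain a key/value mapping")
  cfg
}
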