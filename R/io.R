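#' Construct a multi-channel EEG recording
#'
#' The basic continuous-data container: a channels x samples matrix in
#' microvolts, its sampling rate, channel labels, and event markers
#' (1-based sample indices with an event type, `"keypress"` for the healthy
#' finger-tapping paradigm or `"cue"` for the stroke hand-grasp paradigm).
#'
#' @param signal channels x samples numeric matrix (microvolts).
#' @param fs Sampling rate, Hz.
#' @param labels Channel names, one per row of `signal`.
#' @param events `data.frame` with columns `sample` (1-based index) and
#'   `type`; may have zero rows.
#' @param subject_id,hand,cohort Metadata strings; `cohort` is `"healthy"`
#'   or `"stroke"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs, labels,
                          events = data.frame(sample = integer(), type = character()),
                          subject_id = "s00", hand = "right",
                          cohort = c("healthy", "stroke")) {
  cohort <- match.arg(cohort)
  signal <- as.matrix(signal)
  if (length(labels) != nrow(signal))
    stop("length(labels) must equal the channel count (rows of signal)")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  events <- as.data.frame(events)
  if (nrow(events)) {
    if (!all(c("sample", "type") %in% names(events)))
      stop("events needs columns 'sample' and 'type'")
    if (any(events$sample < 1) || any(events$sample > ncol(signal)))
      stop("event sample indices must lie within the recording")
    events <- events[order(events$sample), , drop = FALSE]
    events$sample <- as.integer(events$sample)
    events$type <- as.character(events$type)
    rownames(events) <- NULL
  } else {
    events <- data.frame(sample = integer(), type = character())
  }
  rownames(signal) <- labels
  structure(list(signal = signal, fs = fs, labels = labels, events = events,
                 subject_id = subject_id, hand = hand, cohort = cohort),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", x$subject_id, "/", x$hand, " (", x$cohort, "): ",
      nrow(x$signal), " ch x ", ncol(x$signal), " samples @ ", x$fs, " Hz, ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$signal)

# ---- EDF --------------------------------------------------------------------

# Event markers travel in an extra 'Events' signal holding integer codes at
# event samples (1 = keypress, 2 = cue). EDF stores whole 1 s records, so the
# true sample count is kept in the reserved header field as 'NSAMP=<n>'.
event_codes <- c(keypress = 1, cue = 2)

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to disk
#'
#' `format = "edf"` writes a valid EDF file (16-bit samples, 1 s records);
#' `format = "matrix"` writes a plain TSV signal matrix (samples x channels)
#' with a JSON sidecar header (`<path>.json`) - a convenient dialect for
#' tests and inspection.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @param format `"edf"` or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("edf", "matrix")) {
  format <- match.arg(format)
  if (format == "matrix") return(write_recording_matrix(rec, path))
  sig <- rec$signal
  ns <- nrow(sig)
  n <- ncol(sig)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n_rec <- as.integer(ceiling(n / fs))
  npad <- n_rec * fs - n

  ev <- numeric(n)
  if (nrow(rec$events)) {
    code <- event_codes[rec$events$type]
    if (anyNA(code)) stop("unknown event type in recording")
    ev[rec$events$sample] <- code
  }
  data <- rbind(sig, Events = ev)
  labels <- c(rec$labels, "Events")
  if (npad > 0) data <- cbind(data, matrix(0, nrow(data), npad))

  # physical scaling per signal: symmetric range covering the data
  pmax_ <- pmax(apply(abs(data), 1, max), 1)
  pmax_ <- ceiling(pmax_)
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  nsig <- ns + 1L
  header_bytes <- 256L * (1L + nsig)
  wr <- function(x, width) writeChar(pad_field(x, width), con, width, eos = NULL)
  wr("0", 8)
  wr(paste(rec$subject_id, rec$hand, rec$cohort), 80)
  wr("hotspotEEG recording", 80)
  wr("01.01.00", 8)   # fixed start date/time: outputs are byte-reproducible
  wr("00.00.00", 8)
  wr(header_bytes, 8)
  wr(paste0("NSAMP=", n), 44)
  wr(n_rec, 8)
  wr("1", 8)          # record duration, seconds
  wr(nsig, 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(nsig)) wr("", 80)                     # transducer
  for (i in seq_len(nsig)) wr(if (i <= ns) "uV" else "", 8)
  for (i in seq_len(nsig)) wr(format(-pmax_[i]), 8)       # physical min
  for (i in seq_len(nsig)) wr(format(pmax_[i]), 8)        # physical max
  for (i in seq_len(nsig)) wr(-dig_max, 8)
  for (i in seq_len(nsig)) wr(dig_max, 8)
  for (i in seq_len(nsig)) wr("", 80)                     # prefilter
  for (i in seq_len(nsig)) wr(fs, 8)                      # samples per record
  for (i in seq_len(nsig)) wr("", 32)

  dig <- round(data / pmax_ * dig_max)  # rows scaled by their own range
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols])), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' Counterpart of [write_recording()]. Reading an EDF file without an
#' `Events` signal yields a recording with zero events and a warning.
#'
#' @param path File path.
#' @param format `"edf"` or `"matrix"`.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("edf", "matrix")) {
  format <- match.arg(format)
  if (format == "matrix") return(read_recording_matrix(path))
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file (bad version field): ", path)
  patient <- rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nsig <- as.integer(rd(4))
  if (is.na(nsig) || nsig < 1) stop("malformed EDF header: number of signals")
  labels <- vapply(seq_len(nsig), function(i) rd(16), character(1))
  for (i in seq_len(nsig)) rd(80)
  for (i in seq_len(nsig)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(nsig), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(nsig), function(i) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(nsig), function(i) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(nsig), function(i) rd(8), character(1)))
  if (anyNA(c(pmin_, pmax_, dmin_, dmax_)))
    stop("malformed EDF header: physical/digital ranges")
  for (i in seq_len(nsig)) rd(80)
  spr <- as.integer(vapply(seq_len(nsig), function(i) rd(8), character(1)))
  for (i in seq_len(nsig)) rd(32)
  if (length(unique(spr)) != 1)
    stop("malformed EDF: differing samples-per-record across signals")
  fs <- spr[1] / dur

  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                 endian = "little")
  data <- matrix(NA_real_, nsig, n_rec * spr[1])
  off <- 0L
  for (r in seq_len(n_rec)) {
    block <- matrix(raw[(off + 1):(off + nsig * spr[1])], nrow = spr[1])
    data[, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <- t(block)
    off <- off + nsig * spr[1]
  }
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  data <- data * scale + (pmax_ - dmax_ * scale)

  nsamp <- n_rec * spr[1]
  m <- regmatches(reserved, regexpr("NSAMP=[0-9]+", reserved))
  if (length(m)) nsamp <- as.integer(sub("NSAMP=", "", m))
  data <- data[, seq_len(nsamp), drop = FALSE]

  meta <- strsplit(patient, " +")[[1]]
  subject_id <- if (length(meta) >= 1) meta[1] else "s00"
  hand <- if (length(meta) >= 2) meta[2] else "right"
  cohort <- if (length(meta) >= 3 && meta[3] %in% c("healthy", "stroke"))
    meta[3] else "healthy"

  iev <- which(labels == "Events")
  if (length(iev) == 1) {
    code <- round(data[iev, ])
    at <- which(code != 0)
    events <- data.frame(
      sample = at,
      type = names(event_codes)[match(code[at], event_codes)]
    )
    data <- data[-iev, , drop = FALSE]
    labels <- labels[-iev]
  } else {
    warning("no 'Events' signal in ", path, "; recording has empty events")
    events <- data.frame(sample = integer(), type = character())
  }
  eeg_recording(data, fs, labels, events, subject_id, hand, cohort)
}

# ---- plain matrix + JSON sidecar -------------------------------------------

write_recording_matrix <- function(rec, path) {
  utils::write.table(
    t(rec$signal), path, sep = "\t", row.names = FALSE,
    col.names = rec$labels, quote = FALSE
  )
  meta <- list(fs = rec$fs, labels = rec$labels,
               events = rec$events, subject_id = rec$subject_id,
               hand = rec$hand, cohort = rec$cohort,
               n_samples = ncol(rec$signal))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_recording_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing JSON sidecar header: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("fs", "labels")) if (is.null(meta[[f]]))
    stop("malformed sidecar header (missing field '", f, "'): ", side)
  x <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  events <- if (is.null(meta$events) || length(meta$events) == 0)
    data.frame(sample = integer(), type = character())
  else as.data.frame(meta$events)
  eeg_recording(t(x), meta$fs, meta$labels, events,
                meta$subject_id %||% "s00", meta$hand %||% "right",
                meta$cohort %||% "healthy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- hotspot locations ------------------------------------------------------

#' A motor-hotspot location in the Cz-origin head frame
#'
#' Coordinates are millimetres; +x right, +y nasion, +z up. The hemisphere
#' is inferred from the sign of x (x < 0 is the left hemisphere, the
#' convention used throughout the package).
#'
#' @param x,y,z Coordinates in mm.
#' @param source `"tms_ground_truth"`, `"predicted"`, or `"synthetic_truth"`.
#' @param head_radius Used to validate that the point is on or near the
#'   scalp over the motor region.
#' @return An object of class `hotspot_location`.
#' @export
hotspot_location <- function(x, y, z,
                             source = c("tms_ground_truth", "predicted",
                                        "synthetic_truth"),
                             head_radius = 90) {
  source <- match.arg(source)
  x <- unname(x); y <- unname(y); z <- unname(z)
  if (!all(is.finite(c(x, y, z)))) stop("hotspot coordinates must be finite")
  # scalp points reach sqrt(2) * R from the Cz origin at ear level
  if (sqrt(x^2 + y^2 + z^2) > 1.05 * sqrt(2) * head_radius)
    stop("hotspot location implausibly far from the vertex")
  structure(list(x = x, y = y, z = z,
                 hemisphere = if (x < 0) "left" else "right",
                 source = source),
            class = "hotspot_location")
}

#' @export
print.hotspot_location <- function(x, ...) {
  cat(sprintf("<hotspot_location> (%.1f, %.1f, %.1f) mm, %s hemisphere [%s]\n",
              x$x, x$y, x$z, x$hemisphere, x$source))
  invisible(x)
}

as_coord <- function(p) {
  if (inherits(p, "hotspot_location")) c(p$x, p$y, p$z)
  else {
    p <- as.numeric(p)
    if (length(p) != 3) stop("expected a 3-vector or hotspot_location")
    p
  }
}

#' Read / write a ground-truth hotspot table
#'
#' CSV with columns `subject_id`, `hand`, `x_mm`, `y_mm`, `z_mm` and an
#' optional `source` column, one row per subject and hand.
#'
#' @param path CSV path.
#' @return `read_hotspot_table()` returns a `data.frame` with columns
#'   `subject_id`, `hand`, `x_mm`, `y_mm`, `z_mm`, `hemisphere`, `source`.
#' @export
read_hotspot_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "hand", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("hotspot table is missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("x_mm", "y_mm", "z_mm")) {
    v <- d[[col]]
    if (is.character(v) || is.factor(v)) {
      vn <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("non-numeric coordinate in column '", col, "' at row ", bad[1])
      d[[col]] <- vn
    }
    if (anyNA(d[[col]]))
      stop("non-numeric coordinate in column '", col, "' at row ",
           which(is.na(d[[col]]))[1])
  }
  d$hemisphere <- ifelse(d$x_mm < 0, "left", "right")
  if (is.null(d$source)) d$source <- rep("tms_ground_truth", nrow(d))
  d[c("subject_id", "hand", "x_mm", "y_mm", "z_mm", "hemisphere", "source")]
}

#' @rdname read_hotspot_table
#' @param table A data.frame as returned by `read_hotspot_table()`.
#' @export
write_hotspot_table <- function(table, path) {
  cols <- c("subject_id", "hand", "x_mm", "y_mm", "z_mm", "source")
  cols <- intersect(cols, names(table))
  utils::write.csv(table[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
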