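# Minimal EDF (European Data Format) support: plain continuous recordings,
# 16-bit samples, no annotations. Reading covers what polysomnographic EEG
# exports typically contain; writing exists so synthetic fixtures and
# round-trip tests can be built in code.

edf_field <- function(raw, offset, width) {
  trimws(rawToChar(raw[(offset + 1):(offset + width)]))
}

read_edf_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readBin(con, "raw", 256L)
  if (length(fixed) < 256L) stop("not an EDF file (truncated header): ", path,
                                 call. = FALSE)
  ns <- as.integer(edf_field(fixed, 252, 4))
  if (is.na(ns) || ns < 1L) stop("not an EDF file (bad signal count): ", path,
                                 call. = FALSE)
  n_records <- as.integer(edf_field(fixed, 236, 8))
  record_duration <- as.numeric(edf_field(fixed, 244, 8))
  sig <- readBin(con, "raw", 256L * ns)
  # per-signal blocks are stored field-by-field, each field contiguous
  off <- 0L
  take <- function(width) {
    out <- vapply(seq_len(ns) - 1L,
                  function(i) edf_field(sig, off + i * width, width),
                  character(1))
    off <<- off + ns * width
    out
  }
  labels <- take(16L)
  take(80L)                      # transducer
  dims <- take(8L)
  phys_min <- as.numeric(take(8L))
  phys_max <- as.numeric(take(8L))
  dig_min <- as.numeric(take(8L))
  dig_max <- as.numeric(take(8L))
  take(80L)                      # prefiltering
  spr <- as.integer(take(8L))
  take(32L)                      # reserved
  list(ns = ns, n_records = n_records, record_duration = record_duration,
       labels = labels, dims = dims,
       phys_min = phys_min, phys_max = phys_max,
       dig_min = dig_min, dig_max = dig_max,
       samples_per_record = spr)
}

read_edf_signal <- function(path, channel = NULL, label = basename(path)) {
  h <- read_edf_header(path)
  if (is.null(channel)) {
    if (h$ns > 1L) {
      stop("EDF file has ", h$ns, " channels; pick one of: ",
           paste(h$labels, collapse = ", "), call. = FALSE)
    }
    idx <- 1L
  } else {
    idx <- match(channel, h$labels)
    if (is.na(idx)) {
      stop("channel '", channel, "' not found; available: ",
           paste(h$labels, collapse = ", "), call. = FALSE)
    }
  }
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 256L + 256L * h$ns)
  rec_len <- sum(h$samples_per_record)
  raw16 <- readBin(con, "integer", n = rec_len * h$n_records, size = 2L,
                   signed = TRUE, endian = "little")
  if (length(raw16) < rec_len * h$n_records) {
    stop("EDF data area shorter than the header promises: ", path,
         call. = FALSE)
  }
  offsets <- c(0L, cumsum(h$samples_per_record))
  spr <- h$samples_per_record[idx]
  pick <- unlist(lapply(seq_len(h$n_records) - 1L, function(r) {
    r * rec_len + offsets[idx] + seq_len(spr)
  }))
  dig <- raw16[pick]
  gain <- (h$phys_max[idx] - h$phys_min[idx]) / (h$dig_max[idx] - h$dig_min[idx])
  phys <- h$phys_min[idx] + (dig - h$dig_min[idx]) * gain
  fs <- spr / h$record_duration
  signal(phys, fs, label = sprintf("%s:%s", label, h$labels[idx]))
}

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

# shortest numeric representation that fits an 8-character EDF field
edf_num <- function(x) {
  for (d in 7:1) {
    s <- sprintf("%.*g", d, x)
    if (nchar(s) <= 8L) return(s)
  }
  substr(sprintf("%g", x), 1L, 8L)
}

#' Write a single-channel EDF file (synthetic fixtures)
#'
#' Writes a minimal, standard-conforming EDF recording with one channel and
#' one-second data records, quantized to 16-bit over the sample range. The
#' sampling rate must therefore be a positive integer and the signal is
#' truncated to a whole number of seconds. Intended for building synthetic
#' test recordings, not for clinical data export.
#'
#' @param x a [signal()] with integer `sampling_rate_hz`.
#' @param path output file.
#' @param channel_label EDF channel label (max 16 characters).
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, path, channel_label = "EEG synth") {
  if (!inherits(x, "seq_signal")) stop("`x` must be a seq_signal", call. = FALSE)
  fs <- x$sampling_rate_hz
  if (fs != round(fs) || fs < 1) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(fs)
  n_records <- length(x$samples) %/% fs
  if (n_records < 1L) stop("signal shorter than one data record", call. = FALSE)
  v <- x$samples[seq_len(n_records * fs)]
  # store the header-representable (8-char) bounds and scale against those,
  # so reading back inverts the quantization exactly
  phys_min <- as.numeric(edf_num(min(v))); phys_max <- as.numeric(edf_num(max(v)))
  if (phys_max <= phys_min) phys_max <- phys_min + 1
  dig_min <- -32768L; dig_max <- 32767L
  dig <- as.integer(round((v - phys_min) / (phys_max - phys_min) *
                            (dig_max - dig_min) + dig_min))
  dig <- pmin(pmax(dig, dig_min), dig_max)
  header <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad(paste("Startdate 01-JAN-2000", x$label), 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256L + 256L, 8),
    edf_pad("", 44),
    edf_pad(n_records, 8),
    edf_pad("1", 8),
    edf_pad("1", 4),
    edf_pad(channel_label, 16),
    edf_pad("", 80),
    edf_pad("uV", 8),
    edf_pad(edf_num(phys_min), 8),
    edf_pad(edf_num(phys_max), 8),
    edf_pad(dig_min, 8),
    edf_pad(dig_max, 8),
    edf_pad("", 80),
    edf_pad(fs, 8),
    edf_pad("", 32)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}
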