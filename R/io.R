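#' Read a signal from a text, CSV or EDF file
#'
#' Text inputs are one column (sample values) or two columns (time in
#' seconds, value); lines starting with `#` are treated as comments, and a
#' comment of the form `# sampling_rate_hz=128` (as written by
#' [write_signal()]) supplies the rate for one-column files. Two-column
#' files derive the rate from the time spacing. A rate given via
#' `sampling_rate_hz` always wins; a one-column file with no embedded rate
#' and no override is refused, because the length-frequency mapping is
#' meaningless without it. EDF files carry their rate in the header.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"csv"`, `"txt"` or `"edf"`.
#' @param sampling_rate_hz optional rate override for text formats.
#' @param channel EDF channel label; may be omitted for single-channel files.
#' @param label label for the returned signal; defaults to the file name.
#' @return A [signal()].
#' @export
read_signal <- function(path, format = c("auto", "csv", "txt", "edf"),
                        sampling_rate_hz = NULL, channel = NULL,
                        label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", csv = "csv", "txt")
  }
  if (format == "edf") {
    return(read_edf_signal(path, channel = channel, label = label))
  }
  sep <- if (format == "csv") "," else ""
  lines <- readLines(path, warn = FALSE)
  comments <- grep("^\\s*#", lines, value = TRUE)
  body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(body_idx) == 0L) stop("no data lines in ", path, call. = FALSE)
  header_rate <- parse_rate_comment(comments)

  body <- lines[body_idx]
  # optional single header line of column names
  first_fields <- strsplit(trimws(body[1L]),
                           if (format == "csv") "," else "\\s+")[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(first_fields)))
  df <- utils::read.table(text = body, header = has_header, sep = sep,
                          strip.white = TRUE)
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(df[[j]])))))[1L]
      stop("non-numeric value in ", path, " at data line ",
           bad + has_header, call. = FALSE)
    }
  }
  nf <- which(rowSums(!is.finite(as.matrix(df))) > 0)
  if (length(nf) > 0L) {
    stop("non-finite value in ", path, " at data line ", nf[1L] + has_header,
         call. = FALSE)
  }
  if (ncol(df) >= 2L) {
    t <- df[[1L]]; v <- df[[2L]]
    dts <- diff(t)
    if (any(dts <= 0) || (max(dts) - min(dts)) > 1e-6 * stats::median(dts)) {
      stop("time column in ", path, " is not uniformly increasing", call. = FALSE)
    }
    fs <- if (!is.null(sampling_rate_hz)) sampling_rate_hz else 1 / stats::median(dts)
  } else {
    v <- df[[1L]]
    fs <- if (!is.null(sampling_rate_hz)) sampling_rate_hz else header_rate
    if (is.null(fs)) {
      stop("no sampling rate: ", path, " has a single column and no ",
           "'# sampling_rate_hz=' header; pass `sampling_rate_hz` (--fs)",
           call. = FALSE)
    }
  }
  signal(v, fs, label = label)
}

parse_rate_comment <- function(comments) {
  m <- regmatches(comments,
                  regexpr("sampling_rate_hz\\s*=\\s*[0-9.eE+-]+", comments))
  if (length(m) == 0L) return(NULL)
  as.numeric(sub(".*=\\s*", "", m[[1L]]))
}

#' Write a signal as plain text
#'
#' Either two tab-separated columns (time in seconds, value) or a single
#' value column; both carry a `# sampling_rate_hz=` comment so that
#' [read_signal()] can restore the rate.
#'
#' @param x a [signal()].
#' @param path output file.
#' @param columns `"two"` (time, value; default) or `"one"` (values only).
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path, columns = c("two", "one")) {
  if (!inherits(x, "seq_signal")) stop("`x` must be a seq_signal", call. = FALSE)
  columns <- match.arg(columns)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# label=%s", x$label), con)
  writeLines(sprintf("# sampling_rate_hz=%.15g", x$sampling_rate_hz), con)
  if (columns == "two") {
    t <- (seq_along(x$samples) - 1) / x$sampling_rate_hz
    writeLines(sprintf("%.15g\t%.15g", t, x$samples), con)
  } else {
    writeLines(sprintf("%.15g", x$samples), con)
  }
  invisible(path)
}

#' Write a sequential spectrum to TSV or JSON
#'
#' TSV has columns `symbol`, `N`, `L`, `occupancy`, `frequency_hz` (the last
#' empty when no sampling rate is known), symbol-0 rows before symbol-1 rows
#' and `N` ascending, so outputs diff cleanly. JSON mirrors the
#' `seq_spectrum` fields at full precision.
#'
#' @param spectrum a `seq_spectrum`.
#' @param path output file.
#' @param format `"tsv"` or `"json"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @seealso [read_spectrum()]
#' @export
write_spectrum <- function(spectrum, path, format = c("auto", "tsv", "json")) {
  if (!inherits(spectrum, "seq_spectrum")) {
    stop("`spectrum` must be a seq_spectrum", call. = FALSE)
  }
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  }
  fs <- attr(spectrum, "sampling_rate_hz") %||% NA_real_
  lab <- attr(spectrum, "label") %||% ""
  I <- attr(spectrum, "source_length_I") %||% 0L
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# label=%s", lab), con)
    writeLines(sprintf("# source_length_I=%d", as.integer(I)), con)
    if (is.finite(fs)) writeLines(sprintf("# sampling_rate_hz=%.15g", fs), con)
    writeLines("symbol\tN\tL\toccupancy\tfrequency_hz", con)
    if (nrow(spectrum) > 0L) {
      freq <- if (is.finite(fs)) sprintf("%.15g", length_to_frequency(spectrum$length, fs)) else ""
      writeLines(sprintf("%d\t%d\t%d\t%.15g\t%s",
                         spectrum$symbol, spectrum$length, spectrum$count,
                         spectrum$occupancy, freq), con)
    }
  } else {
    obj <- list(
      label = lab,
      source_length_I = I,
      sampling_rate_hz = if (is.finite(fs)) fs else NULL,
      entries = data.frame(symbol = spectrum$symbol, length = spectrum$length,
                           count = spectrum$count, occupancy = spectrum$occupancy)
    )
    # I(17) significant digits: doubles survive the round trip bit-exactly
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         dataframe = "columns")
  }
  invisible(path)
}

#' Read a sequential spectrum written by [write_spectrum()]
#'
#' @param path file to read.
#' @param format `"auto"`, `"tsv"` or `"json"`.
#' @return A `seq_spectrum` data frame.
#' @export
read_spectrum <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    tab <- as.data.frame(obj$entries)
    fs <- if (!is.null(obj$sampling_rate_hz)) obj$sampling_rate_hz else NA_real_
    I <- obj$source_length_I
    lab <- obj$label
  } else {
    lines <- readLines(path, warn = FALSE)
    comments <- grep("^#", lines, value = TRUE)
    fs <- parse_rate_comment(comments)
    fs <- if (is.null(fs)) NA_real_ else fs
    Im <- regmatches(comments, regexpr("source_length_I\\s*=\\s*[0-9]+", comments))
    I <- if (length(Im)) as.integer(sub(".*=", "", Im[[1L]])) else NA_integer_
    labm <- grep("^# label=", comments, value = TRUE)
    lab <- if (length(labm)) sub("^# label=", "", labm[[1L]]) else ""
    tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                             sep = "\t", fill = TRUE)
    names(tab)[names(tab) == "N"] <- "length"
    names(tab)[names(tab) == "L"] <- "count"
    tab <- tab[, c("symbol", "length", "count", "occupancy"), drop = FALSE]
  }
  if (nrow(tab) > 0L && is.finite(fs)) {
    tab$frequency_hz <- length_to_frequency(tab$length, fs)
  }
  structure(tab,
            source_length_I = I,
            sampling_rate_hz = fs,
            label = lab,
            class = c("seq_spectrum", "data.frame"))
}

#' Write a seq-spectrogram as a long-format TSV
#'
#' Columns: `frame_start`, `symbol`, `N`, `occupancy`.
#'
#' @param spectrogram a `seq_spectrogram` from [compute_spectrogram()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrogram <- function(spectrogram, path) {
  if (!inherits(spectrogram, "seq_spectrogram")) {
    stop("`spectrogram` must be a seq_spectrogram", call. = FALSE)
  }
  df <- as.data.frame(spectrogram)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# window_length_samples=%d", spectrogram$window_length_samples), con)
  writeLines(sprintf("# step_samples=%d", spectrogram$step_samples), con)
  writeLines("frame_start\tsymbol\tN\toccupancy", con)
  writeLines(sprintf("%d\t%d\t%d\t%.15g",
                     df$frame_start, df$symbol, df$length, df$occupancy), con)
  invisible(path)
}
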