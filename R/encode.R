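#' Encode a signal as a binary symbol series
#'
#' The first differences of the series are mapped onto the alphabet \{0, 1\}:
#' symbol 1 where the signal does not decrease (`x[i+1] >= x[i]`), symbol 0
#' where it decreases. Ties (constant stretches) are deliberately assigned
#' symbol 1, so a constant signal encodes as all ones. The resulting symbol
#' series `P` has one symbol per difference, i.e. length `I = n - 1`.
#'
#' @param x a [signal()] object or a bare numeric vector of samples.
#' @param epsilon non-negative tie tolerance: differences greater than
#'   `-epsilon` are treated as non-decreasing. The default 0 performs exact
#'   floating-point comparison; any positive value acts as an explicit
#'   smoothing parameter and is never applied silently.
#' @return An integer vector of 0/1 symbols with class `symbol_series`.
#' @examples
#' encode_signal(c(1, 2, 3, 2, 1))   # 1 1 0 0
#' encode_signal(c(5, 5, 5))         # ties encode as 1 1
#' @seealso [extract_mono_sequences()], [seq_spectrum()]
#' @export
encode_signal <- function(x, epsilon = 0) {
  samples <- signal_samples(x)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon < 0) {
    stop("`epsilon` must be a single non-negative number", call. = FALSE)
  }
  d <- diff(samples)
  structure(as.integer(d >= -epsilon), class = "symbol_series")
}

#' @export
print.symbol_series <- function(x, ...) {
  n <- length(x)
  shown <- paste(utils::head(unclass(x), 40L), collapse = "")
  cat(sprintf("<symbol_series> I = %d: %s%s\n", n, shown,
              if (n > 40L) "..." else ""))
  invisible(x)
}

# coerce/validate a 0/1 series (symbol_series or plain vector)
validate_symbols <- function(series) {
  sym <- as.integer(unclass(series))
  if (length(sym) == 0L) {
    stop("symbol series is empty", call. = FALSE)
  }
  if (anyNA(sym) || !all(sym %in% c(0L, 1L))) {
    stop("symbol series must contain only 0 and 1", call. = FALSE)
  }
  sym
}

#' Count maximal mono-sequences of a symbol series
#'
#' A mono-sequence `[N x s]` is a maximal run of `N` identical symbols `s`
#' within the binary series `P`; maximality means it can be extended in
#' neither direction, so consecutive runs alternate symbols and every symbol
#' belongs to exactly one run. The cardinalities `L[N x s]` therefore satisfy
#' the exact conservation identity `sum(N * L) == I`.
#'
#' @param series a `symbol_series` (or plain 0/1 vector), non-empty.
#' @return An object of class `mono_counts`: a list with
#'   \describe{
#'     \item{table}{data frame `(symbol, length, count)` of run cardinalities,}
#'     \item{runs}{data frame `(symbol, length)` of the runs in series order
#'       (kept so the series can be reconstructed exactly),}
#'     \item{source_length_I}{the symbol-series length `I`.}
#'   }
#' @examples
#' extract_mono_sequences(encode_signal(c(1, 2, 3, 2, 1)))
#' @export
extract_mono_sequences <- function(series) {
  sym <- validate_symbols(series)
  r <- rle(sym)
  runs <- data.frame(symbol = r$values, length = r$lengths)
  tab <- stats::aggregate(
    list(count = rep(1L, nrow(runs))),
    by = list(symbol = runs$symbol, length = runs$length),
    FUN = sum
  )
  tab <- tab[order(tab$symbol, tab$length), , drop = FALSE]
  rownames(tab) <- NULL
  structure(
    list(table = tab, runs = runs, source_length_I = length(sym)),
    class = "mono_counts"
  )
}

#' @export
print.mono_counts <- function(x, ...) {
  cat(sprintf("<mono_counts> I = %d, %d maximal runs, %d distinct [N x s]\n",
              x$source_length_I, nrow(x$runs), nrow(x$table)))
  print(x$table)
  invisible(x)
}

#' Rebuild a symbol series from an ordered run list
#'
#' Inverse of the run decomposition: concatenating the runs in order
#' reproduces the original series exactly. Mainly used to verify that
#' [extract_mono_sequences()] partitions the series without loss.
#'
#' @param runs a `mono_counts` object (its `runs` field is used) or a data
#'   frame with columns `symbol` and `length` in series order. An empty run
#'   list yields an empty series.
#' @return A `symbol_series`.
#' @examples
#' reconstruct_symbols(data.frame(symbol = c(1, 0), length = c(3, 2)))
#' @export
reconstruct_symbols <- function(runs) {
  if (inherits(runs, "mono_counts")) runs <- runs$runs
  if (!is.data.frame(runs) || !all(c("symbol", "length") %in% names(runs))) {
    stop("`runs` must be a mono_counts object or a data frame with ",
         "columns `symbol` and `length`", call. = FALSE)
  }
  if (nrow(runs) == 0L) {
    return(structure(integer(0), class = "symbol_series"))
  }
  if (!all(runs$symbol %in% c(0L, 1L)) || any(runs$length < 1L)) {
    stop("runs must have symbols in {0,1} and positive lengths", call. = FALSE)
  }
  structure(rep(as.integer(runs$symbol), runs$length), class = "symbol_series")
}
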