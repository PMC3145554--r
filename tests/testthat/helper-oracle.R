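# Independent oracles kept deliberately naive: a character-by-character run
# scan and a literal occupancy formula, against which the package's
# rle-based pipeline is checked.

naive_runs <- function(sym) {
  sym <- as.integer(sym)
  out_sym <- integer(0)
  out_len <- integer(0)
  cur <- sym[1L]
  len <- 0L
  for (s in sym) {
    if (s == cur) {
      len <- len + 1L
    } else {
      out_sym <- c(out_sym, cur)
      out_len <- c(out_len, len)
      cur <- s
      len <- 1L
    }
  }
  data.frame(symbol = c(out_sym, cur), length = c(out_len, len))
}

naive_count_table <- function(sym) {
  runs <- naive_runs(sym)
  key <- paste(runs$symbol, runs$length)
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " "))
  out <- data.frame(symbol = as.integer(parts[, 1]),
                    length = as.integer(parts[, 2]),
                    count = as.integer(tab))
  out[order(out$symbol, out$length), ]
}

random_symbol_series <- function(n) {
  structure(sample(c(0L, 1L), n, replace = TRUE), class = "symbol_series")
}

# the worked 33-symbol example series used across tests
worked_series <- function() {
  structure(
    as.integer(c(1,1,1,0,0,0,1,1,1,1,0,0,1,1,1,0,0,0,0,
                 1,1,1,1,1,1,0,0,0,0,0,0,0,0)),
    class = "symbol_series"
  )
}

occupancy_of <- function(spectrum, sym, len) {
  rows <- spectrum$symbol == sym & spectrum$length == len
  if (!any(rows)) 0 else sum(spectrum$occupancy[rows])
}
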