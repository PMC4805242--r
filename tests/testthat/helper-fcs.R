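# Byte-level FCS writer used to create read-back fixtures at test time.
# Written directly from the FCS header/TEXT/DATA layout, independently of
# the package's reader.

write_fcs_fixture <- function(path, values, channels,
                              version = "FCS3.0",
                              datatype = c("F", "I", "D"),
                              endian = c("little", "big")) {
  datatype <- match.arg(datatype)
  endian <- match.arg(endian)
  values <- as.matrix(values)
  n <- nrow(values); d <- ncol(values)
  bits <- switch(datatype, F = 32L, D = 64L, I = 16L)
  byteord <- if (endian == "little") "1,2,3,4" else "4,3,2,1"

  kv <- c("$DATATYPE", datatype, "$MODE", "L", "$BYTEORD", byteord,
          "$PAR", as.character(d), "$TOT", as.character(n),
          "$NEXTDATA", "0")
  for (j in seq_len(d)) {
    kv <- c(kv,
            paste0("$P", j, "B"), as.character(bits),
            paste0("$P", j, "N"), channels[j],
            paste0("$P", j, "E"), "0,0",
            paste0("$P", j, "R"), "262144")
  }
  text <- paste0("/", paste(kv, collapse = "/"), "/")
  text_start <- 58L
  text_end <- text_start + nchar(text) - 1L
  data_start <- text_end + 1L
  data_end <- data_start + n * d * (bits / 8L) - 1L
  header <- sprintf("%-10s%8d%8d%8d%8d%8d%8d", version, text_start,
                    text_end, data_start, data_end, 0L, 0L)
  stopifnot(nchar(header) == 58L)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  flat <- as.vector(t(values)) # event-interleaved
  if (datatype == "I") {
    writeBin(as.integer(round(flat)), con, size = 2L, endian = endian)
  } else {
    writeBin(as.numeric(flat), con, size = bits / 8L, endian = endian)
  }
  invisible(path)
}
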