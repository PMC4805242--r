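#' Read cytometry events from an FCS or delimited text file
#'
#' Supports FCS 2.0/3.0/3.1 list-mode files (integer, float or double data
#' segments, either byte order) and delimited text tables (comma or tab
#' separated) with a mandatory header row of channel names. No fluorescence
#' compensation is applied.
#'
#' @param path Path to the file.
#' @param format `"auto"` (sniff the FCS magic bytes), `"fcs"` or
#'   `"delimited"`.
#' @return An [event_matrix()] with `transform_tag = "none"`, rows in file
#'   order.
#' @export
read_events <- function(path, format = c("auto", "fcs", "delimited")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file",
                               call. = FALSE)
  if (file.size(path) == 0)
    stop("degenerate input: '", path, "' is empty", call. = FALSE)
  if (format == "auto") {
    magic <- readBin(path, "raw", n = 3L)
    format <- if (identical(rawToChar(magic), "FCS")) "fcs" else "delimited"
  }
  if (format == "fcs") read_fcs(path) else read_delimited(path)
}

read_delimited <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(first))
    stop("degenerate input: '", path, "' has no header row", call. = FALSE)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "")
  if (nrow(df) == 0L)
    stop("degenerate input: '", path, "' contains a header but no events",
         call. = FALSE)
  if (!all(vapply(df, is.numeric, logical(1L))))
    stop("non-numeric values in event table '", path, "'", call. = FALSE)
  event_matrix(as.matrix(df), channels = names(df))
}

#' Write an event matrix to a delimited text file
#'
#' @param events An [event_matrix()].
#' @param path Output path; a `.tsv`/`.txt` extension selects tab separation,
#'   anything else comma.
#' @param sep Optional explicit separator overriding the extension rule.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, sep = NULL) {
  events <- as_event_matrix(events)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(as.data.frame(unclass(events)), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Minimal FCS list-mode reader (versions 2.0/3.0/3.1). The HEADER carries
# ASCII byte offsets of the TEXT segment; TEXT is a delimited keyword/value
# list; the DATA segment layout is given by $DATATYPE, $BYTEORD, $PAR, $TOT
# and the per-parameter $PnB bit widths.
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS2.0", "FCS3.0", "FCS3.1"))
    stop("unsupported FCS version '", version, "' in '", path, "'",
         call. = FALSE)
  off <- function(i) {
    s <- substr(header, 11L + (i - 1L) * 8L, 10L + i * 8L)
    suppressWarnings(as.numeric(trimws(s)))
  }
  text_start <- off(1); text_end <- off(2)
  data_start <- off(3); data_end <- off(4)
  if (is.na(text_start) || is.na(text_end) || text_end <= text_start)
    stop("malformed FCS header in '", path, "'", call. = FALSE)

  seek(con, text_start)
  txt <- readChar(con, text_end - text_start + 1L, useBytes = TRUE)
  delim <- substr(txt, 1L, 1L)
  parts <- strsplit(substring(txt, 2L), delim, fixed = TRUE)[[1L]]
  parts <- parts[seq_len(length(parts) - length(parts) %% 2L)]
  kw <- trimws(parts[seq(2L, length(parts), by = 2L)])
  names(kw) <- toupper(trimws(parts[seq(1L, length(parts), by = 2L)]))

  need <- function(k) {
    if (is.na(kw[k])) stop("FCS file missing required keyword ", k,
                           call. = FALSE)
    kw[[k]]
  }
  npar <- as.integer(need("$PAR"))
  ntot <- as.numeric(need("$TOT"))
  if (is.na(ntot) || ntot < 1)
    stop("degenerate input: FCS file reports 0 events", call. = FALSE)
  dtype <- toupper(need("$DATATYPE"))
  mode <- toupper(need("$MODE"))
  if (mode != "L")
    stop("only list-mode ($MODE L) FCS data is supported", call. = FALSE)
  byteord <- gsub("[^0-9,]", "", need("$BYTEORD"))
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little" else "big"
  bits <- vapply(seq_len(npar), function(i)
    as.integer(kw[[paste0("$P", i, "B")]]), integer(1L))
  chan <- vapply(seq_len(npar), function(i) {
    nm <- kw[paste0("$P", i, "N")]
    if (is.na(nm)) paste0("P", i) else nm
  }, character(1L))
  if (anyDuplicated(chan)) chan <- make.unique(chan, sep = "_")

  # FCS 3.x may keep 0 in the header and the real offsets in TEXT
  if (is.na(data_start) || data_start == 0)
    data_start <- as.numeric(need("$BEGINDATA"))
  if (is.na(data_end) || data_end == 0)
    data_end <- as.numeric(need("$ENDDATA"))

  nvals <- as.integer(ntot) * npar
  seek(con, data_start)
  vals <- switch(dtype,
    F = {
      if (any(bits != 32L)) stop("$DATATYPE F requires 32-bit parameters",
                                 call. = FALSE)
      readBin(con, "double", n = nvals, size = 4L, endian = endian)
    },
    D = {
      if (any(bits != 64L)) stop("$DATATYPE D requires 64-bit parameters",
                                 call. = FALSE)
      readBin(con, "double", n = nvals, size = 8L, endian = endian)
    },
    I = read_fcs_int(con, nvals, npar, bits, endian),
    stop("unsupported $DATATYPE '", dtype, "'", call. = FALSE))
  if (length(vals) < nvals)
    stop("truncated FCS data segment in '", path, "'", call. = FALSE)
  m <- matrix(vals, ncol = npar, byrow = TRUE)
  event_matrix(m, channels = chan)
}

read_fcs_int <- function(con, nvals, npar, bits, endian) {
  if (length(unique(bits)) == 1L) {
    size <- bits[1L] / 8L
    if (!size %in% c(1, 2, 4))
      stop("unsupported integer width ", bits[1L], " bits", call. = FALSE)
    v <- readBin(con, "integer", n = nvals, size = size,
                 signed = size == 4, endian = endian)
    if (size == 4 && any(v < 0)) v[v < 0] <- v[v < 0] + 2^32
    as.numeric(v)
  } else {
    # mixed widths: read event-interleaved, column by column from raw bytes
    bytes_per_event <- sum(bits) / 8L
    raw <- readBin(con, "raw", n = as.integer(nvals / npar * bytes_per_event))
    offs <- c(0L, cumsum(bits / 8L))
    nev <- length(raw) %/% bytes_per_event
    out <- matrix(0, nev, npar)
    for (j in seq_len(npar)) {
      size <- bits[j] / 8L
      idx <- outer(seq_len(size), (seq_len(nev) - 1L) * bytes_per_event +
                     offs[j], "+")
      col <- readBin(raw[as.vector(idx)], "integer", n = nev, size = size,
                     signed = size == 4, endian = endian)
      if (size == 4 && any(col < 0)) col[col < 0] <- col[col < 0] + 2^32
      out[, j] <- col
    }
    as.vector(t(out))
  }
}

#' Define a rectangular gate
#'
#' A rectangular gate is a set of closed intervals `[lower, upper]` on a
#' subset of channels; an event passes when it lies inside every interval
#' (boundary values are inside).
#'
#' @param ... Named length-2 numeric vectors, e.g.
#'   `rect_gate(CD63 = c(0, 5), FSC = c(100, 1e5))`.
#' @return An object of class `rect_gate`.
#' @export
rect_gate <- function(...) {
  iv <- list(...)
  if (length(iv) == 1L && is.list(iv[[1L]]) && !is.null(names(iv[[1L]])))
    iv <- iv[[1L]]
  if (length(iv) == 0L || is.null(names(iv)) || any(!nzchar(names(iv))))
    stop("rect_gate needs named channel intervals", call. = FALSE)
  for (ch in names(iv)) {
    v <- as.numeric(iv[[ch]])
    if (length(v) != 2L || anyNA(v) || v[1L] > v[2L])
      stop("gate interval on '", ch, "' must be c(lower, upper) with ",
           "lower <= upper", call. = FALSE)
    iv[[ch]] <- v
  }
  structure(iv, class = "rect_gate")
}

#' Apply a rectangular gate to an event matrix
#'
#' @param events An [event_matrix()].
#' @param gate A [rect_gate()].
#' @return The gated `event_matrix` (row order preserved). Errors if the gate
#'   removes every event, reporting the surviving count.
#' @examples
#' em <- event_matrix(cbind(x = c(1, 5, 9)))
#' apply_gate(em, rect_gate(x = c(4, 10)))
#' @export
apply_gate <- function(events, gate) {
  events <- as_event_matrix(events)
  if (!inherits(gate, "rect_gate")) stop("gate must be a rect_gate",
                                         call. = FALSE)
  missing_ch <- setdiff(names(gate), channels(events))
  if (length(missing_ch))
    stop("gated channel(s) not present: ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  keep <- rep(TRUE, nrow(events))
  for (ch in names(gate)) {
    v <- events[, ch]
    keep <- keep & v >= gate[[ch]][1L] & v <= gate[[ch]][2L]
  }
  if (!any(keep))
    stop("degenerate input: gate empties the sample (0 of ", nrow(events),
         " events survive)", call. = FALSE)
  subset_events(events, keep)
}
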