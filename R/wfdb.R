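# Minimal WFDB (waveform database) export/import: format-16 signals in one
# .dat file with a plain-text .hea header. Covers what this package needs
# for interoperable waveform output; not a general WFDB implementation.

#' Write a 12-lead waveform as a WFDB record
#'
#' Stores the signal as interleaved 16-bit little-endian integers (WFDB
#' format 16) in `<record>.dat` with a `<record>.hea` header carrying the
#' per-signal gain and units (mV).
#'
#' @param x numeric matrix, leads x samples, in millivolts.
#' @param record record name (file stem).
#' @param dir output directory.
#' @param fs sampling frequency, Hz.
#' @param adc_gain integer ADC units per millivolt (default 1000).
#' @return invisibly, the path to the header file.
#' @export
write_wfdb <- function(x, record, dir = ".", fs = 500, adc_gain = 1000) {
  stopifnot(is.matrix(x), nrow(x) >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_sig <- nrow(x); n_samp <- ncol(x)
  leads <- rownames(x)
  if (is.null(leads)) leads <- paste0("sig", seq_len(n_sig))
  dig <- round(x * adc_gain)
  dig <- pmin(pmax(dig, -32768), 32767)
  dat <- paste0(record, ".dat")
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con))
  writeBin(as.integer(dig), con, size = 2, endian = "little")
  hea <- c(sprintf("%s %d %g %d", record, n_sig, fs, n_samp),
           sprintf("%s 16 %d/mV 16 0 %d 0 0 %s", dat, adc_gain,
                   as.integer(dig[, 1]), leads))
  writeLines(hea, file.path(dir, paste0(record, ".hea")))
  invisible(file.path(dir, paste0(record, ".hea")))
}

#' Read a WFDB record written by [write_wfdb()]
#'
#' @param record record name (file stem).
#' @param dir directory containing the `.hea`/`.dat` pair.
#' @return numeric matrix, leads x samples, in millivolts, with attributes
#'   `fs` (sampling frequency).
#' @export
read_wfdb <- function(record, dir = ".") {
  hea <- readLines(file.path(dir, paste0(record, ".hea")))
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  n_sig <- as.integer(top[2]); fs <- as.numeric(top[3])
  n_samp <- as.integer(top[4])
  sig_lines <- strsplit(trimws(hea[1 + seq_len(n_sig)]), "\\s+")
  fmt <- vapply(sig_lines, `[`, character(1), 2)
  if (!all(fmt == "16")) stop("only WFDB format 16 is supported")
  gain <- as.numeric(sub("/.*", "", vapply(sig_lines, `[`, character(1), 3)))
  leads <- vapply(sig_lines, function(z) z[length(z)], character(1))
  dat <- vapply(sig_lines, `[`, character(1), 1)[1]
  con <- file(file.path(dir, dat), "rb")
  on.exit(close(con))
  raw <- readBin(con, integer(), n = n_sig * n_samp, size = 2,
                 endian = "little", signed = TRUE)
  x <- matrix(raw, nrow = n_sig) / gain
  rownames(x) <- leads
  attr(x, "fs") <- fs
  x
}
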