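# File formats: delimited-text beat matrices (one beat per row, label last)
# and a minimal WFDB-compatible subset (text header, 16-bit little-endian
# signal, MIT-style annotation words) sufficient for round-tripping annotated
# records. Model parameters travel via write_params()/read_params().

#' Write a beat matrix as delimited text
#'
#' One beat per row: 250 comma-separated sample values followed by the class
#' label in the last column. No header row.
#'
#' @param bm A [beat_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_beats <- function(bm, path) {
  stopifnot(inherits(bm, "beat_matrix"))
  df <- as.data.frame(bm$beats)
  df$label <- bm$labels
  write.table(df, path, sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a beat matrix from delimited text
#'
#' Expects the format of [write_beats()]: 250 numeric columns plus a label
#' column. Every row is validated; a ragged or mislabeled row is rejected
#' with its row number.
#'
#' @param path Input file.
#' @param sep Field separator (default comma).
#' @return A [beat_matrix()].
#' @export
read_beats <- function(path, sep = ",") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warnf("empty beat file: %s", path)
    return(beat_matrix(matrix(numeric(0), 0, 250), character(0),
                       character(0)))
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 251L)
  if (length(bad))
    stopf("row %d of %s has %d fields (expected 250 samples + 1 label)",
          bad[1], path, nf[bad[1]])
  labels <- vapply(fields, function(f) f[[251L]], character(1))
  badlab <- which(!labels %in% beat_classes())
  if (length(badlab))
    stopf("row %d of %s has unknown beat label '%s'", badlab[1], path,
          labels[badlab[1]])
  beats <- matrix(as.numeric(vapply(fields, function(f)
    as.numeric(f[1:250]), numeric(250))), ncol = 250, byrow = TRUE)
  if (any(!is.finite(beats))) {
    badrow <- which(rowSums(!is.finite(beats)) > 0)[1]
    stopf("row %d of %s has non-numeric sample values", badrow, path)
  }
  beat_matrix(beats, labels, rep(basename(path), length(labels)))
}

# --- WFDB subset -------------------------------------------------------------

# Annotation codes of the MIT arrhythmia convention for the classes handled
# here: N=1, L=2, R=3, V=5, A=8.
#' @noRd
wfdb_codes <- function() c(N = 1L, L = 2L, R = 3L, V = 5L, A = 8L)

#' @noRd
wfdb_skip_code <- 59L

#' Write an annotated record in WFDB-compatible format
#'
#' Produces `<prefix>.hea` (text header), `<prefix>.dat` (format 16: 16-bit
#' little-endian integers at gain `gain` adu per unit, lead description "II")
#' and `<prefix>.atr` (MIT annotation words; N/L/R/V/A beat codes, SKIP
#' escapes for long intervals). Covers the subset of WFDB this package reads.
#'
#' @param record An [ecg_record()].
#' @param prefix Path prefix (no extension).
#' @param gain Integer quantization gain (default 1000 adu per unit).
#' @return `prefix`, invisibly.
#' @export
write_wfdb <- function(record, prefix, gain = 1000L) {
  stopifnot(inherits(record, "ecg_record"))
  rec_name <- basename(prefix)
  n <- length(record$samples)
  dig <- as.integer(round(record$samples * gain))
  if (any(abs(dig) > 32767L))
    stopf("signal exceeds the 16-bit range at gain %d", gain)
  writeLines(c(sprintf("%s 1 %g %d", rec_name, record$fs, n),
               sprintf("%s.dat 16 %d 16 0 %d 0 0 II", rec_name, gain,
                       dig[1])),
             paste0(prefix, ".hea"))
  con <- file(paste0(prefix, ".dat"), "wb")
  writeBin(dig, con, size = 2L, endian = "little")
  close(con)

  codes <- wfdb_codes()
  words <- integer(0)
  t_prev <- 0L
  for (i in seq_along(record$r_peaks)) {
    code <- codes[[record$beat_labels[i]]]
    if (is.null(code))
      stopf("beat label '%s' has no annotation code", record$beat_labels[i])
    dt <- (record$r_peaks[i] - 1L) - t_prev        # 0-based sample times
    if (dt > 1023L) {
      lo16 <- dt %% 65536L
      hi16 <- dt %/% 65536L
      words <- c(words, wfdb_skip_code * 1024L, hi16, lo16, code * 1024L)
    } else {
      words <- c(words, code * 1024L + dt)
    }
    t_prev <- record$r_peaks[i] - 1L
  }
  words <- c(words, 0L)                             # end of annotations
  words <- ifelse(words > 32767L, words - 65536L, words)
  con <- file(paste0(prefix, ".atr"), "wb")
  writeBin(as.integer(words), con, size = 2L, endian = "little")
  close(con)
  invisible(prefix)
}

#' Read a WFDB record (subset)
#'
#' Parses the header, selects the lead described as "II" (required when the
#' record is multi-lead), reads the format-16 signal and the annotations.
#' Annotation symbols outside N/L/R/V/A are dropped; the number dropped is
#' attached as attribute `n_dropped`.
#'
#' @param prefix Path prefix of the `.hea`/`.dat`/`.atr` files.
#' @return An [ecg_record()].
#' @export
read_wfdb <- function(prefix) {
  hea <- paste0(prefix, ".hea")
  if (!file.exists(hea)) stopf("no such header: %s", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  n <- as.integer(top[4])
  sig_lines <- lines[1 + seq_len(nsig)]
  descs <- vapply(strsplit(trimws(sig_lines), "\\s+"), function(f)
    if (length(f) >= 9) paste(f[-(1:8)], collapse = " ") else "", character(1))
  lead <- which(descs == "II")
  if (!length(lead))
    stopf("record %s has no lead II signal (leads: %s)", prefix,
          paste(sQuote(descs), collapse = ", "))
  lead <- lead[1]
  fmt <- as.integer(strsplit(trimws(sig_lines[lead]), "\\s+")[[1]][2])
  if (fmt != 16L) stopf("only format 16 signals are supported, got %d", fmt)
  gain <- as.numeric(strsplit(trimws(sig_lines[lead]), "\\s+")[[1]][3])
  if (!is.finite(gain) || gain <= 0) gain <- 200   # WFDB default gain

  con <- file(paste0(prefix, ".dat"), "rb")
  raw16 <- readBin(con, "integer", n = n * nsig, size = 2L, signed = TRUE,
                   endian = "little")
  close(con)
  sig <- raw16[seq(lead, length(raw16), by = nsig)] / gain

  con <- file(paste0(prefix, ".atr"), "rb")
  words <- readBin(con, "integer", n = file.size(paste0(prefix, ".atr")) / 2,
                   size = 2L, signed = FALSE, endian = "little")
  close(con)
  codes <- wfdb_codes()
  rev_codes <- stats::setNames(names(codes), codes)
  t_cur <- 0L
  i <- 1L
  r_peaks <- integer(0)
  labels <- character(0)
  n_dropped <- 0L
  while (i <= length(words)) {
    w <- words[i]
    if (w == 0L) break
    code <- w %/% 1024L
    dt <- w %% 1024L
    if (code == wfdb_skip_code) {
      t_cur <- t_cur + words[i + 1L] * 65536L + words[i + 2L]
      i <- i + 3L
      next
    }
    t_cur <- t_cur + dt
    sym <- rev_codes[as.character(code)]
    if (is.na(sym)) n_dropped <- n_dropped + 1L
    else {
      r_peaks <- c(r_peaks, t_cur + 1L)            # back to 1-based
      labels <- c(labels, sym)
    }
    i <- i + 1L
  }
  out <- ecg_record(sig, fs, r_peaks, labels)
  attr(out, "n_dropped") <- n_dropped
  out
}
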