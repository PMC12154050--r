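# Minimal EDF (European Data Format) reader/writer for continuous
# multichannel recordings: fixed-width ASCII header, 16-bit little-endian
# samples, per-signal linear digital->physical scaling. Annotations,
# discontinuous recordings and per-signal sampling rates are not supported.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) cc_input_error(
    sprintf("EDF header field too wide: '%s' (max %d chars)", s, width))
  formatC(s, width = -width)  # left-justified, space padded
}

# format a number to fit an 8-char EDF field; returns the string actually
# written so the caller can quantize against its parsed value
edf_num8 <- function(x) {
  for (d in c(7, 6, 5, 4, 3, 2)) {
    s <- sprintf("%.*g", d, x)
    if (nchar(s) <= 8) return(s)
  }
  cc_input_error(sprintf("cannot represent %g in an 8-char EDF field", x))
}

write_edf <- function(rec, path) {
  ns <- nrow(rec$data)
  n_samp <- ncol(rec$data)
  # one-second records; trailing partial second padded with the last value
  spr <- as.integer(round(rec$sfreq))
  if (abs(rec$sfreq - spr) > 1e-9)
    cc_input_error("EDF writer requires an integer sampling rate")
  n_rec <- as.integer(ceiling(n_samp / spr))
  total <- n_rec * spr

  pm_str <- character(ns); pmin <- numeric(ns); pmax <- numeric(ns)
  for (i in seq_len(ns)) {
    a <- max(abs(rec$data[i, ]), 1e-6)
    pm_str[i] <- edf_num8(signif(a * 1.0001, 5))
    a <- as.numeric(pm_str[i])
    pmin[i] <- -a; pmax[i] <- a
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  wr(edf_field("0", 8))
  wr(edf_field(rec$subject_id, 80))
  wr(edf_field(if (is.null(rec$label)) "Startdate X X X X" else
               paste("Startdate X X X", rec$label), 80))
  wr(edf_field("01.01.00", 8))
  wr(edf_field("00.00.00", 8))
  wr(edf_field(hdr_bytes, 8))
  # record true sample count in the reserved field so the reader can trim
  # the zero-order-hold padding of the trailing partial second
  wr(edf_field(sprintf("NSAMP=%d", n_samp), 44))
  wr(edf_field(n_rec, 8))
  wr(edf_field("1", 8))                       # record duration: 1 s
  wr(edf_field(ns, 4))
  for (i in seq_len(ns)) wr(edf_field(rec$channel_names[i], 16))
  for (i in seq_len(ns)) wr(edf_field("", 80))      # transducer
  for (i in seq_len(ns)) wr(edf_field("uV", 8))     # physical dimension
  for (i in seq_len(ns)) wr(edf_field(paste0("-", pm_str[i]), 8))
  for (i in seq_len(ns)) wr(edf_field(pm_str[i], 8))
  for (i in seq_len(ns)) wr(edf_field("-32768", 8))
  for (i in seq_len(ns)) wr(edf_field("32767", 8))
  for (i in seq_len(ns)) wr(edf_field("", 80))      # prefiltering
  for (i in seq_len(ns)) wr(edf_field(spr, 8))
  for (i in seq_len(ns)) wr(edf_field("", 32))

  # pad each channel to a whole number of records, quantize, interleave
  dig <- matrix(0L, ns, total)
  for (i in seq_len(ns)) {
    x <- rec$data[i, ]
    if (total > n_samp) x <- c(x, rep(x[n_samp], total - n_samp))
    # inverse of the standard EDF affine: phys = (dig - dmin) * g + pmin
    d <- round((x - pmin[i]) / (pmax[i] - pmin[i]) * 65535 - 32768)
    dig[i, ] <- as.integer(base::pmin(base::pmax(d, -32768), 32767))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.vector(t(dig[, idx, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    s <- readChar(con, w, useBytes = TRUE)
    if (length(s) == 0 || nchar(s, type = "bytes") < w)
      cc_input_error(sprintf("%s: truncated EDF header", path))
    trimws(s)
  }
  rd(8)                       # version
  subject_id <- rd(80)
  rec_id <- rd(80)
  rd(8); rd(8)                # date, time
  rd(8)                       # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) cc_input_error(sprintf("%s: bad EDF signal count", path))
  if (is.na(n_rec) || n_rec < 0)
    cc_input_error(sprintf("%s: unknown EDF record count", path))
  if (is.na(dur) || dur <= 0)
    cc_input_error(sprintf("%s: missing EDF record duration (no sampling rate)", path))

  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    cc_input_error(sprintf("%s: per-signal sampling rates differ; not supported", path))
  sfreq <- spr[1] / dur

  data <- matrix(0, ns, n_rec * spr[1])
  per_rec <- sum(spr)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, integer(), per_rec, size = 2L, signed = TRUE,
                     endian = "little")
    if (length(block) < per_rec)
      cc_input_error(sprintf("%s: truncated EDF data record %d", path, r))
    off <- 0L
    for (i in seq_len(ns)) {
      data[i, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
        block[(off + 1L):(off + spr[i])]
      off <- off + spr[i]
    }
  }
  # digital -> physical
  for (i in seq_len(ns)) {
    g <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    data[i, ] <- (data[i, ] - dmin[i]) * g + pmin[i]
  }
  m <- regmatches(reserved, regexec("NSAMP=([0-9]+)", reserved))[[1]]
  if (length(m) == 2) {
    n_true <- as.integer(m[2])
    if (n_true >= 1 && n_true <= ncol(data))
      data <- data[, seq_len(n_true), drop = FALSE]
  }
  lbl <- NULL
  m <- regmatches(rec_id, regexec("^Startdate X X X (.+)$", rec_id))[[1]]
  if (length(m) == 2 && nzchar(m[2]) && m[2] != "X") lbl <- m[2]
  list(data = data, channel_names = labels, sfreq = sfreq,
       subject_id = subject_id, label = lbl)
}
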