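# Minimal FCS 3.1 support: single dataset, list mode, DATATYPE F (32-bit
# float), little-endian. This covers what cytometer list-mode exports need
# here; compensation/ANALYSIS segments and integer data types are out of scope.

write_fcs <- function(table, path) {
  ev <- table$events
  par_names <- names(ev)
  p <- length(par_names)
  n <- nrow(ev)
  rng <- 262144L  # 2^18, a common ADC range

  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$BEGINDATA" = "%010d", "$ENDDATA" = "%010d",
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0", "$TOT" = as.character(n), "$PAR" = as.character(p),
          "$SRC" = table$well_id, "$CYT" = table$instrument_id)
  for (i in seq_len(p)) {
    kw[sprintf("$P%dN", i)] <- par_names[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- as.character(rng)
  }
  text_tpl <- paste0("/", paste(names(kw), kw, sep = "/", collapse = "/"), "/")
  header_len <- 58L
  # %010d renders at fixed width, so the TEXT length is offset-independent
  data_start <- header_len + nchar(sprintf(text_tpl, 0L, 0L))
  data_end <- data_start + 4L * n * p - 1L
  if (n == 0) data_start <- data_end <- 0L
  text <- sprintf(text_tpl, data_start, data_end)
  text_start <- header_len
  text_end <- text_start + nchar(text) - 1L

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar("FCS3.1    ", con, eos = NULL)
  writeChar(sprintf("%8d%8d%8d%8d%8d%8d", text_start, text_end,
                    data_start, data_end, 0L, 0L), con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (n > 0) {
    # interleave events (list mode): row-major over events x parameters
    m <- t(as.matrix(ev))
    writeBin(as.vector(m), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_fcs <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(raw[1:6]) != "FCS3.1" && rawToChar(raw[1:6]) != "FCS3.0") {
    abort_format("not an FCS 3.x file")
  }
  off <- function(a, b) as.integer(trimws(rawToChar(raw[a:b])))
  text_start <- off(11, 18); text_end <- off(19, 26)
  text <- rawToChar(raw[(text_start + 1):(text_end + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        parts[seq(1, length(parts), 2)])

  if (toupper(kw[["$DATATYPE"]]) != "F") {
    abort_format(paste0("unsupported FCS $DATATYPE: ", kw[["$DATATYPE"]]))
  }
  if (toupper(kw[["$MODE"]]) != "L") abort_format("only list-mode FCS supported")
  endian <- if (kw[["$BYTEORD"]] == "4,3,2,1") "big" else "little"
  n <- as.integer(kw[["$TOT"]]); p <- as.integer(kw[["$PAR"]])
  par_names <- vapply(seq_len(p), function(i) kw[[sprintf("$P%dN", i)]], "")

  if (n > 0) {
    data_start <- as.integer(kw[["$BEGINDATA"]])
    if (is.na(data_start) || data_start == 0) data_start <- off(27, 34)
    vals <- readBin(raw[(data_start + 1):length(raw)], "numeric",
                    n = n * p, size = 4, endian = endian)
    m <- matrix(vals, nrow = n, ncol = p, byrow = TRUE,
                dimnames = list(NULL, par_names))
  } else {
    m <- matrix(numeric(0), ncol = p, dimnames = list(NULL, par_names))
  }
  get_kw <- function(k) if (k %in% names(kw)) unname(kw[[k]]) else NULL
  list(events = tibble::as_tibble(as.data.frame(m)),
       well_id = get_kw("$SRC"),
       instrument_id = get_kw("$CYT"))
}
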