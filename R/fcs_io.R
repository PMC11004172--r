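# FCS 3.0/3.1 list-mode I/O, restricted to what ALOT exports need:
# $DATATYPE F (single-precision float) or D on read, $MODE L, either byte
# order. Written files are FCS 3.1, float, little-endian.

FCS_HEADER_LEN <- 58L

# -- reading -----------------------------------------------------------------

parse_fcs_text <- function(raw_text) {
  if (length(raw_text) < 2L) stop_format("TEXT segment too short")
  delim <- rawToChar(raw_text[1L])
  body <- rawToChar(raw_text[-1L])
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  # trailing delimiter leaves an empty last element; drop it
  if (length(parts) && parts[length(parts)] == "") parts <- parts[-length(parts)]
  if (length(parts) %% 2L != 0L)
    stop_format("TEXT segment has an odd number of key/value tokens")
  keys <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  vals <- trimws(parts[seq(2, length(parts), by = 2)])
  stats::setNames(as.list(vals), keys)
}

fcs_keyword <- function(kw, name, default = NULL) {
  v <- kw[[toupper(name)]]
  if (is.null(v)) default else v
}

#' Read an ALOT FCS file
#'
#' Parses an FCS 3.0/3.1 list-mode file with float data and maps its
#' parameters onto the 12-channel ALOT panel by stain name (`$PnS`) first,
#' then short name (`$PnN`), using a case-insensitive substring alias table.
#' Extra instrument parameters (e.g. `Time`) are dropped with a warning.
#'
#' @param path Path to the FCS file.
#' @param panel Target [channel_panel()].
#' @param max_events Event cap passed to [event_matrix()].
#' @return An [event_matrix()] whose columns follow the panel order; event
#'   order is preserved.
#' @export
read_fcs <- function(path, panel = alot_panel(), max_events = 250000L) {
  if (!file.exists(path)) stop_io(paste0("no such file: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", FCS_HEADER_LEN)
  if (length(header) < FCS_HEADER_LEN) stop_format("file shorter than an FCS header")
  version <- trimws(rawToChar(header[1:6]))
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop_format(paste0("unsupported FCS version: ", version))
  offs <- function(i) {
    s <- rawToChar(header[(11L + (i - 1L) * 8L):(10L + i * 8L)])
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (is.na(v)) stop_format("non-numeric segment offset in header")
    v
  }
  text_beg <- offs(1); text_end <- offs(2)
  data_beg <- offs(3); data_end <- offs(4)
  fsize <- file.size(path)
  if (text_beg < FCS_HEADER_LEN || text_end < text_beg || text_end >= fsize)
    stop_format("TEXT segment offsets are inconsistent with file size")
  seek(con, text_beg)
  kw <- parse_fcs_text(readBin(con, "raw", text_end - text_beg + 1L))

  if (data_beg == 0 || data_end == 0) {
    data_beg <- as.numeric(fcs_keyword(kw, "$BEGINDATA", NA))
    data_end <- as.numeric(fcs_keyword(kw, "$ENDDATA", NA))
    if (is.na(data_beg) || is.na(data_end))
      stop_format("DATA segment offsets missing from header and TEXT")
  }

  dtype <- fcs_keyword(kw, "$DATATYPE")
  mode <- fcs_keyword(kw, "$MODE")
  if (is.null(dtype) || !dtype %in% c("F", "D"))
    stop_format("only $DATATYPE F or D is supported")
  if (is.null(mode) || toupper(mode) != "L")
    stop_format("only list-mode ($MODE L) data is supported")
  npar <- as.integer(fcs_keyword(kw, "$PAR", NA))
  ntot <- as.numeric(fcs_keyword(kw, "$TOT", NA))
  if (is.na(npar) || is.na(ntot) || npar < 1L || ntot < 1)
    stop_format("$PAR/$TOT missing or invalid")
  if (npar < 12L)
    stop_panel_mismatch(sprintf("file declares %d parameters; 12 needed", npar))
  word <- if (dtype == "F") 4L else 8L
  bits <- vapply(seq_len(npar), function(i)
    as.integer(fcs_keyword(kw, sprintf("$P%dB", i), NA)), integer(1))
  if (any(is.na(bits)) || any(bits != word * 8L))
    stop_format("all $PnB must equal the datatype word size")
  byteord <- fcs_keyword(kw, "$BYTEORD", "1,2,3,4")
  endian <- if (byteord == "1,2,3,4") "little"
            else if (byteord == "4,3,2,1") "big"
            else stop_format(paste0("unsupported $BYTEORD: ", byteord))

  expected <- ntot * npar * word
  if (data_beg < FCS_HEADER_LEN || data_end >= fsize ||
      (data_end - data_beg + 1) != expected)
    stop_format(sprintf(
      "DATA segment length %.0f disagrees with $TOT*$PAR*%d = %.0f bytes",
      data_end - data_beg + 1, word, expected))

  seek(con, data_beg)
  vals <- readBin(con, "double", n = ntot * npar, size = word, endian = endian)
  if (length(vals) != ntot * npar) stop_format("DATA segment truncated")
  mat <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE)
  if (!all(is.finite(mat))) stop_format("non-finite values in DATA segment")

  pnn <- vapply(seq_len(npar), function(i)
    fcs_keyword(kw, sprintf("$P%dN", i), ""), character(1))
  pns <- vapply(seq_len(npar), function(i)
    fcs_keyword(kw, sprintf("$P%dS", i), ""), character(1))
  sel <- map_panel_columns(panel, pns = pns, pnn = pnn)
  dropped <- setdiff(seq_len(npar), sel)
  if (length(dropped))
    warning(sprintf("ignoring %d extra parameter(s): %s", length(dropped),
                    paste(ifelse(nzchar(pnn[dropped]), pnn[dropped], "?"),
                          collapse = ", ")),
            call. = FALSE)
  sample_id <- fcs_keyword(kw, "$FIL",
                           sub("\\.fcs$", "", basename(path), ignore.case = TRUE))
  event_matrix(sample_id, mat[, sel, drop = FALSE], panel = panel,
               max_events = max_events)
}

# For each panel channel pick the first unclaimed parameter whose $PnS (then
# $PnN) contains one of the channel's aliases, case-insensitively.
map_panel_columns <- function(panel, pns, pnn) {
  aliases <- panel_alias_table()
  ls <- tolower(pns); ln <- tolower(pnn)
  claimed <- rep(FALSE, length(pns))
  sel <- integer(length(panel$names))
  for (j in seq_along(panel$names)) {
    al <- aliases[[panel$names[j]]]
    if (is.null(al)) al <- tolower(panel$names[j])
    hit <- NA_integer_
    for (a in al) {
      cand <- which(!claimed & (grepl(a, ls, fixed = TRUE) |
                                grepl(a, ln, fixed = TRUE)))
      if (length(cand)) { hit <- cand[1L]; break }
    }
    if (is.na(hit))
      stop_panel_mismatch(paste0("cannot map panel channel '", panel$names[j],
                                 "' to any file parameter"))
    claimed[hit] <- TRUE
    sel[j] <- hit
  }
  sel
}

# -- writing -----------------------------------------------------------------

#' Write an event matrix as FCS 3.1
#'
#' Emits list-mode, single-precision float, little-endian FCS 3.1. Reading
#' the file back reproduces the values to float32 precision with event order
#' preserved.
#'
#' @param em An [event_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(em, path) {
  stopifnot(inherits(em, "event_matrix"))
  vals <- em$values
  n <- nrow(vals); p <- ncol(vals)
  rng <- max(262144, 2^ceiling(log2(max(1, max(vals)))))
  kv <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(p), "$TOT" = as.character(n),
    "$FIL" = em$sample_id
  )
  for (i in seq_len(p)) {
    kv[sprintf("$P%dB", i)] <- "32"
    kv[sprintf("$P%dE", i)] <- "0,0"
    kv[sprintf("$P%dN", i)] <- em$panel$names[i]
    kv[sprintf("$P%dS", i)] <- em$panel$names[i]
    kv[sprintf("$P%dR", i)] <- format(rng, scientific = FALSE)
  }
  delim <- "/"
  build_text <- function(beg_data, end_data) {
    kv2 <- c(kv, "$BEGINDATA" = format(beg_data, scientific = FALSE),
             "$ENDDATA" = format(end_data, scientific = FALSE))
    paste0(delim, paste0(names(kv2), delim, unname(kv2), delim, collapse = ""))
  }
  # offsets depend on TEXT length; iterate to a fixed point
  text_beg <- FCS_HEADER_LEN
  beg_data <- 0; end_data <- 0
  for (iter in 1:5) {
    txt <- build_text(beg_data, end_data)
    nb <- text_beg + nchar(txt, type = "bytes")
    ne <- nb + n * p * 4 - 1
    if (nb == beg_data && ne == end_data) break
    beg_data <- nb; end_data <- ne
  }
  txt <- build_text(beg_data, end_data)
  text_end <- text_beg + nchar(txt, type = "bytes") - 1L
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_beg, text_end, beg_data, end_data, 0L, 0L)

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_io(paste0("cannot open for write: ", path)))
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  writeBin(as.numeric(t(vals)), con, size = 4, endian = "little")
  invisible(path)
}

# -- label sidecars ----------------------------------------------------------

#' Read a per-event cell-type label sidecar
#'
#' A sidecar is a CSV with columns `event_index,label` (1-based row indices
#' into the event matrix). Events missing from the sidecar are assigned
#' `"debris"`, the package's unlabeled/unclassifiable convention.
#'
#' @param path Sidecar CSV path.
#' @param n_events Number of events in the companion FCS file.
#' @return Character vector of length `n_events` with labels from
#'   [cell_types()].
#' @export
read_label_sidecar <- function(path, n_events) {
  if (!file.exists(path)) stop_io(paste0("no such file: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("event_index", "label") %in% names(df)))
    stop_format("sidecar must have columns event_index,label")
  check_labels(df$label)
  idx <- as.integer(df$event_index)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > n_events))
    stop_format("sidecar event_index out of range")
  labels <- rep("debris", n_events)
  labels[idx] <- df$label
  labels
}

#' @describeIn read_label_sidecar Write a label vector as a sidecar CSV.
#' @param labels Character vector of per-event labels.
#' @export
write_label_sidecar <- function(labels, path) {
  check_labels(labels)
  utils::write.csv(
    data.frame(event_index = seq_along(labels), label = labels),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a cohort manifest
#'
#' The manifest CSV has columns `sample_id,fcs_path,label_path,diagnosis`;
#' relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return A data.frame with the four manifest columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_io(paste0("no such file: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "fcs_path", "label_path", "diagnosis")
  if (!all(need %in% names(df)))
    stop_format("manifest must have columns sample_id,fcs_path,label_path,diagnosis")
  bad <- setdiff(unique(df$diagnosis), diagnosis_levels())
  if (length(bad))
    stop_unknown_label(paste0("unknown diagnosis label(s): ",
                              paste(bad, collapse = ", ")))
  base <- dirname(normalizePath(path))
  for (col in c("fcs_path", "label_path")) {
    rel <- !grepl("^(/|[A-Za-z]:)", df[[col]])
    df[[col]][rel] <- file.path(base, df[[col]][rel])
  }
  df
}
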