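test_that("write/read round trip preserves values and order", {
  em <- random_event_matrix(n = 1000, seed = 0)
  f <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(em, f)
  em2 <- read_fcs(f)
  expect_equal(nrow(em2$values), 1000)
  expect_equal(ncol(em2$values), 12)
  rel <- max(abs(em2$values - em$values) / pmax(abs(em$values), 1))
  expect_lt(rel, 1e-5)
  expect_identical(em2$panel$names, alot_panel()$names)
  expect_identical(em2$sample_id, "fix")
})

test_that("round trip is float32-accurate on 20 random fixtures", {
  f <- withr::local_tempfile(fileext = ".fcs")
  for (s in 1:20) {
    em <- random_event_matrix(n = 37, seed = s)
    write_fcs(em, f)
    em2 <- read_fcs(f)
    expect_lt(max(abs(em2$values - em$values) /
                    pmax(abs(em$values), 1e-6)), 1e-5)
  }
})

test_that("an all-zero matrix survives the round trip", {
  em <- event_matrix("z", matrix(0, 5, 12))
  f <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(em, f)
  expect_true(all(read_fcs(f)$values == 0))
})

test_that("extra parameters such as Time are dropped with a warning", {
  # hand-build a 13-parameter file by appending a Time column
  em <- random_event_matrix(n = 20, seed = 3)
  f <- withr::local_tempfile(fileext = ".fcs")
  # write a 13-col file through the low-level path: reuse write_fcs on a
  # panel-shaped file, then rewrite TEXT+DATA with 13 params
  vals <- cbind(em$values, Time = seq_len(20))
  write_fcs13 <- function(vals, path) {
    n <- nrow(vals); p <- ncol(vals)
    names13 <- c(alot_panel()$names, "Time")
    kv <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
            "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
            "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
            "$NEXTDATA" = "0", "$PAR" = as.character(p),
            "$TOT" = as.character(n), "$FIL" = "thirteen")
    for (i in seq_len(p)) {
      kv[sprintf("$P%dB", i)] <- "32"
      kv[sprintf("$P%dE", i)] <- "0,0"
      kv[sprintf("$P%dN", i)] <- names13[i]
      kv[sprintf("$P%dR", i)] <- "262144"
    }
    build <- function(b, e) paste0("/", paste0(names(kv), "/", kv, "/",
                                               collapse = ""),
                                   "$BEGINDATA/", b, "/$ENDDATA/", e, "/")
    tb <- 58L; bd <- 0; ed <- 0
    for (it in 1:5) {
      txt <- build(bd, ed)
      nb <- tb + nchar(txt); ne <- nb + n * p * 4 - 1
      if (nb == bd && ne == ed) break
      bd <- nb; ed <- ne
    }
    txt <- build(bd, ed)
    con <- file(path, "wb"); on.exit(close(con))
    writeChar(sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", tb,
                      tb + nchar(txt) - 1L, bd, ed, 0L, 0L),
              con, eos = NULL)
    writeChar(txt, con, eos = NULL)
    writeBin(as.numeric(t(vals)), con, size = 4, endian = "little")
  }
  write_fcs13(vals, f)
  expect_warning(em2 <- read_fcs(f), "extra parameter")
  expect_equal(ncol(em2$values), 12)
  expect_equal(em2$values[, 1], em$values[, 1], tolerance = 1e-6)
})

test_that("inconsistent data offsets raise a format error", {
  em <- random_event_matrix(n = 10, seed = 4)
  f <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(em, f)
  # corrupt $TOT in the TEXT segment: 10 -> 90 events declared
  raw <- readBin(f, "raw", file.size(f))
  pat <- charToRaw("$TOT/10/")
  hit <- which(vapply(seq_len(length(raw) - length(pat) + 1L), function(i)
    identical(raw[i:(i + length(pat) - 1L)], pat), logical(1)))[1]
  raw[hit + 5L] <- charToRaw("9")
  writeBin(raw, f)
  expect_error(read_fcs(f), class = "ef_format_error")
})

test_that("non-finite data values raise a format error", {
  em <- random_event_matrix(n = 10, seed = 5)
  f <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(em, f)
  # overwrite the first data value with NaN (float32, little-endian)
  hdr <- readBin(f, "raw", 58)
  beg <- as.integer(trimws(rawToChar(hdr[27:34])))
  con <- file(f, "r+b")
  seek(con, beg, rw = "write")
  writeBin(NaN, con, size = 4, endian = "little")
  close(con)
  expect_error(read_fcs(f), class = "ef_format_error")
})

test_that("event cap and panel invariants are enforced", {
  expect_error(event_matrix("big", matrix(0, 11, 12), max_events = 10L),
               class = "ef_cap_exceeded")
  expect_error(event_matrix("bad", matrix(0, 5, 11)),
               class = "ef_panel_mismatch")
  expect_error(event_matrix("nan", matrix(NaN, 5, 12)),
               class = "ef_format_error")
  expect_error(channel_panel(letters[1:12], rep("fluorescence", 12)),
               class = "ef_panel_mismatch")
})

test_that("label sidecars default missing rows to debris", {
  labels <- rep("Neu", 30)
  f <- withr::local_tempfile(fileext = ".csv")
  write_label_sidecar(labels, f)
  expect_identical(read_label_sidecar(f, 30), labels)
  # drop rows 10-20
  df <- read.csv(f)
  write.csv(df[-(10:20), ], f, row.names = FALSE)
  got <- read_label_sidecar(f, 30)
  expect_true(all(got[10:20] == "debris"))
  expect_true(all(got[-(10:20)] == "Neu"))
})

test_that("labels outside the 16-class vocabulary are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(event_index = 1:3, label = "Basophil"), f,
            row.names = FALSE)
  expect_error(read_label_sidecar(f, 3), class = "ef_unknown_label")
})
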