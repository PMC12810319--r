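# MRC2014 and STAR round trips, metadata ingestion.

test_that("MRC stack write/read round-trips images, count and pixel size", {
  withSeed(11, {
    imgs <- lapply(1:50, function(i) matrix(rnorm(128^2), 128, 128))
    st <- classAverageStack(imgs, pixelSize = 0.82)
    f <- tempfile(fileext = ".mrcs")
    writeClassStack(st, f)
    rt <- readClassStack(f)
    expect_equal(nClasses(rt), 50L)
    expect_equal(dim(rt@images)[1], 128L)
    expect_equal(pixelSize(rt), 0.82, tolerance = 1e-6)
    # values survive at float32 precision ...
    expect_equal(rt@images, st@images, tolerance = 1e-6)
    # ... and a second write/read is bit-identical (float32 grid reached)
    f2 <- tempfile(fileext = ".mrcs")
    writeClassStack(rt, f2)
    expect_identical(readClassStack(f2)@images, rt@images)
  })
})

test_that("MRC reader converts integer modes and rejects bad input", {
  writeRawMrc <- function(path, mode, payload, writer) {
    con <- file(path, "wb")
    on.exit(close(con))
    wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                               endian = "little")
    wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                               endian = "little")
    wi(c(4L, 4L, 1L, mode, 0L, 0L, 0L, 4L, 4L, 1L))
    wf(c(4, 4, 1, 90, 90, 90))
    wi(c(1L, 2L, 3L))
    wf(c(0, 0, 0))
    wi(c(0L, 0L))
    writeBin(raw(1024L - 96L), con)
    writer(con, payload)
  }
  vals <- c(-3L, 0L, 5L, 120L, -8L, 2L, 7L, 1L, 0L, 0L, 4L, 9L, 1L, 2L, 3L, 4L)
  f0 <- tempfile()
  writeRawMrc(f0, 0L, vals, function(con, v) {
    writeBin(as.integer(v), con, size = 1L)
  })
  expect_equal(as.vector(readClassStack(f0)@images), as.numeric(vals))
  f1 <- tempfile()
  writeRawMrc(f1, 1L, vals * 100L, function(con, v) {
    writeBin(as.integer(v), con, size = 2L, endian = "little")
  })
  expect_equal(as.vector(readClassStack(f1)@images), as.numeric(vals * 100L))
  f6 <- tempfile()
  writeRawMrc(f6, 6L, abs(vals) * 300L, function(con, v) {
    writeBin(as.integer(v), con, size = 2L, endian = "little")
  })
  expect_equal(as.vector(readClassStack(f6)@images),
               as.numeric(abs(vals) * 300L))
  # unsupported mode
  f4 <- tempfile()
  writeRawMrc(f4, 4L, vals, function(con, v) {
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
  })
  expect_error(readClassStack(f4), "unsupported MRC mode")
  expect_error(readClassStack(tempfile()), "not found")
})

test_that("non-square MRC sections are rejected", {
  f <- tempfile()
  con <- file(f, "wb")
  writeBin(as.integer(c(100L, 120L, 1L, 2L)), con, size = 4L,
           endian = "little")
  writeBin(raw(1024L - 16L + 100L * 120L * 4L), con)
  close(con)
  expect_error(readClassStack(f), "non-square")
})

test_that("scores STAR output has the loop layout relion_display expects", {
  recs <- classRecords(0:2, 1.0, c(3.2, 4.1, 8.0), c(0.5, 0.3, 0.2),
                       stackFile = "run1.mrcs")
  recs$score <- c(1.25, 2.5, 4.75)
  f <- tempfile(fileext = ".star")
  writeScoresStar(recs, f)
  txt <- readLines(f)
  expect_true(any(grepl("^data_", txt)))
  expect_true(any(txt == "loop_"))
  expect_true(any(grepl("^_rlnReferenceImage", txt)))
  expect_true(any(grepl("^_cryosiftScore", txt)))
  back <- readStarTable(f)
  expect_equal(nrow(back), 3L)
  expect_equal(back$cryosiftScore, recs$score, tolerance = 5e-7)
  expect_equal(back$rlnReferenceImage,
               c("1@run1.mrcs", "2@run1.mrcs", "3@run1.mrcs"))
})

test_that("empty record list still writes a valid STAR header", {
  recs <- classRecords(integer(), numeric(), numeric(), numeric())
  f <- tempfile(fileext = ".star")
  writeScoresStar(recs, f)
  back <- readStarTable(f)
  expect_equal(nrow(back), 0L)
  expect_true("cryosiftScore" %in% names(back))
})

test_that("records without scores are refused by name", {
  recs <- classRecords(0:1, 1.0, c(3, 4), c(0.6, 0.4))
  recs$score <- c(2.0, NA_real_)
  expect_error(writeScoresStar(recs, tempfile()), "class index 1")
})

test_that("metadata ingestion renormalizes near-1 distributions", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(class_index = 0:19, pixel_size = 1.1,
                   frc_resolution = seq(3, 12, length.out = 20),
                   class_distribution = rep(0.995 / 20, 20))
  write.csv(df, f, row.names = FALSE)
  recs <- ingestMetadata(f)
  expect_equal(nrow(recs), 20L)
  expect_equal(sum(recs$classDistribution), 1, tolerance = 1e-9)

  # sums exactly 1 are preserved
  df$class_distribution <- rep(0.05, 20)
  write.csv(df, f, row.names = FALSE)
  expect_equal(sum(ingestMetadata(f)$classDistribution), 1, tolerance = 1e-12)

  # a >1% deviation is an error
  df$class_distribution <- rep(0.9 / 20, 20)
  write.csv(df, f, row.names = FALSE)
  expect_error(ingestMetadata(f), "1%")

  # missing required column is an error naming the field
  df2 <- df[, setdiff(names(df), "frc_resolution")]
  write.csv(df2, f, row.names = FALSE)
  expect_error(ingestMetadata(f), "missing column")
})

test_that("metadata ingestion reads STAR tables with RELION tags", {
  df <- data.frame(rlnClassNumber = 1:5, rlnPixelSize = 0.9,
                   rlnEstimatedResolutionA = c(3, 4, 5, 6, 7),
                   rlnClassDistribution = rep(0.2, 5))
  f <- tempfile(fileext = ".star")
  writeStarTable(df, f)
  recs <- ingestMetadata(f)
  expect_equal(recs$classIndex, 0:4)     # converted to 0-based
  expect_equal(recs$frcResolution, c(3, 4, 5, 6, 7))
})
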