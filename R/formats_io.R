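# MRC2014 and STAR file handling.
#
# MRC layout: 1024-byte header of 56 4-byte words plus 800 bytes of labels,
# then the data section (x fastest, then y, then z sections). Writes always
# use mode 2 (IEEE float32); reads accept modes 0 (int8), 1 (int16),
# 2 (float32) and 6 (uint16) and convert to double.

MRC_HEADER_BYTES <- 1024L

# word offsets (1-based, 4-byte words) per the MRC2014 standard
.mrcWriteHeader <- function(con, nx, ny, nz, pixelSize, dmin, dmax, dmean,
                            rms) {
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(c(nx, ny, nz))              # NX NY NZ
  wi(2L)                         # MODE 2 = float32
  wi(c(0L, 0L, 0L))              # NXSTART NYSTART NZSTART
  wi(c(nx, ny, nz))              # MX MY MZ
  wf(c(nx, ny, nz) * pixelSize)  # CELLA (A)
  wf(c(90, 90, 90))              # CELLB (deg)
  wi(c(1L, 2L, 3L))              # MAPC MAPR MAPS
  wf(c(dmin, dmax, dmean))       # DMIN DMAX DMEAN
  wi(0L)                         # ISPG (0 = image stack)
  wi(0L)                         # NSYMBT
  writeBin(raw(8L), con)         # EXTRA words 25-26
  writeChar("MRCO", con, nchars = 4L, eos = NULL)  # EXTTYP (word 27)
  wi(20140L)                     # NVERSION (word 28)
  writeBin(raw(4L * 21L), con)   # EXTRA words 29-49
  wf(c(0, 0, 0))                 # ORIGIN
  writeChar("MAP ", con, nchars = 4L, eos = NULL)  # word 53
  writeBin(as.raw(c(0x44L, 0x44L, 0x00L, 0x00L)), con)  # MACHST (LE)
  wf(rms)                        # RMS
  wi(0L)                         # NLABL
  writeBin(raw(800L), con)       # labels
}

#' Write a class-average stack as an MRC/MRCS file
#'
#' Writes MRC2014 mode 2 (32-bit float), little-endian, with the pixel size
#' stored in the cell dimensions (CELLA / MX), which is where
#' [readClassStack()] and the usual cryo-EM tools recover it from.
#'
#' @param stack a [ClassAverageStack-class].
#' @param path output file path (conventionally \code{.mrc}/\code{.mrcs}).
#' @return \code{path}, invisibly.
#' @examples
#' st <- classAverageStack(list(matrix(rnorm(64^2), 64, 64)), pixelSize = 1)
#' f <- tempfile(fileext = ".mrcs")
#' writeClassStack(st, f)
#' nClasses(readClassStack(f))
#' @export
writeClassStack <- function(stack, path) {
  stopifnot(is(stack, "ClassAverageStack"))
  v <- as.numeric(stack@images)
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(stack@images)
  .mrcWriteHeader(con, d[1], d[2], d[3], stack@pixelSize,
                  min(v), max(v), mean(v), sd(v))
  writeBin(v, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a class-average stack from an MRC/MRCS file
#'
#' Accepts MRC2014 modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16);
#' values are converted to double. Sections must be square. The pixel size
#' is taken from the header voxel size along x (CELLA[1]/MX).
#'
#' @param path path to an MRC/MRCS file.
#' @return A [ClassAverageStack-class] with one image per section.
#' @export
readClassStack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4L,
                            endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L,
                            endian = "little")
  nxyz <- ri(3L)
  mode <- ri(1L)
  ri(3L)                       # nstart
  mxyz <- ri(3L)
  cella <- rf(3L)
  if (any(nxyz < 1L)) stop("corrupt MRC header (non-positive dimensions)")
  if (nxyz[1] != nxyz[2]) {
    stop(sprintf("non-square sections (%d x %d): class averages must be square",
                 nxyz[1], nxyz[2]))
  }
  px <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else 1
  seek(con, MRC_HEADER_BYTES + {
    # skip extended header if present (NSYMBT, word 24)
    seek(con, 23L * 4L)
    nsymbt <- ri(1L)
    nsymbt
  })
  nval <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nval, size = 1L,
                             signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = nval, size = 2L,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = nval, size = 4L, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = nval, size = 2L,
                             signed = FALSE, endian = "little")),
    stop("unsupported MRC mode ", mode,
         " (supported: 0 int8, 1 int16, 2 float32, 6 uint16)"))
  if (length(vals) != nval) stop("truncated MRC data section")
  arr <- array(vals, dim = nxyz)
  # float32 storage: round-trip through float grid for bit-stable values
  new("ClassAverageStack", images = arr, pixelSize = px,
      sourceId = basename(path))
}

# ---------------------------------------------------------------------------
# STAR

#' Read the first loop table of a STAR file
#'
#' Minimal reader for the RELION STAR dialect: finds the first
#' \code{data_}/\code{loop_} block and returns its rows as a data.frame
#' with the \code{_rln...}-style tags (leading underscore stripped) as
#' column names. Numeric columns are converted.
#'
#' @param path path to a STAR file.
#' @return data.frame (zero rows for an empty loop).
#' @export
readStarTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  li <- which(lines == "loop_")
  if (!length(li)) stop("no loop_ block found in ", path)
  i <- li[1] + 1L
  cols <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    tag <- strsplit(lines[i], "[[:space:]]+")[[1]][1]
    cols <- c(cols, sub("^_", "", tag))
    i <- i + 1L
  }
  if (!length(cols)) stop("loop_ block without column tags in ", path)
  rows <- list()
  while (i <= length(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "data_") || ln == "loop_") break
    fields <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(fields) != length(cols)) {
      stop(sprintf("STAR row with %d fields, expected %d, in %s",
                   length(fields), length(cols), path))
    }
    rows[[length(rows) + 1L]] <- fields
    i <- i + 1L
  }
  if (!length(rows)) {
    df <- as.data.frame(matrix(character(), 0L, length(cols)),
                        stringsAsFactors = FALSE)
    names(df) <- cols
    return(df)
  }
  m <- do.call(rbind, rows)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- cols
  for (j in seq_along(df)) {
    sup <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(sup)) df[[j]] <- sup
  }
  df
}

#' Write a data.frame as a single-block STAR loop
#'
#' @param df data.frame; column names become loop tags (a leading
#'   underscore is added).
#' @param path output path.
#' @param blockName name after \code{data_}.
#' @return \code{path}, invisibly.
#' @export
writeStarTable <- function(df, path, blockName = "") {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("", paste0("data_", blockName), "", "loop_"), con)
  writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
  if (nrow(df)) {
    fmt <- vapply(df, function(col) {
      if (is.numeric(col)) formatC(col, format = "f", digits = 6L)
      else as.character(col)
    }, FUN.VALUE = character(nrow(df)))
    if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
    writeLines(apply(fmt, 1L, paste, collapse = "  "), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Class records: the per-class metadata table
#'
#' A class record table is a plain data.frame with one row per 2D class and
#' (at least) the columns \code{classIndex} (0-based), \code{imageRef}
#' (\code{"N@stackfile"}, 1-based index, RELION convention),
#' \code{pixelSize} (A/px), \code{frcResolution} (A), and
#' \code{classDistribution} (fraction of the particle stack in the class).
#' Optional columns filled in by later stages: \code{estMass},
#' \code{devMeanMass}, \code{devMedianMass}, \code{devModeMass} (kDa),
#' \code{score} and \code{grade} (one of A, B, C, D, F).
#'
#' @param classIndex integer vector, 0-based class indices.
#' @param pixelSize pixel size(s) in A/px.
#' @param frcResolution FRC resolution estimate(s) in A (> 0).
#' @param classDistribution fractions in [0, 1] summing to 1 over a run.
#' @param imageRef optional reference strings; defaults to
#'   \code{"<index+1>@<stackFile>"}.
#' @param stackFile stack filename used to build default \code{imageRef}s.
#' @param grade optional grades in \code{A,B,C,D,F}.
#' @param score optional numeric quality scores.
#' @param checkSum require the distributions to sum to 1 (one
#'   classification run); disable for tables pooling several runs.
#' @return data.frame of class records.
#' @export
classRecords <- function(classIndex, pixelSize, frcResolution,
                         classDistribution, imageRef = NULL,
                         stackFile = "stack.mrcs", grade = NA_character_,
                         score = NA_real_, checkSum = TRUE) {
  n <- length(classIndex)
  if (is.null(imageRef)) {
    imageRef <- sprintf("%d@%s", as.integer(classIndex) + 1L, stackFile)
  }
  df <- data.frame(
    classIndex = as.integer(classIndex),
    imageRef = imageRef,
    pixelSize = rep_len(as.numeric(pixelSize), n),
    frcResolution = rep_len(as.numeric(frcResolution), n),
    classDistribution = rep_len(as.numeric(classDistribution), n),
    estMass = rep_len(NA_real_, n), devMeanMass = rep_len(NA_real_, n),
    devMedianMass = rep_len(NA_real_, n), devModeMass = rep_len(NA_real_, n),
    score = rep_len(as.numeric(score), n),
    grade = rep_len(as.character(grade), n),
    stringsAsFactors = FALSE
  )
  validateClassRecords(df, checkSum = checkSum)
  df
}

validateClassRecords <- function(df, requireScore = FALSE, checkSum = TRUE) {
  need <- c("classIndex", "imageRef", "pixelSize", "frcResolution",
            "classDistribution")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$frcResolution)) || any(df$frcResolution <= 0)) {
    stop("frcResolution must be positive and finite (A)")
  }
  if (any(df$classDistribution < 0 | df$classDistribution > 1)) {
    stop("classDistribution must lie in [0, 1]")
  }
  if (checkSum && nrow(df) && abs(sum(df$classDistribution) - 1) > 1e-6) {
    stop(sprintf("class distributions must sum to 1 (got %.6f)",
                 sum(df$classDistribution)))
  }
  g <- df$grade
  if (!is.null(g) && any(!is.na(g) & !g %in% c("A", "B", "C", "D", "F"))) {
    stop("grade must be one of A, B, C, D, F")
  }
  if (requireScore && (is.null(df$score) || anyNA(df$score))) {
    bad <- if (is.null(df$score)) df$classIndex else df$classIndex[is.na(df$score)]
    stop("record(s) missing score for class index ",
         paste(bad, collapse = ", "))
  }
  invisible(df)
}

#' Write per-class quality scores as a STAR file
#'
#' Emits a single \code{data_}/\code{loop_} block with the image reference
#' column (\code{_rlnReferenceImage}, \code{N@file} 1-based syntax) and the
#' score column \code{_cryosiftScore}, one row per record in input order,
#' so the result is directly inspectable with \code{relion_display}.
#'
#' @param records class record data.frame (see [classRecords()]); every
#'   record must carry a \code{score} and an \code{imageRef}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScoresStar <- function(records, path) {
  validateClassRecords(records, requireScore = TRUE, checkSum = FALSE)
  df <- data.frame(
    rlnReferenceImage = records$imageRef,
    cryosiftScore = records$score,
    rlnClassDistribution = records$classDistribution,
    rlnEstimatedResolutionA = records$frcResolution,
    stringsAsFactors = FALSE
  )
  writeStarTable(df, path, blockName = "cryosift_scores")
}

# synonyms accepted when ingesting metadata tables
.metaSynonyms <- list(
  classIndex = c("classIndex", "class_index", "rlnClassNumber", "class"),
  frcResolution = c("frcResolution", "frc_resolution",
                    "rlnEstimatedResolutionA", "rlnEstimatedResolution",
                    "est_res_A", "resolution"),
  classDistribution = c("classDistribution", "class_distribution",
                        "rlnClassDistribution", "distribution"),
  pixelSize = c("pixelSize", "pixel_size", "rlnPixelSize", "psize_A",
                "rlnImagePixelSize")
)

#' Ingest a per-class metadata table
#'
#' Reads a delimited (CSV) or STAR table carrying, under any of the usual
#' column spellings, the class index, FRC resolution estimate (A), relative
#' class distribution and pixel size (A/px), and returns a class record
#' data.frame. Distributions whose sum deviates from 1 by at most 1% are
#' renormalized to sum exactly 1; larger deviations are an error.
#'
#' @param path path to a \code{.csv} or \code{.star} table.
#' @param stackFile stack filename for default image references.
#' @return class record data.frame, ordered by class index.
#' @export
ingestMetadata <- function(path, stackFile = "stack.mrcs") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (grepl("\\.star$", path, ignore.case = TRUE)) {
    readStarTable(path)
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
  pick <- function(field) {
    hit <- intersect(.metaSynonyms[[field]], names(raw))
    if (!length(hit)) {
      stop("missing column for ", field, " (accepted names: ",
           paste(.metaSynonyms[[field]], collapse = ", "), ")")
    }
    raw[[hit[1]]]
  }
  ci <- as.integer(pick("classIndex"))
  # RELION class numbers are 1-based; normalize to 0-based if they start at 1
  if (length(ci) && min(ci) == 1L && max(ci) == length(ci)) ci <- ci - 1L
  res <- as.numeric(pick("frcResolution"))
  if (any(!is.finite(res)) || any(res <= 0)) {
    stop("frcResolution must be positive (A)")
  }
  dist <- as.numeric(pick("classDistribution"))
  s <- sum(dist)
  if (abs(s - 1) > 0.01) {
    stop(sprintf("class distributions sum to %.4f, more than 1%% from 1", s))
  }
  dist <- dist / s
  px <- as.numeric(pick("pixelSize"))
  df <- classRecords(ci, px, res, dist, stackFile = stackFile)
  extra <- intersect(c("grade", "score"), names(raw))
  for (e in extra) df[[e]] <- raw[[e]]
  validateClassRecords(df)
  df[order(df$classIndex), , drop = FALSE]
}
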