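#' @include AllClasses.R
NULL

#' Read and write segment tables
#'
#' A segment table is stored as CSV with columns `subject`, `activity`,
#' `t_start`, `t_end` (times in seconds).
#'
#' @param segments a segment table data.frame.
#' @param file path of the CSV file.
#' @return `readSegmentTable` returns the validated data.frame;
#'   `writeSegmentTable` invisibly returns `file`.
#' @export
writeSegmentTable <- function(segments, file) {
  .checkSegments(segments)
  utils::write.csv(segments[, c("subject", "activity", "t_start", "t_end")],
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeSegmentTable
#' @export
readSegmentTable <- function(file) {
  .checkSegments(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' Read and write per-sensor signal tables
#'
#' Signals are stored as delimited tables: a comment line `# rate_hz=<r>`
#' carrying the sampling rate, then a header row naming the channels, with
#' the time in seconds as the first column.
#'
#' @param signal samples-by-channels numeric matrix with named columns.
#' @param rate sampling rate in Hz.
#' @param file path of the file.
#' @return `readSignalTable` returns the matrix with attribute `rate`;
#'   `writeSignalTable` invisibly returns `file`.
#' @export
writeSignalTable <- function(signal, rate, file) {
  stopifnot(is.matrix(signal), rate > 0)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%g", rate), con)
  df <- data.frame(time = (seq_len(nrow(signal)) - 1L) / rate, signal)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' @rdname writeSignalTable
#' @export
readSignalTable <- function(file) {
  first <- readLines(file, n = 1L)
  rate <- as.numeric(sub("^# rate_hz=", "", first))
  if (!is.finite(rate) || rate <= 0)
    stop("missing or invalid '# rate_hz=' line in ", file)
  df <- utils::read.csv(file, comment.char = "#")
  x <- as.matrix(df[, -1L, drop = FALSE])
  attr(x, "rate") <- rate
  x
}

#' Read and write PGM grayscale images
#'
#' Minimal portable graymap support for exchanging video frames: `P5`
#' (binary, default) and `P2` (ASCII) variants with maxval 255. Intensities
#' map linearly between `[0, 1]` and 0..255.
#'
#' @param frame numeric intensity matrix in `[0, 1]`.
#' @param file path of the `.pgm` file.
#' @param ascii write the ASCII `P2` variant instead of binary `P5`.
#' @return `readPGM` returns an intensity matrix in `[0, 1]`; `writePGM`
#'   invisibly returns `file`.
#' @export
writePGM <- function(frame, file, ascii = FALSE) {
  stopifnot(is.matrix(frame))
  vals <- as.integer(round(pmin(pmax(frame, 0), 1) * 255))
  h <- nrow(frame); w <- ncol(frame)
  con <- file(file, "wb")
  on.exit(close(con))
  if (ascii) {
    writLines <- c("P2", paste(w, h), "255",
                   apply(matrix(vals, h, w), 1L, paste, collapse = " "))
    writeChar(paste0(paste(writLines, collapse = "\n"), "\n"), con,
              eos = NULL)
  } else {
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(t(matrix(vals, h, w))), con)
  }
  invisible(file)
}

#' @rdname writePGM
#' @export
readPGM <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  readToken <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch)) break
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) break else next
      }
      tok <- paste0(tok, ch)
    }
    tok
  }
  magic <- readToken()
  if (!magic %in% c("P2", "P5")) stop("not a P2/P5 PGM file: ", file)
  w <- as.integer(readToken())
  h <- as.integer(readToken())
  maxval <- as.integer(readToken())
  n <- w * h
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  t(matrix(vals, nrow = w, ncol = h)) / maxval
}

#' Write a frame stream as numbered PGM files
#'
#' @param video a [SilhouetteVideo-class] or an `h x w x n` array.
#' @param dir output directory; files are named `frame_%06d.pgm`.
#' @param indices frames to write (default all).
#' @return Invisibly, the file paths.
#' @export
writeFrames <- function(video, dir, indices = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is(video, "SilhouetteVideo")) {
    if (is.null(indices)) indices <- seq_len(nFrames(video))
    arr <- getFrames(video, indices)
  } else {
    if (is.null(indices)) indices <- seq_len(dim(video)[3L])
    arr <- video[, , indices, drop = FALSE]
  }
  paths <- file.path(dir, sprintf("frame_%06d.pgm", indices))
  for (k in seq_along(indices)) writePGM(arr[, , k], paths[k])
  invisible(paths)
}

#' Read and write feature sets as CSV
#'
#' Feature matrices are exchanged as CSV with columns `subject`,
#' `activity`, `sensor`, then `f_000 ... f_NNN`.
#'
#' @param x a [FeatureSet-class].
#' @param file path of the CSV file.
#' @return `readFeatureSet` returns a [FeatureSet-class]; `writeFeatureSet`
#'   invisibly returns `file`.
#' @export
writeFeatureSet <- function(x, file) {
  stopifnot(is(x, "FeatureSet"))
  f <- t(featureMatrix(x))
  colnames(f) <- sprintf("f_%03d", seq_len(ncol(f)) - 1L)
  df <- data.frame(subject = subjectIds(x), activity = activityLabels(x),
                   sensor = sensorId(x), f, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeFeatureSet
#' @export
readFeatureSet <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  fcols <- grep("^f_[0-9]+$", names(df))
  if (!length(fcols)) stop("no feature columns f_NNN in ", file)
  sensor <- unique(df$sensor)
  if (length(sensor) != 1L) stop("a feature file holds exactly one sensor")
  FeatureSet(t(as.matrix(df[, fcols])), subject = df$subject,
             activity = df$activity, sensor = sensor)
}
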