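# Plain-file interfaces: PNG frame directories, CSV time series and score
# tables, JSON cross-validation reports.

#' Read a frame stack from a directory of PNG files
#'
#' Reads lexicographically ordered 8-bit grayscale PNG frames plus a
#' `timestamps.csv` (column `t_s`) from a directory. Multi-channel PNGs are
#' reduced to their first (R) channel.
#'
#' @param dir directory containing `*.png` and `timestamps.csv`.
#' @return A [FrameStack-class].
#' @export
readFrameStack <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) < 2L) stop("need at least 2 PNG frames in ", dir)
  tsfile <- file.path(dir, "timestamps.csv")
  if (!file.exists(tsfile)) stop("missing ", tsfile)
  ts <- read.csv(tsfile)
  if (!"t_s" %in% names(ts)) stop("timestamps.csv needs a t_s column")
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    round(img * 255)
  })
  FrameStack(frames, ts$t_s)
}

#' Write a frame stack as PNG files plus timestamps.csv
#'
#' @param stack a [FrameStack-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFrameStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack@frames))
    png::writePNG(stack@frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%05d.png", i)))
  write.csv(data.frame(t_s = stack@timestamps),
            file.path(dir, "timestamps.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read/write thermal and signal CSVs
#'
#' `readThermalCsv` expects columns `t_s,temp_c`; `writeBvpCsv` writes
#' `t_s,value`; `writePPIntervalsCsv` writes `peak_time_s,pp_ms,valid` (the
#' first peak has no interval and `pp_ms` is `NA` there);
#' `writeThermalVariabilityCsv` writes `t_s,scaled,filtered_c`.
#'
#' @param path CSV file path.
#' @return `readThermalCsv` returns a [ThermalSeries-class]; writers return
#'   `path` invisibly.
#' @name csv-io
NULL

#' @rdname csv-io
#' @export
readThermalCsv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("t_s", "temp_c") %in% names(df)))
  ThermalSeries(df$temp_c, df$t_s)
}

#' @rdname csv-io
#' @param series,bvp,pp,tv the object to write.
#' @export
writeThermalCsv <- function(series, path) {
  write.csv(data.frame(t_s = series@timestamps, temp_c = series@temps), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname csv-io
#' @export
writeBvpCsv <- function(bvp, path) {
  write.csv(data.frame(t_s = timestamps(bvp), value = bvp@values), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname csv-io
#' @export
readBvpCsv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("t_s", "value") %in% names(df)))
  dt <- diff(df$t_s)
  new("BvpSignal", values = df$value, rate = 1 / stats::median(dt),
      t0 = df$t_s[1L])
}

#' @rdname csv-io
#' @export
writePPIntervalsCsv <- function(pp, path) {
  write.csv(data.frame(peak_time_s = pp@peakTimes,
                       pp_ms = c(NA, pp@intervals),
                       valid = c(NA, pp@valid)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv-io
#' @export
writeThermalVariabilityCsv <- function(tv, path) {
  write.csv(data.frame(t_s = timestamps(tv), scaled = tv@values,
                       filtered_c = tv@filteredC), path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv-io
#' @export
readScoresCsv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("participant_id", "session_id", "vas") %in% names(df)))
  df
}

#' Write a cross-validation report as JSON
#'
#' @param report a [CvReport-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeCvReport <- function(report, path) {
  jsonlite::write_json(list(
    model = report@model, modality = report@modality, level = report@level,
    fold_accuracy = as.list(report@foldAccuracy),
    mean_accuracy = mean(report@foldAccuracy),
    sd_accuracy = sd(report@foldAccuracy),
    mean_f1 = report@meanF1,
    confusion = list(rows = rownames(report@confusion),
                     counts = report@confusion)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
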