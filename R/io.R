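#' Read a time series from a delimited text file
#'
#' Tab- or comma-separated text with a header row; decimal point only.
#' Times must be unique and are sorted increasing; duplicate timestamps
#' and non-numeric cells are rejected with the offending row named.
#'
#' @param path file path.
#' @param time_col,value_col column names (defaults `"time"`, `"value"`).
#' @param time_unit,value_unit unit tags attached to the series.
#' @param basal optional basal level; defaults to the value at the earliest
#'   time.
#' @return a [timeseries()].
#' @export
read_timeseries <- function(path, time_col = "time", value_col = "value",
                            time_unit = "min", value_unit = "",
                            basal = NULL) {
  df <- read_table_(path)
  for (col in c(time_col, value_col)) {
    if (!col %in% names(df)) {
      stop(sprintf("missing column '%s' in %s", col, path), call. = FALSE)
    }
  }
  tt <- check_numeric_(df[[time_col]], time_col, path)
  vv <- check_numeric_(df[[value_col]], value_col, path)
  if (anyDuplicated(tt)) {
    row <- which(duplicated(tt))[1L]
    stop(sprintf("duplicated timestamp t = %g at row %d of %s",
                 tt[row], row, path), call. = FALSE)
  }
  o <- order(tt)
  b <- if (is.null(basal)) vv[o][1L] else basal
  timeseries(tt[o], vv[o], time_unit, value_unit, basal = b)
}

#' Read an OGTT table
#'
#' Expects columns `time_min`, `glucose`, `insulin`, `cpeptide`.
#'
#' @param path file path.
#' @param body_weight body weight in g attached to the record.
#' @return an [ogtt_record()] with basal levels set from the t = 0 row.
#' @export
read_ogtt <- function(path, body_weight = NA_real_) {
  df <- read_table_(path)
  need <- c("time_min", "glucose", "insulin", "cpeptide")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("missing column '%s' in %s", miss[1L], path), call. = FALSE)
  }
  tt <- check_numeric_(df$time_min, "time_min", path)
  o <- order(tt)
  ogtt_record(
    glucose = timeseries(tt[o], check_numeric_(df$glucose, "glucose",
                                               path)[o], "min", "mmol/L"),
    insulin = timeseries(tt[o], check_numeric_(df$insulin, "insulin",
                                               path)[o], "min", "pmol/L"),
    cpeptide = timeseries(tt[o], check_numeric_(df$cpeptide, "cpeptide",
                                                path)[o], "min", "nmol/L"),
    body_weight = body_weight
  )
}

#' Write a time series to a tab-separated file
#'
#' Full float precision (round-trip identity through [read_timeseries()]).
#' A plain-text sidecar `<path>.meta` records the units and basal level.
#'
#' @param x a [timeseries()].
#' @param path output file path.
#' @param sidecar write the unit-metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path, sidecar = TRUE) {
  stopifnot(inherits(x, "gutpk_ts"))
  df <- data.frame(time = format(x$time, digits = 17, trim = TRUE),
                   value = format(x$value, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (sidecar) {
    writeLines(c(sprintf("time_unit: %s", x$time_unit),
                 sprintf("value_unit: %s", x$value_unit),
                 sprintf("basal: %s", format(x$basal, digits = 17))),
               paste0(path, ".meta"))
  }
  invisible(path)
}

# delimiter-sniffing reader: tab default, comma accepted
read_table_ <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) ","
  else ""
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

check_numeric_ <- function(x, col, path) {
  y <- suppressWarnings(as.numeric(x))
  if (anyNA(y)) {
    row <- which(is.na(y))[1L]
    stop(sprintf("non-numeric cell in column '%s', row %d of %s",
                 col, row, path), call. = FALSE)
  }
  y
}
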