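# Readers and writers for the package's plain-text dialects. All tabular
# files are header-bearing delimited text; the delimiter (tab or comma) is
# auto-detected from the header line.

detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!length(hdr)) stop("empty file: ", path)
  if (grepl("\t", hdr)) "\t" else ","
}

read_delim_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  miss <- setdiff(required_cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  df
}

#' Read a spike table from disk
#'
#' Two formats are supported. `tabular`: delimited text with header columns
#' `unit_id`, `spike_time_s`, `region`, `cell_class` (one row per spike).
#' `neurosuite`: a pair of files in the Neurosuite convention -- a `.res` file
#' of integer sample indices (one per line) and a `.clu` file whose first
#' line is the number of clusters followed by one cluster id per spike --
#' converted to seconds with `sampling_rate_hz`, plus an optional metadata
#' sidecar (delimited, columns `unit_id`, `region`, `cell_class`).
#'
#' @param path Path to the tabular file, or to the `.res` file for neurosuite.
#' @param format `"tabular"` or `"neurosuite"`.
#' @param clu_path Path to the `.clu` file (neurosuite); defaults to `path`
#'   with extension replaced by `.clu`.
#' @param sampling_rate_hz Sampling rate used to convert `.res` sample indices
#'   to seconds (neurosuite only).
#' @param metadata_path Optional sidecar with per-unit `region`/`cell_class`
#'   (neurosuite only); units absent from the sidecar get `region = "unknown"`,
#'   `cell_class = "principal"`.
#' @param dup_tol_s Within-unit duplicate-spike tolerance, seconds.
#' @return A [spike_table].
#' @export
read_spike_table <- function(path, format = c("tabular", "neurosuite"),
                             clu_path = NULL, sampling_rate_hz = NULL,
                             metadata_path = NULL, dup_tol_s = 1e-6) {
  format <- match.arg(format)
  if (format == "tabular") {
    df <- read_delim_checked(path, c("unit_id", "spike_time_s", "region", "cell_class"))
    if (!is.numeric(df$spike_time_s)) {
      bad <- which(is.na(suppressWarnings(as.numeric(df$spike_time_s))))[1]
      stop(sprintf("%s: non-numeric spike_time_s at data line %d", path, bad))
    }
    ids <- as.character(df$unit_id)
    spikes <- split(df$spike_time_s, ids)
    meta <- df[!duplicated(ids), c("unit_id", "region", "cell_class")]
    meta <- meta[match(names(spikes), as.character(meta$unit_id)), ]
    spike_table(spikes, region = meta$region, cell_class = meta$cell_class,
                dup_tol_s = dup_tol_s)
  } else {
    if (is.null(sampling_rate_hz) || sampling_rate_hz <= 0)
      stop("neurosuite format requires sampling_rate_hz > 0")
    if (is.null(clu_path)) clu_path <- sub("\\.[^.]*$", ".clu", path)
    if (!file.exists(path)) stop("file not found: ", path)
    if (!file.exists(clu_path)) stop("file not found: ", clu_path)
    res <- scan(path, what = numeric(), quiet = TRUE)
    clu <- scan(clu_path, what = integer(), quiet = TRUE)
    if (length(clu) < 1L) stop(clu_path, ": empty .clu file")
    clu <- clu[-1L]  # first line is the cluster count
    if (length(res) != length(clu))
      stop(sprintf("length mismatch: %d sample indices vs %d cluster ids",
                   length(res), length(clu)))
    times <- res / sampling_rate_hz
    spikes <- split(times, as.character(clu))
    region <- rep("unknown", length(spikes))
    cls <- rep("principal", length(spikes))
    if (!is.null(metadata_path)) {
      md <- read_delim_checked(metadata_path, c("unit_id", "region", "cell_class"))
      m <- match(names(spikes), as.character(md$unit_id))
      region[!is.na(m)] <- md$region[m[!is.na(m)]]
      cls[!is.na(m)] <- md$cell_class[m[!is.na(m)]]
    }
    spike_table(spikes, region = region, cell_class = cls, dup_tol_s = dup_tol_s)
  }
}

#' Write a spike table in the tabular dialect
#'
#' @param x A [spike_table].
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @export
write_spike_table <- function(x, path, sep = "\t") {
  stopifnot(is_spike_table(x))
  df <- data.frame(
    unit_id = rep(x$units$unit_id, x$units$n_spikes),
    spike_time_s = unlist(x$spikes, use.names = FALSE),
    region = rep(x$units$region, x$units$n_spikes),
    cell_class = rep(x$units$cell_class, x$units$n_spikes),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hypnogram interval table
#'
#' Expects delimited text with header columns `state`, `start_s`, `end_s`.
#' Overlapping same-state rows are merged when `merge_touching = TRUE`;
#' overlapping rows with different states are rejected.
#'
#' @param path Input path.
#' @param merge_touching Merge touching/overlapping same-state rows.
#' @return A [hypnogram].
#' @export
read_hypnogram <- function(path, merge_touching = TRUE) {
  df <- read_delim_checked(path, c("state", "start_s", "end_s"))
  if (any(df$end_s <= df$start_s)) {
    bad <- which(df$end_s <= df$start_s)[1]
    stop(sprintf("%s: non-positive duration at data line %d", path, bad))
  }
  hypnogram(df$state, df$start_s, df$end_s, merge_touching = merge_touching)
}

#' Write a hypnogram (or any labeled interval set) as an interval table
#'
#' The same dialect carries substate intervals: pass an `interval_set` whose
#' `label` attribute is `OFF`, `LOW` or `MA`.
#'
#' @param x A [hypnogram] or [interval_set].
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @export
write_hypnogram <- function(x, path, sep = "\t") {
  if (is_hypnogram(x)) {
    df <- data.frame(state = x$state, start_s = x$start, end_s = x$end)
  } else {
    x <- as_interval_set(x)
    lab <- attr(x, "label")
    if (is.null(lab)) lab <- "UNLABELED"
    df <- data.frame(state = rep(lab, nrow(x)), start_s = x$start, end_s = x$end)
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signal trace
#'
#' Two dialects: two-column `(time_s, value)` delimited text on a regular
#' grid, or a `(start, step, values)` header form in which the first two data
#' rows hold `start_s` and `step_s` and the remainder the values
#' (column names `field`, `value`).
#'
#' @param path Input path.
#' @param kind `"emg_power"` or `"lfp_band_power"`.
#' @return A [signal_trace].
#' @export
read_signal_trace <- function(path, kind = c("emg_power", "lfp_band_power")) {
  kind <- match.arg(kind)
  sep <- detect_sep(path)
  hdr <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  if (identical(hdr[1:2], c("time_s", "value"))) {
    df <- read_delim_checked(path, c("time_s", "value"))
    if (nrow(df) < 2L) stop(path, ": need at least 2 samples")
    steps <- diff(df$time_s)
    if (max(abs(steps - steps[1L])) > 1e-6 * steps[1L])
      stop(path, ": time grid is not regular")
    signal_trace(df$time_s[1L], steps[1L], df$value, kind = kind)
  } else if (identical(hdr[1:2], c("field", "value"))) {
    df <- read_delim_checked(path, c("field", "value"))
    get1 <- function(f) {
      v <- df$value[df$field == f]
      if (length(v) != 1L) stop(path, ": expected exactly one '", f, "' row")
      as.numeric(v)
    }
    signal_trace(get1("start_s"), get1("step_s"),
                 as.numeric(df$value[df$field == "v"]), kind = kind)
  } else stop(path, ": unrecognized signal trace header")
}

#' Write a signal trace in the two-column dialect
#'
#' @param x A [signal_trace].
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @export
write_signal_trace <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "signal_trace"))
  df <- data.frame(time_s = trace_times(x), value = x$values)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
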