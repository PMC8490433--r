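# Trace container and event-table file formats.
#
# A trace is stored as a JSON sidecar (metadata, schema version, optional
# ground-truth interval table) plus a sample payload: little-endian IEEE-754
# float32 (.f32), or CSV (time_s, current_pA) for small traces.

TRACE_SCHEMA_VERSION <- "1"

hash_object <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  # version = 2 keeps the serialization stable across R minor versions
  saveRDS(obj, f, version = 2)
  unname(tools::md5sum(f))
}

as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "double", n = length(x), size = 4L, endian = "little")
}

#' Write a trace to disk
#'
#' Writes `<path>.json` (metadata + ground truth) and the sample payload
#' `<path>.f32` (float32 little-endian) or `<path>.csv`. The float32
#' container round-trips bit-exactly through [read_trace()].
#'
#' @param trace A `sense_trace`.
#' @param path Output path stem (no extension).
#' @param format `"f32"` (default) or `"csv"`.
#' @param config_hash Optional provenance hash embedded in the metadata.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("f32", "csv"),
                        config_hash = NULL) {
  stopifnot(inherits(trace, "sense_trace"))
  format <- match.arg(format)
  meta <- list(
    schema_version = TRACE_SCHEMA_VERSION,
    format = format,
    units = trace$meta$units %||% "pA",
    sampling_rate_hz = trace$acq$sampling_rate,
    n_samples = length(trace$current),
    analog_corner_hz = trace$acq$analog_corner,
    filter_order = trace$acq$filter_order,
    filter_type = trace$acq$filter_type,
    concentration_molar = trace$meta$concentration,
    voltage_mV = trace$meta$voltage_mV,
    temperature_K = trace$meta$temperature_K,
    seed = trace$meta$seed,
    master_seed = trace$meta$master_seed,
    config_hash = config_hash)
  if (!is.null(trace$path))
    meta$ground_truth <- data.frame(state = trace$path$state,
                                    t_start_s = trace$path$t_start,
                                    t_end_s = trace$path$t_end,
                                    cycle = trace$path$cycle)
  if (!is.null(trace$cycles)) meta$cycles <- trace$cycles
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (format == "f32") {
    con <- file(paste0(path, ".f32"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(trace$current), con, size = 4L, endian = "little")
  } else {
    n <- length(trace$current)
    df <- data.frame(
      time_s = sprintf("%.9g", (seq_len(n) - 0.5) / trace$acq$sampling_rate),
      current_pA = sprintf("%.9g", trace$current))
    write.table(df, paste0(path, ".csv"), sep = ",", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path Path stem used at write time.
#' @return A `sense_trace` (ground truth restored when present).
#' @export
read_trace <- function(path) {
  meta_file <- paste0(path, ".json")
  if (!file.exists(meta_file)) stop_integrity("missing metadata file %s", meta_file)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  if (!identical(as.character(meta$schema_version), TRACE_SCHEMA_VERSION))
    stop_integrity("trace schema version '%s' needs migration (reader supports '%s')",
                   meta$schema_version, TRACE_SCHEMA_VERSION)
  n <- as.integer(meta$n_samples)
  if (identical(meta$format, "f32")) {
    payload <- paste0(path, ".f32")
    if (!file.exists(payload)) stop_integrity("missing payload %s", payload)
    sz <- file.info(payload)$size
    if (sz != 4L * n)
      stop_integrity("payload length %d bytes inconsistent with %d samples", sz, n)
    con <- file(payload, "rb")
    on.exit(close(con))
    x <- readBin(con, "double", n = n, size = 4L, endian = "little")
  } else {
    payload <- paste0(path, ".csv")
    if (!file.exists(payload)) stop_integrity("missing payload %s", payload)
    df <- utils::read.csv(payload)
    if (nrow(df) != n)
      stop_integrity("payload has %d rows, metadata says %d samples", nrow(df), n)
    x <- as.numeric(df$current_pA)
  }
  acq <- acquisition(sampling_rate = meta$sampling_rate_hz,
                     analog_corner = meta$analog_corner_hz,
                     filter_order = meta$filter_order %||% 4L,
                     filter_type = if (identical(meta$filter_type, "butterworth"))
                       "butterworth" else "bessel",
                     duration = n / meta$sampling_rate_hz)
  path_df <- NULL
  if (!is.null(meta$ground_truth)) {
    gt <- as.data.frame(meta$ground_truth)
    path_df <- structure(
      data.frame(state = gt$state, t_start = gt$t_start_s,
                 t_end = gt$t_end_s, cycle = gt$cycle),
      duration = max(gt$t_end_s) - min(gt$t_start_s), t0 = min(gt$t_start_s),
      class = c("state_path", "data.frame"))
  }
  cycles <- if (!is.null(meta$cycles)) as.data.frame(meta$cycles) else NULL
  structure(list(current = x, acq = acq, path = path_df, cycles = cycles,
                 scheme = NULL,
                 meta = list(units = meta$units,
                             concentration = meta$concentration_molar,
                             voltage_mV = meta$voltage_mV,
                             temperature_K = meta$temperature_K,
                             seed = meta$seed, master_seed = meta$master_seed,
                             config_hash = meta$config_hash)),
            class = "sense_trace")
}

EVENT_COLUMNS <- c("event_id", "cycle", "start_s", "end_s", "t_off_s",
                   "t_on_s", "delta_I_pA", "level_sd_pA", "label")

#' Write an event table as TSV
#'
#' Header columns: event_id, cycle, start_s, end_s, t_off_s, t_on_s,
#' delta_I_pA, level_sd_pA, label. Numeric fields carry 9 significant
#' digits. A provenance hash can be embedded as a `#`-comment first line.
#'
#' @param table An `event_table` (or compatible data.frame).
#' @param path Output file.
#' @param config_hash Optional provenance hash.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path, config_hash = NULL) {
  df <- as.data.frame(table)
  for (cc in setdiff(EVENT_COLUMNS, names(df)))
    df[[cc]] <- if (cc == "label") NA_character_ else NA_real_
  df <- df[, EVENT_COLUMNS, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (cc in names(df)[num])
    out[[cc]] <- ifelse(is.na(df[[cc]]), "NA", sprintf("%.9g", df[[cc]]))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(sprintf("# config_hash: %s", config_hash), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' Columns are matched by name, so reordered files parse correctly; a
#' missing required column raises a schema error naming it.
#'
#' @param path TSV file.
#' @return An `event_table` data.frame.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_integrity("missing event file %s", path)
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  required <- setdiff(EVENT_COLUMNS, "label")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_integrity("event table %s is missing required column(s): %s",
                   path, paste(missing, collapse = ", "))
  if (!"label" %in% names(df)) df$label <- NA_character_
  df <- df[, c(EVENT_COLUMNS, setdiff(names(df), EVENT_COLUMNS)), drop = FALSE]
  structure(df, class = c("event_table", "data.frame"))
}
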