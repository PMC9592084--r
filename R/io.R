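# File formats: TCSPC histogram TSV, ROI trace CSV (+ JSON stimulus
# sidecar), JSON run configuration with schema-style validation.  All
# writers round-trip losslessly through their readers.

#' Write a TCSPC histogram to a tab-separated file
#'
#' Format: `#`-prefixed header lines carrying channel, frame time and laser
#' period, then two tab-separated columns `bin_start_ns` and `counts`.
#' Numeric values are written with full precision so read/write round-trips
#' are exact.
#'
#' @param hist A [tcspc_histogram()].
#' @param path Output file path.
#' @param frame_time_s Optional frame time recorded in the header.
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(hist, path, frame_time_s = NA_real_) {
  stopifnot(inherits(hist, "tcspc_histogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# channel=%s", hist$channel),
    sprintf("# frame_time_s=%.17g", frame_time_s),
    sprintf("# laser_period_ns=%.17g", hist$laser_period),
    "bin_start_ns\tcounts"), con)
  starts <- hist$bin_edges[-length(hist$bin_edges)]
  writeLines(sprintf("%.17g\t%.17g", starts, hist$counts), con)
  invisible(path)
}

parse_header_kv <- function(lines, key) {
  pat <- paste0("^#\\s*", key, "=")
  hit <- grep(pat, lines, value = TRUE)
  if (!length(hit)) stop_invalid("histogram file lacks '# %s=' header", key)
  sub(pat, "", hit[1])
}

#' Read a TCSPC histogram from a tab-separated file
#'
#' @param path File written by [write_histogram_tsv()].
#' @return A [tcspc_histogram()] with attribute `"frame_time_s"`.
#' @export
read_histogram_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  channel <- parse_header_kv(hdr, "channel")
  frame_time <- as.numeric(parse_header_kv(hdr, "frame_time_s"))
  period <- as.numeric(parse_header_kv(hdr, "laser_period_ns"))
  body <- lines[!startsWith(lines, "#")]
  if (!length(body) || body[1] != "bin_start_ns\tcounts")
    stop_invalid("%s line %d: expected column header 'bin_start_ns\\tcounts'",
                 path, length(hdr) + 1L)
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 2L)
  if (length(bad))
    stop_invalid("%s line %d: malformed row", path, length(hdr) + 1L + bad[1])
  mat <- matrix(as.numeric(unlist(rows)), ncol = 2L, byrow = TRUE)
  if (any(!is.finite(mat)))
    stop_invalid("%s: non-numeric values in histogram body", path)
  if (any(mat[, 2] < 0))
    stop_invalid("%s: negative photon counts are not allowed", path)
  starts <- mat[, 1]
  edges <- c(starts, starts[1] + period)
  h <- tcspc_histogram(edges, mat[, 2], channel = channel)
  attr(h, "frame_time_s") <- frame_time
  h
}

#' Write ROI traces to CSV with a JSON stimulus sidecar
#'
#' CSV columns: `roi_id,sensor,time_s,value,units` (one row per sample,
#' traces concatenated).  Stimulus metadata (`stim_time_s` per trace,
#' protocol name) goes to `<path>.json`.
#'
#' @param traces A list of [roi_trace()]s.
#' @param path CSV output path.
#' @param protocol_name Optional protocol label for the sidecar.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path, protocol_name = NULL) {
  if (inherits(traces, "roi_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(roi_id = tr$roi_id, sensor = tr$sensor,
               time_s = sprintf("%.17g", tr$times),
               value = sprintf("%.17g", tr$values), units = tr$units)
  }))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  stim <- lapply(traces, function(tr)
    list(roi_id = tr$roi_id, sensor = tr$sensor,
         stim_time_s = tr$stim_time %||% NA))
  jsonlite::write_json(list(protocol = protocol_name %||% NA, stimuli = stim),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read ROI traces from CSV (+ optional JSON stimulus sidecar)
#'
#' @param path CSV file written by [write_traces_csv()].
#' @return A named list of [roi_trace()]s (names `roi_id.sensor`).
#' @export
read_traces_csv <- function(path) {
  df <- tryCatch(
    read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE),
    error = function(e) stop_invalid("%s: %s", path, conditionMessage(e)))
  need <- c("roi_id", "sensor", "time_s", "value", "units")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_invalid("%s line 1: missing column(s) %s", path,
                 paste(miss, collapse = ", "))
  sidecar <- paste0(path, ".json")
  stim_map <- list()
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    for (s in meta$stimuli)
      stim_map[[paste(s$roi_id, s$sensor, sep = ".")]] <- s$stim_time_s
  }
  keys <- paste(df$roi_id, df$sensor, sep = ".")
  out <- lapply(split(seq_len(nrow(df)), keys), function(i) {
    roi_trace(df$roi_id[i[1]], df$sensor[i[1]],
              as.numeric(df$time_s[i]), as.numeric(df$value[i]),
              stim_time = stim_map[[paste(df$roi_id[i[1]], df$sensor[i[1]],
                                          sep = ".")]],
              units = df$units[i[1]])
  })
  out
}

#' Read bleed-through control pairs from a tab-separated file
#'
#' Columns: `roi_id  red_counts  green_counts`.
#'
#' @param path File path.
#' @return A matrix with columns red, green suitable for
#'   [estimate_bleedthrough()].
#' @export
read_control_pairs <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("roi_id", "red_counts", "green_counts")
  if (!all(need %in% names(df)))
    stop_invalid("%s: expected columns %s", path, paste(need, collapse = ", "))
  cbind(red = df$red_counts, green = df$green_counts)
}

# --- run configuration -------------------------------------------------------

config_default <- function() {
  list(
    seed = 1L,
    tcspc = list(laser_period_ns = 12.5, n_bins = 256L,
                 irf = list(center_ns = 1.5, sigma_ns = 0.2, mode = "fixed"),
                 fit = list(components = 2L, window_ns = 8,
                            objective = "poisson")),
    unmixing = list(ratio = 0.053),
    thresholds = list(min_delta_rcamp = 0.2, max_half_decay = 35,
                      baseline_window = 60),
    calibration = list(kd = 26, na_rest = 13, quench_amplitude_a = 0.74),
    pumps = list(alpha1beta1 = list(k_half = 13, hill_n = 3)),
    synthexp = list(preset = "acsf_vs_cavblock", n_cells = 13L,
                    t_end = 420, render_photons = FALSE))
}

check_field <- function(x, path, type, required = TRUE) {
  leaf <- x
  for (p in path) {
    if (!is.list(leaf) || is.null(leaf[[p]])) {
      if (required) stop_invalid("config: missing required field `%s`",
                                 paste(path, collapse = "."))
      return(invisible(NULL))
    }
    leaf <- leaf[[p]]
  }
  ok <- switch(type,
               number = is.numeric(leaf) && length(leaf) == 1L && is.finite(leaf),
               string = is.character(leaf) && length(leaf) == 1L,
               flag = is.logical(leaf) && length(leaf) == 1L && !is.na(leaf))
  if (!ok) stop_invalid("config: field `%s` must be a %s",
                        paste(path, collapse = "."), type)
  invisible(leaf)
}

#' Validate a run configuration
#'
#' Checks required fields and types and rejects unknown top-level keys;
#' errors name the offending field path.  Pump entries other than
#' `alpha1beta1` (e.g. `alpha3`) must supply `k_half` explicitly.
#'
#' @param config A configuration list (see [read_config()] /
#'   `flimion:::config_default`).
#' @return The validated config, with defaults filled in, invisibly.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) stop_invalid("config must be a list")
  known <- names(config_default())
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop_invalid("config: unknown key(s): %s", paste(unknown, collapse = ", "))
  config <- modifyList(config_default(), config)
  check_field(config, "seed", "number")
  check_field(config, c("tcspc", "laser_period_ns"), "number")
  check_field(config, c("tcspc", "n_bins"), "number")
  check_field(config, c("tcspc", "irf", "center_ns"), "number")
  check_field(config, c("tcspc", "irf", "sigma_ns"), "number")
  check_field(config, c("unmixing", "ratio"), "number")
  check_field(config, c("thresholds", "min_delta_rcamp"), "number")
  check_field(config, c("thresholds", "max_half_decay"), "number")
  check_field(config, c("calibration", "kd"), "number")
  check_field(config, c("calibration", "na_rest"), "number")
  check_field(config, c("calibration", "quench_amplitude_a"), "number")
  for (nm in names(config$pumps)) {
    check_field(config, c("pumps", nm, "k_half"), "number")
    check_field(config, c("pumps", nm, "hill_n"), "number")
  }
  check_field(config, c("synthexp", "preset"), "string")
  check_field(config, c("synthexp", "n_cells"), "number")
  invisible(config)
}

#' Read and validate a JSON run configuration
#'
#' @param path JSON file path.
#' @return The validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e) stop_invalid("%s: %s", path,
                                                   conditionMessage(e)))
  validate_config(cfg)
}

#' Write a run configuration to JSON
#'
#' @param config A configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
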