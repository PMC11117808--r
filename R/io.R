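#' Read a recording from disk
#'
#' Two formats are supported.  `"fixture"` is a plain-text format: header
#' lines `# srate_hz=<float>` and `# channels=<comma list>` (plus an
#' optional `# times_s=<comma list>` for epoched data), followed by one
#' whitespace-separated row of fT values per channel.  A continuous fixture
#' is a single file; an epoched fixture is a directory of per-trial files
#' `trial_<k>.txt` (each in the same format, sharing a `times_s` header)
#' plus a `sensors.txt` geometry file (`id x y z ox oy oz` per line,
#' meters).  `"fif"` delegates to an installed FIF reader when one is
#' available and fails with an informative error otherwise.
#'
#' @param path file (continuous) or directory (epoched) to read.
#' @param format `"fixture"` (default) or `"fif"`.
#' @return A `continuous_recording`, or for an epoched fixture directory a
#'   list with elements `epochs` (`epoched_recording`) and `sensors`
#'   (`sensor_array` or NULL).
#' @export
read_recording <- function(path, format = c("fixture", "fif")) {
  format <- match.arg(format)
  if (format == "fif") {
    stop("FIF reading requires an installed FIF reader, which was not found; ",
         "export the data to the text fixture format instead")
  }
  if (dir.exists(path)) {
    read_epoched_fixture(path)
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    read_continuous_fixture(path)
  }
}

parse_fixture_header <- function(lines, path) {
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    pat <- paste0("^#\\s*", key, "=")
    hit <- grep(pat, hdr, value = TRUE)
    if (length(hit) == 0) return(NULL)
    sub(pat, "", hit[1])
  }
  srate <- get("srate_hz")
  chans <- get("channels")
  if (is.null(srate) || is.null(chans)) {
    bad <- which(!grepl("^#\\s*(srate_hz|channels|times_s)=", hdr))
    stop(sprintf("malformed fixture header in %s%s: need '# srate_hz=' and '# channels=' lines",
                 path,
                 if (length(bad)) sprintf(" (line %d: '%s')", bad[1], hdr[bad[1]]) else ""))
  }
  times <- get("times_s")
  list(srate = as.numeric(srate),
       channels = trimws(strsplit(chans, ",")[[1]]),
       times = if (is.null(times)) NULL else as.numeric(strsplit(times, ",")[[1]]))
}

read_fixture_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- parse_fixture_header(lines, path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) != length(hdr$channels)) {
    stop(sprintf("%s: header names %d channels but file has %d data rows",
                 path, length(hdr$channels), length(body)))
  }
  rows <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  n <- unique(vapply(rows, length, 1L))
  if (length(n) != 1) stop(path, ": data rows have unequal lengths")
  hdr$data <- do.call(rbind, rows)
  hdr
}

read_continuous_fixture <- function(path) {
  p <- read_fixture_matrix(path)
  continuous_recording(p$data, p$srate, p$channels)
}

read_epoched_fixture <- function(path) {
  files <- list.files(path, pattern = "^trial_\\d+\\.txt$", full.names = TRUE)
  if (length(files) == 0) stop("no trial_<k>.txt files in ", path)
  ord <- order(as.integer(sub("^trial_(\\d+)\\.txt$", "\\1", basename(files))))
  files <- files[ord]
  parsed <- lapply(files, read_fixture_matrix)
  p1 <- parsed[[1]]
  if (is.null(p1$times)) stop("epoched fixture trials need a '# times_s=' header")
  data <- array(0, dim = c(length(p1$channels), length(parsed), ncol(p1$data)))
  for (k in seq_along(parsed)) data[, k, ] <- parsed[[k]]$data
  ep <- epoched_recording(data, p1$srate, p1$times, p1$channels)
  sens_path <- file.path(path, "sensors.txt")
  sensors <- if (file.exists(sens_path)) read_sensors(sens_path) else NULL
  list(epochs = ep, sensors = sensors)
}

fmt_num <- function(x) sprintf("%.17g", x)

write_fixture_matrix <- function(path, data, srate, channel_ids, times = NULL) {
  lines <- c(
    paste0("# srate_hz=", fmt_num(srate)),
    paste0("# channels=", paste(channel_ids, collapse = ","))
  )
  if (!is.null(times)) {
    lines <- c(lines, paste0("# times_s=", paste(fmt_num(times), collapse = ",")))
  }
  body <- apply(data, 1, function(r) paste(fmt_num(r), collapse = " "))
  writeLines(c(lines, body), path)
}

#' Write a recording to the text fixture format
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the doubles bit-exactly.
#'
#' @param rec a `continuous_recording` or `epoched_recording`.
#' @param path output file (continuous) or directory (epoched).
#' @param sensors optional `sensor_array` written as `sensors.txt` next to
#'   epoched trials.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sensors = NULL) {
  if (inherits(rec, "continuous_recording")) {
    write_fixture_matrix(path, rec$data, rec$srate, rec$channel_ids)
  } else if (inherits(rec, "epoched_recording")) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_len(rec$n_trials)) {
      write_fixture_matrix(file.path(path, sprintf("trial_%d.txt", k)),
                           rec$data[, k, , drop = TRUE], rec$srate,
                           rec$channel_ids, rec$times)
    }
    if (!is.null(sensors)) write_sensors(sensors, file.path(path, "sensors.txt"))
  } else {
    stop("unsupported recording class: ", paste(class(rec), collapse = "/"))
  }
  invisible(path)
}

#' Read / write sensor geometry (`id x y z ox oy oz` per line, meters)
#'
#' @param path text file path.
#' @return `read_sensors` returns a `sensor_array`.
#' @export
read_sensors <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 7) stop(path, ": expected 7 columns (id x y z ox oy oz)")
  sensor_array(tab[[1]], unname(as.matrix(tab[, 2:4])),
               unname(as.matrix(tab[, 5:7])))
}

#' @rdname read_sensors
#' @param sensors a `sensor_array`.
#' @export
write_sensors <- function(sensors, path) {
  lines <- vapply(seq_along(sensors$channel_ids), function(i) {
    paste(c(sensors$channel_ids[i],
            fmt_num(sensors$positions[i, ]),
            fmt_num(sensors$orientations[i, ])), collapse = " ")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Reports use the keys `objective_trace`, `selected_threshold`, `metrics`,
#' `config` and `log`.  No timestamps are written, so identical runs give
#' byte-identical files.
#'
#' @param report a named list.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(sanitize_json(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

# jsonlite has no representation for +/-Inf; use string sentinels.
sanitize_json <- function(x) {
  if (is.list(x)) return(lapply(x, sanitize_json))
  if (is.numeric(x)) {
    x <- as.vector(x)
    if (any(!is.finite(x) & !is.na(x))) {
      x <- as.list(x)
      x[vapply(x, function(v) is.infinite(v) && v > 0, TRUE)] <- "Inf"
      x[vapply(x, function(v) is.numeric(v) && is.infinite(v) && v < 0, TRUE)] <- "-Inf"
    }
  }
  x
}
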