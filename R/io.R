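# Table, profile and config I/O.
#
# Supplementary-table dialects: "one-per-line" files hold one numeric
# value per line (counts, or total intensities in the same fish order as
# the counts file); "labeled-csv" files hold one row per group, a label
# in the first cell followed by that group's counts. Delimiters are
# sniffed among comma, semicolon, tab and whitespace.

#' Read a per-fish table
#'
#' @param path text file.
#' @param dialect `"one-per-line"` or `"labeled-csv"`.
#' @return a [fish_records()] data.frame. For `"labeled-csv"`, one record
#'   per value with its row label as `group`.
#' @export
read_fish_table <- function(path, dialect = c("one-per-line", "labeled-csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty table: ", path)
  if (dialect == "one-per-line") {
    vals <- suppressWarnings(as.numeric(lines))
    bad <- which(is.na(vals))
    if (length(bad))
      stop(sprintf("non-numeric value at line %d of %s: '%s'",
                   bad[1], path, lines[bad[1]]))
    return(fish_records(vals))
  }
  delim <- sniff_delimiter(lines)
  counts <- numeric(0); groups <- character(0)
  for (i in seq_along(lines)) {
    cells <- trimws(strsplit(lines[i], delim)[[1]])
    cells <- cells[cells != ""]
    if (length(cells) < 2L)
      stop(sprintf("line %d of %s has no values after its label", i, path))
    v <- suppressWarnings(as.numeric(cells[-1]))
    if (any(is.na(v)))
      stop(sprintf("non-numeric cell at line %d of %s: '%s'",
                   i, path, cells[-1][which(is.na(v))[1]]))
    counts <- c(counts, v)
    groups <- c(groups, rep(cells[1], length(v)))
  }
  fish_records(counts, group = groups)
}

sniff_delimiter <- function(lines) {
  for (d in c(",", ";", "\t")) {
    if (all(vapply(lines, function(l) length(strsplit(l, d, fixed = TRUE)[[1]]) > 1L,
                   TRUE)))
      return(d)
  }
  "[[:space:]]+"
}

#' Read paired count and intensity tables
#'
#' Counts and total intensities come in separate one-per-line files in
#' the same fish order; the pairing is by line order.
#'
#' @param counts_path,intensity_path one-per-line files of equal length.
#' @return a [fish_records()] with both `count` and `intensity`.
#' @export
read_paired_tables <- function(counts_path, intensity_path) {
  counts <- read_fish_table(counts_path, "one-per-line")$count
  inten <- read_fish_table(intensity_path, "one-per-line")$count
  if (length(counts) != length(inten))
    stop(sprintf("length mismatch: %d counts vs %d intensities",
                 length(counts), length(inten)))
  fish_records(counts, intensity = inten)
}

#' Write segmented objects as CSV
#'
#' @param seg a `neutro_seg` from [segment_stack()] (or its `objects`
#'   data.frame).
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_objects_csv <- function(seg, path) {
  objects <- if (inherits(seg, "neutro_seg")) seg$objects else seg
  cols <- c("label", "x_um", "y_um", "z_um", "voxels", "volume_um3",
            "total_intensity")
  atomic_write(path, function(tmp)
    write.csv(objects[, cols], tmp, row.names = FALSE))
}

#' Write / read an intensity profile as CSV
#'
#' Columns `position_um,intensity`; the step is recovered from the
#' position column on read.
#'
#' @param profile an [intensity_profile()].
#' @param path CSV path.
#' @return `path` invisibly (write); an [intensity_profile()] (read).
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "intensity_profile"))
  u <- profile$origin + (seq_along(profile$values) - 1) * profile$step
  atomic_write(path, function(tmp)
    write.csv(data.frame(position_um = u, intensity = profile$values),
              tmp, row.names = FALSE))
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("position_um", "intensity") %in% names(d)))
    stop("profile CSV needs columns position_um,intensity: ", path)
  steps <- diff(d$position_um)
  if (any(abs(steps - steps[1]) > 1e-6))
    stop("profile CSV is not uniformly sampled: ", path)
  intensity_profile(d$intensity, step = steps[1], origin = d$position_um[1])
}

#' Load a template library from a directory of profile CSVs
#'
#' Every `*.csv` in the directory becomes a template named after its
#' file.
#'
#' @param dir directory of `position_um,intensity` CSVs.
#' @return a [template_library()].
#' @export
read_template_library <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no profile CSVs in ", dir)
  tpl <- lapply(files, read_profile_csv)
  names(tpl) <- sub("\\.csv$", "", basename(files))
  template_library(tpl)
}

#' Write ground-truth blobs as CSV
#'
#' Columns `x_um,y_um,z_um,rx_um,ry_um,rz_um,peak`.
#'
#' @param blobs list of [blob_spec()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(blobs, path) {
  m <- t(vapply(blobs, function(b) c(b$center, b$radii, b$peak_intensity),
                numeric(7)))
  colnames(m) <- c("x_um", "y_um", "z_um", "rx_um", "ry_um", "rz_um", "peak")
  atomic_write(path, function(tmp)
    write.csv(as.data.frame(m), tmp, row.names = FALSE))
}

#' Flat key-value run configuration
#'
#' Configs are `key = value` lines (strings, numbers, or comma-separated
#' numeric vectors); every pipeline run writes its resolved config next
#' to its outputs so it can be reproduced from config + seed.
#'
#' @param config named list of scalars / numeric vectors.
#' @param path destination file.
#' @return `path` invisibly (write); named list (read).
#' @export
write_run_config <- function(config, path) {
  if (is.null(names(config)) || any(names(config) == ""))
    stop("config entries must be named")
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 15, trim = TRUE),
                                collapse = ","))
  }, character(1))
  atomic_write(path, function(tmp) writeLines(lines, tmp))
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  out <- list()
  for (l in lines) {
    kv <- regmatches(l, regexec("^([^=]+)=(.*)$", l))[[1]]
    if (length(kv) != 3L) stop("malformed config line: ", l)
    key <- trimws(kv[2])
    parts <- trimws(strsplit(kv[3], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (any(is.na(num))) paste(parts, collapse = ",") else num
  }
  out
}
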