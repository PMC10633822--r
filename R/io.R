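#' Write an umbrella dataset to plain-text window files
#'
#' Writes one two-column file per window (time in ps, coordinate in A) and
#' a metadata file with one line per window, `path center spring_constant`
#' (spring in kcal/(mol A^2)) - the de facto umbrella-sampling interchange
#' layout.
#'
#' @param dataset an [umbrella_dataset()].
#' @param dir output directory (created if absent).
#' @param prefix window file-name prefix.
#' @return invisibly, the path of the metadata file.
#' @export
write_umbrella_dataset <- function(dataset, dir, prefix = "window") {
  stopifnot(inherits(dataset, "umbrella_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- character(length(dataset$windows))
  for (i in seq_along(dataset$windows)) {
    w <- dataset$windows[[i]]
    fn <- sprintf("%s_%02d.dat", prefix, i)
    t <- (seq_along(w$samples) - 1) * w$sample_interval
    utils::write.table(
      data.frame(time = t, coordinate = w$samples),
      file.path(dir, fn), row.names = FALSE, col.names = FALSE)
    meta[i] <- sprintf("%s %.6f %.6f", fn, w$center, w$spring)
  }
  meta_path <- file.path(dir, "metadata.dat")
  writeLines(meta, meta_path)
  invisible(meta_path)
}

#' Read an umbrella dataset from a metadata file
#'
#' @param metadata_path path to a metadata file as written by
#'   [write_umbrella_dataset()]; window paths are resolved relative to its
#'   directory.
#' @param temperature temperature of the dataset, K (the interchange layout
#'   does not carry it).
#' @return an [umbrella_dataset()].
#' @export
read_umbrella_dataset <- function(metadata_path, temperature) {
  lines <- readLines(metadata_path)
  lines <- lines[nzchar(trimws(lines))]
  dir <- dirname(metadata_path)
  windows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) < 3L)
      stop("metadata line ", i, ": expected 'path center spring_constant'")
    center <- suppressWarnings(as.numeric(parts[2]))
    spring <- suppressWarnings(as.numeric(parts[3]))
    if (is.na(center) || is.na(spring))
      stop("metadata line ", i, ": non-numeric center or spring constant")
    d <- utils::read.table(file.path(dir, parts[1]))
    dt <- if (nrow(d) > 1L) d[2, 1] - d[1, 1] else 0.1
    umbrella_window(center, spring, temperature, d[[2]],
                    sample_interval = dt)
  })
  umbrella_dataset(windows)
}

#' Write a PMF table
#'
#' Three-column plain text (`r`, `W`, `W_error`) with a header naming the
#' units and the temperature.
#'
#' @param profile a [pmf_profile()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pmf_table <- function(profile, path) {
  stopifnot(inherits(profile, "pmf_profile"))
  err <- profile$W_error
  if (is.null(err)) err <- rep(NA_real_, length(profile$W))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# temperature_K %g", profile$temperature),
               "# r_A W_kJ_per_mol W_error_kJ_per_mol"), con)
  utils::write.table(
    data.frame(r = profile$bin_centers, W = profile$W, W_error = err),
    con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PMF table
#'
#' @param path path to a file written by [write_pmf_table()].
#' @param temperature temperature override, K; by default taken from the
#'   header.
#' @return a [pmf_profile()].
#' @export
read_pmf_table <- function(path, temperature = NULL) {
  lines <- readLines(path)
  hdr <- grep("^# temperature_K", lines, value = TRUE)
  if (is.null(temperature)) {
    if (length(hdr) == 0L)
      stop("no temperature header in ", path, "; pass temperature=")
    temperature <- as.numeric(sub("^# temperature_K\\s+", "", hdr[1]))
  }
  d <- utils::read.table(text = lines[!startsWith(lines, "#")])
  err <- if (ncol(d) >= 3L && !all(is.na(d[[3]]))) d[[3]] else NULL
  pmf_profile(d[[1]], d[[2]], temperature, W_error = err)
}

#' Read a CSV table against a column schema
#'
#' Reads a CSV with a header row, maps columns by name (so column order is
#' free), checks that every required column is present and numeric columns
#' parse cleanly, and reports offending line and column names otherwise.
#'
#' @param path CSV path.
#' @param columns named character vector mapping required column names to
#'   types (`"numeric"` or `"character"`).
#' @return data.frame with the requested columns, in schema order.
#' @export
read_table <- function(path, columns) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       check.names = FALSE)
  missing_cols <- setdiff(names(columns), names(d))
  if (length(missing_cols) > 0L)
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  out <- d[names(columns)]
  for (cn in names(columns)) {
    if (columns[[cn]] == "numeric" && !is.numeric(out[[cn]])) {
      vals <- suppressWarnings(as.numeric(out[[cn]]))
      bad <- which(is.na(vals) & !is.na(out[[cn]]) &
                     nzchar(trimws(out[[cn]])))
      if (length(bad) > 0L)
        stop("non-numeric cell in column '", cn, "' at data line ",
             bad[1], " of ", path)
      out[[cn]] <- vals
    }
  }
  out
}

#' Write a CSV table
#'
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
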