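#' SHG emission spectrum
#'
#' A wavelength-indexed SHG emission record. Counts may be negative after
#' background subtraction.
#'
#' @param wavelength Strictly increasing wavelength grid (nm).
#' @param counts Signal per wavelength (counts), same length.
#' @param meta Named list of metadata (e.g. `sample`, `dye_uM`, `time_tag`).
#' @return An object of class `shg_spectrum`.
#' @export
shg_spectrum <- function(wavelength, counts, meta = list()) {
  check_finite(wavelength, "wavelength")
  check_finite(counts, "counts")
  if (length(wavelength) != length(counts))
    stop("invalid input: wavelength and counts must have equal length", call. = FALSE)
  if (any(diff(wavelength) <= 0))
    stop("invalid input: wavelength grid must be strictly increasing", call. = FALSE)
  structure(list(wavelength = wavelength, counts = counts, meta = meta),
            class = "shg_spectrum")
}

#' @export
print.shg_spectrum <- function(x, ...) {
  cat(sprintf("SHG spectrum: %d points, %.1f-%.1f nm", length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  if (length(x$meta)) cat(" |", paste(names(x$meta), unlist(x$meta),
                                      sep = "=", collapse = ", "))
  cat("\n")
  invisible(x)
}

# internal: write `# key=value` header lines then a two-column table
write_commented_csv <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s=%s", k, format(meta[[k]], digits = 17)), con)
  writeLines(paste(colnames(df), collapse = ","), con)
  # 17 significant digits so numeric round trips are exact
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

# internal: read `# key=value` comment headers into a named list
read_comment_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "#")]
  meta <- list()
  for (ln in lines) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- trimws(substr(kv, 1, eq - 1))
      val <- trimws(substr(kv, eq + 1, nchar(kv)))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

#' Read / write spectrum CSV files
#'
#' Two-column CSV with header `wavelength_nm,counts`; metadata either in
#' embedded `# key=value` comment lines or in a sidecar `<path>.json`
#' (both dialects read; comment lines written).
#'
#' @param path File path.
#' @return [read_spectrum()] returns an `shg_spectrum`;
#'   [write_spectrum()] returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  meta <- read_comment_meta(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- utils::modifyList(jsonlite::read_json(sidecar, simplifyVector = TRUE), meta)
  df <- utils::read.csv(path, comment.char = "#")
  shg_spectrum(df[[1]], df[[2]], meta = meta)
}

#' @rdname read_spectrum
#' @param s An `shg_spectrum`.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "shg_spectrum"))
  df <- data.frame(wavelength_nm = s$wavelength, counts = s$counts)
  write_commented_csv(df, path, s$meta)
  invisible(path)
}
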