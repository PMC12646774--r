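#' Read a height map from disk
#'
#' The grid-text dialect is a plain-text format designed to be
#' human-diffable: four header lines `nrow`, `ncol`, `pitch_x_um`,
#' `pitch_y_um` (each `key value`), optional metadata comment lines
#' `# key: value`, then `nrow` whitespace-separated rows of heights in nm
#' with the token `NaN` marking invalid pixels.
#'
#' @param path file to read.
#' @return a [height_map()].
#' @seealso [write_height_map()]
#' @export
read_height_map <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path)
  hdr <- list()
  meta <- list()
  i <- 1L
  hdr_keys <- c("nrow", "ncol", "pitch_x_um", "pitch_y_um")
  while (i <= length(lines) && length(hdr) < 4L) {
    ln <- trimws(lines[[i]])
    if (nzchar(ln) && !startsWith(ln, "#")) {
      tok <- strsplit(ln, "\\s+")[[1]]
      if (length(tok) != 2L || !(tok[1] %in% hdr_keys))
        stop_fmt("malformed header at line %d: '%s'", i, lines[[i]])
      val <- suppressWarnings(as.numeric(tok[2]))
      if (!is.finite(val))
        stop_fmt("malformed header value at line %d: '%s'", i, lines[[i]])
      hdr[[tok[1]]] <- val
    }
    i <- i + 1L
  }
  if (!all(hdr_keys %in% names(hdr)))
    stop_fmt("incomplete header: missing %s",
             paste(setdiff(hdr_keys, names(hdr)), collapse = ", "))
  nr <- as.integer(hdr$nrow); nc <- as.integer(hdr$ncol)
  # metadata comments between header and data
  while (i <= length(lines) && (startsWith(trimws(lines[[i]]), "#") ||
                                !nzchar(trimws(lines[[i]])))) {
    ln <- trimws(lines[[i]])
    if (startsWith(ln, "#")) {
      kv <- sub("^#\\s*", "", ln)
      m <- regmatches(kv, regexec("^([^:]+):\\s*(.*)$", kv))[[1]]
      if (length(m) == 3L) meta[[trimws(m[2])]] <- m[3]
    }
    i <- i + 1L
  }
  data_lines <- lines[seq.int(i, length.out = length(lines) - i + 1L)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) != nr)
    stop_fmt("expected %d data rows, found %d", nr, length(data_lines))
  rows <- lapply(seq_along(data_lines), function(j) {
    tok <- strsplit(trimws(data_lines[[j]]), "\\s+")[[1]]
    if (length(tok) != nc)
      stop_fmt("row %d has %d values, expected %d (non-rectangular data)",
               j, length(tok), nc)
    suppressWarnings(as.numeric(tok))  # "NaN" -> NaN
  })
  z <- do.call(rbind, rows)
  z[is.nan(z)] <- NA_real_
  height_map(z, pitch_x = hdr$pitch_x_um, pitch_y = hdr$pitch_y_um,
             meta = meta)
}

#' Write a height map to disk
#'
#' Writes the grid-text dialect documented in [read_height_map()].
#' Invalid pixels are written as `NaN`. The writer uses full double
#' precision (`%.17g`) so a write/read round-trip reproduces the heights
#' bitwise.
#'
#' @param hm a [height_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_height_map <- function(hm, path) {
  stopifnot(inherits(hm, "height_map"))
  z <- hm$heights
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("nrow %d", nrow(z)),
               sprintf("ncol %d", ncol(z)),
               sprintf("pitch_x_um %.17g", hm$pitch_x),
               sprintf("pitch_y_um %.17g", hm$pitch_y)), con)
  scal <- hm$meta[vapply(hm$meta, function(v)
    is.character(v) || is.numeric(v) || is.logical(v), logical(1))]
  scal <- scal[lengths(scal) == 1L]
  for (k in names(scal))
    writeLines(sprintf("# %s: %s", k, format(scal[[k]])), con)
  txt <- matrix(sprintf("%.17g", z), nrow(z), ncol(z))
  txt[!hm$valid] <- "NaN"
  writeLines(apply(txt, 1L, paste, collapse = " "), con)
  invisible(path)
}
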