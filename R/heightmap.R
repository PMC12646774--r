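#' Construct a surface height map
#'
#' A `height_map` is the raw object all surface metrology operates on: a
#' rectangular grid of surface heights in nanometres on a regular pixel
#' lattice, together with a per-pixel validity mask and the pixel pitch in
#' micrometres. Invalid pixels (typically arising where steep or
#' out-of-focus regions defeat white-light interferometry) carry `NA` in
#' the height grid and are never read as heights.
#'
#' @param heights numeric matrix of heights in nm; `NA` marks invalid
#'   pixels. Row 1 is the top scan line.
#' @param valid optional logical matrix; defaults to `!is.na(heights)`.
#'   Where `valid` is `FALSE` the stored height is forced to `NA`.
#' @param pitch_x,pitch_y pixel pitch in µm along columns (x) and rows (y).
#' @param meta named list of free-form metadata (specimen id, scan index,
#'   pigment region tag, ...).
#' @return an object of class `height_map` with elements `heights`,
#'   `valid`, `pitch_x`, `pitch_y`, `meta`.
#' @examples
#' hm <- height_map(matrix(rnorm(12), 3, 4), pitch_x = 0.83, pitch_y = 0.83)
#' coverage(hm)
#' @export
height_map <- function(heights, valid = NULL, pitch_x = 1, pitch_y = 1,
                       meta = list()) {
  if (!is.matrix(heights) || !is.numeric(heights))
    stop_fmt("'heights' must be a numeric matrix")
  if (nrow(heights) < 2L || ncol(heights) < 2L)
    stop_fmt("height map must be at least 2 x 2 pixels (got %d x %d)",
             nrow(heights), ncol(heights))
  if (!is.numeric(pitch_x) || length(pitch_x) != 1L || !is.finite(pitch_x) ||
      pitch_x <= 0)
    stop_fmt("'pitch_x' must be a single positive number (um per pixel)")
  if (!is.numeric(pitch_y) || length(pitch_y) != 1L || !is.finite(pitch_y) ||
      pitch_y <= 0)
    stop_fmt("'pitch_y' must be a single positive number (um per pixel)")
  if (is.null(valid)) {
    valid <- !is.na(heights)
  } else {
    if (!is.matrix(valid) || !is.logical(valid) ||
        !identical(dim(valid), dim(heights)))
      stop_fmt("'valid' must be a logical matrix matching dim(heights)")
    valid <- valid & !is.na(heights)
  }
  storage.mode(heights) <- "double"
  heights[!valid] <- NA_real_
  if (any(!is.finite(heights[valid])))
    stop_fmt("heights at valid pixels must be finite")
  structure(
    list(heights = heights, valid = valid,
         pitch_x = as.numeric(pitch_x), pitch_y = as.numeric(pitch_y),
         meta = as.list(meta)),
    class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("height map: %d x %d px, pitch %.4g x %.4g um, coverage %.1f%%\n",
              nrow(x$heights), ncol(x$heights), x$pitch_x, x$pitch_y,
              100 * coverage(x)))
  if (isTRUE(x$meta$corrected)) cat("  form-corrected\n")
  invisible(x)
}

#' @export
dim.height_map <- function(x) dim(x$heights)

#' Fraction of valid pixels in a height map
#'
#' @param hm a [height_map()].
#' @return fraction in \[0, 1\]: valid pixel count over total pixel count.
#' @export
coverage <- function(hm) {
  stopifnot(inherits(hm, "height_map"))
  sum(hm$valid) / length(hm$valid)
}

#' Heights at valid pixels
#'
#' @param hm a [height_map()].
#' @return numeric vector of the heights (nm) at valid pixels only.
#' @export
valid_heights <- function(hm) {
  stopifnot(inherits(hm, "height_map"))
  hm$heights[hm$valid]
}
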