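#' Polynomial form correction of a height map
#'
#' Removes the large-scale form (tilt and curvature) from a scan before
#' texture parameters are computed. Eggshell fragments present an
#' approximately spherical surface to the profilometer, so by default a
#' bivariate polynomial of total degree 2 is least-squares fitted to the
#' valid pixels and subtracted; the result is then shifted so that the
#' lowest valid height is exactly 0 nm. The validity mask is unchanged.
#'
#' Pixel coordinates are centred and rescaled to \[-1, 1\] x \[-1, 1\]
#' before the fit so the Vandermonde design stays well conditioned even on
#' large grids.
#'
#' @param hm a [height_map()].
#' @param order total polynomial degree (default 2).
#' @return a [height_map()] with form removed, minimum valid height 0 nm,
#'   and `meta$corrected = TRUE`.
#' @export
plane_correct <- function(hm, order = 2L) {
  stopifnot(inherits(hm, "height_map"))
  if (!is_count(order, min = 0L)) stop_fmt("'order' must be a non-negative integer")
  order <- as.integer(order)
  p <- (order + 1L) * (order + 2L) / 2L
  nv <- sum(hm$valid)
  if (nv < p)
    stop_fmt("form fit of degree %d needs >= %d valid pixels, have %d",
             order, p, nv)
  nr <- nrow(hm$heights); nc <- ncol(hm$heights)
  # centred, scaled pixel coordinates
  xs <- if (nc > 1L) seq(-1, 1, length.out = nc) else 0
  ys <- if (nr > 1L) seq(-1, 1, length.out = nr) else 0
  idx <- which(hm$valid, arr.ind = TRUE)
  x <- xs[idx[, 2L]]; y <- ys[idx[, 1L]]
  X <- poly_design(x, y, order)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop_fmt("rank-deficient form fit (valid pixels degenerate, e.g. collinear)")
  beta <- qr.coef(qrX, hm$heights[hm$valid])
  z <- hm$heights
  z[hm$valid] <- hm$heights[hm$valid] - drop(X %*% beta)
  z[hm$valid] <- z[hm$valid] - min(z[hm$valid])
  out <- hm
  out$heights <- z
  out$meta$corrected <- TRUE
  out
}

poly_design <- function(x, y, order) {
  cols <- list()
  for (d in 0:order)
    for (i in 0:d)
      cols[[length(cols) + 1L]] <- x^(d - i) * y^i
  do.call(cbind, cols)
}

#' Areal surface texture parameters of a height map
#'
#' Computes the height-distribution parameters over the valid pixels of a
#' scan: Sa (arithmetic mean absolute deviation from the mean plane, nm),
#' Sq (root-mean-square deviation, nm), Ssk (skewness: negative =
#' valley-dominated, positive = peak-dominated) and Sku (kurtosis: 3 is
#' the Gaussian reference, above 3 indicates sharp peaks or deep troughs).
#' With mean valid height \eqn{\bar z} and n valid pixels:
#' \deqn{S_a = \frac1n\sum|z-\bar z|,\quad
#'       S_q = \sqrt{\frac1n\sum(z-\bar z)^2},\quad
#'       S_{sk} = \frac{\frac1n\sum(z-\bar z)^3}{S_q^3},\quad
#'       S_{ku} = \frac{\frac1n\sum(z-\bar z)^4}{S_q^4}.}
#' Moments use the population (1/n) convention throughout; only valid
#' pixels enter the sums.
#'
#' A perfectly flat surface (Sq = 0) has no defined skewness or kurtosis:
#' Sa and Sq are returned as 0 with `Ssk`/`Sku` `NA` and
#' `degenerate = TRUE`. Texture on a map that has not passed
#' [plane_correct()] triggers a warning (form contaminates the moments)
#' but is computed.
#'
#' @param hm a [height_map()].
#' @return object of class `texture_summary`: a list with `Sa`, `Sq`,
#'   `Ssk`, `Sku`, `n_valid`, `coverage`, `corrected`, `degenerate`,
#'   plus the scan metadata.
#' @examples
#' hm <- height_map(matrix(c(0, 0, 0, 4), 2, 2))
#' compute_texture(plane_correct(hm, order = 0))
#' @export
compute_texture <- function(hm) {
  stopifnot(inherits(hm, "height_map"))
  z <- valid_heights(hm)
  n <- length(z)
  if (n < 2L) stop_fmt("texture needs >= 2 valid pixels, have %d", n)
  corrected <- isTRUE(hm$meta$corrected)
  if (!corrected)
    warn_fmt("computing texture on an uncorrected height map; run plane_correct() first")
  zc <- z - mean(z)
  Sa <- mean(abs(zc))
  Sq <- sqrt(mean(zc^2))
  if (Sq == 0) {
    Ssk <- NA_real_; Sku <- NA_real_; degenerate <- TRUE
    warn_fmt("flat surface (Sq = 0): Ssk and Sku undefined")
  } else {
    Ssk <- mean(zc^3) / Sq^3
    Sku <- mean(zc^4) / Sq^4
    degenerate <- FALSE
  }
  structure(
    list(Sa = Sa, Sq = Sq, Ssk = Ssk, Sku = Sku,
         n_valid = n, coverage = coverage(hm), corrected = corrected,
         degenerate = degenerate, meta = hm$meta),
    class = "texture_summary")
}

#' @export
print.texture_summary <- function(x, ...) {
  cat(sprintf("Sa = %.4g nm, Sq = %.4g nm, Ssk = %.4g, Sku = %.4g\n",
              x$Sa, x$Sq, x$Ssk, x$Sku))
  cat(sprintf("  %d valid px (coverage %.1f%%)%s\n", x$n_valid,
              100 * x$coverage,
              if (x$corrected) ", form-corrected" else ""))
  invisible(x)
}

#' Coverage-based scan QC: accept, crop, or reject
#'
#' Scans whose pixel coverage falls below the threshold (default 40%) are
#' inspected for salvageable structure: missing pixels concentrate at scan
#' edges and corners where the curved shell falls out of the focal plane,
#' so border rows/columns whose own valid fraction is below the threshold
#' are trimmed iteratively (worst border line first) until every remaining
#' border line meets it. The crop is accepted if its coverage reaches the
#' threshold and its area is at least `min_area` pixels; otherwise a
#' rejection report is returned (rejection is a report, not an error —
#' excluded scans are data to be counted, not exceptions).
#'
#' @param hm a [height_map()].
#' @param coverage_threshold minimum acceptable valid-pixel fraction,
#'   in (0, 1\]; default 0.40.
#' @param min_area minimum pixel count of an accepted crop (default 2500,
#'   i.e. a 50 x 50 px evaluation area; texture parameters on a smaller
#'   patch are not comparable with full-field scans).
#' @return the (possibly cropped) [height_map()] on acceptance, else an
#'   object of class `scan_rejection` with a `reason` of
#'   `"low-coverage"` or `"too-small-after-crop"`.
#' @export
assess_and_crop <- function(hm, coverage_threshold = 0.40,
                            min_area = 2500L) {
  stopifnot(inherits(hm, "height_map"))
  if (!is_prob(coverage_threshold) || coverage_threshold <= 0)
    stop_fmt("'coverage_threshold' must be in (0, 1]")
  if (coverage(hm) >= coverage_threshold) return(hm)
  v <- hm$valid
  r1 <- 1L; r2 <- nrow(v); c1 <- 1L; c2 <- ncol(v)
  repeat {
    if (r2 - r1 < 1L || c2 - c1 < 1L) break
    fr <- c(top    = mean(v[r1, c1:c2]),
            bottom = mean(v[r2, c1:c2]),
            left   = mean(v[r1:r2, c1]),
            right  = mean(v[r1:r2, c2]))
    below <- fr < coverage_threshold
    if (!any(below)) break
    worst <- names(fr)[below][which.min(fr[below])]
    switch(worst,
           top = r1 <- r1 + 1L, bottom = r2 <- r2 - 1L,
           left = c1 <- c1 + 1L, right = c2 <- c2 - 1L)
  }
  sub <- v[r1:r2, c1:c2, drop = FALSE]
  cov <- mean(sub)
  area <- length(sub)
  reject <- function(reason) {
    structure(list(reason = reason, coverage = coverage(hm),
                   crop_coverage = cov, crop_area = area,
                   bounds = c(row_min = r1, row_max = r2,
                              col_min = c1, col_max = c2),
                   meta = hm$meta),
              class = "scan_rejection")
  }
  if (cov < coverage_threshold) return(reject("low-coverage"))
  if (area < min_area) return(reject("too-small-after-crop"))
  out <- hm
  out$heights <- hm$heights[r1:r2, c1:c2, drop = FALSE]
  out$valid <- sub
  out$meta$crop_bounds <- c(row_min = r1, row_max = r2,
                            col_min = c1, col_max = c2)
  out
}

#' @export
print.scan_rejection <- function(x, ...) {
  cat(sprintf("scan rejected (%s): coverage %.1f%%, best crop %.1f%% over %d px\n",
              x$reason, 100 * x$coverage, 100 * x$crop_coverage, x$crop_area))
  invisible(x)
}
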