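#' Specification of a synthetic eggshell scan
#'
#' Describes one synthetic profilometer scan: a spherical-cap base form
#' (the curvature the fragment presents to the objective), a spatially
#' correlated Gaussian height field (the background texture), punched
#' pore-like pits (which drive skewness negative, as on real porous
#' eggshell), optional added peaks (positive skew), and missing pixels
#' concentrated at scan edges and corners (where the curved surface falls
#' out of the interferometer's focal plane).
#'
#' Defaults mirror a 20x-objective white-light interferometry scan:
#' 768 x 576 pixels at 0.8289 µm pitch (636.61 x 477.25 µm² field) on a
#' shell of 20 mm local radius.
#'
#' @param nrow,ncol grid size in pixels.
#' @param pitch pixel pitch, µm (isotropic).
#' @param curvature_radius_um radius of the spherical-cap base form, µm;
#'   `Inf` = flat.
#' @param field_sd marginal standard deviation of the Gaussian texture
#'   field, nm.
#' @param corr_length correlation length of the field, pixels (Gaussian
#'   kernel sd; kernel truncated at 4 correlation lengths).
#' @param pore_density pores per 1000 px².
#' @param pore_depth_mean,pore_depth_sd pore depth distribution, nm
#'   (depths truncated at 0).
#' @param pore_radius pore opening radius, pixels.
#' @param peak_density,peak_height_mean,peak_height_sd,peak_radius
#'   analogous parameters for added peaks.
#' @param edge_dropout fraction of pixels invalidated, in \[0, 1);
#'   placement is biased toward edges/corners.
#' @param seed integer seed; the same spec reproduces the surface
#'   bit-identically.
#' @return object of class `surface_spec`.
#' @export
surface_spec <- function(nrow = 576L, ncol = 768L, pitch = 0.8289,
                         curvature_radius_um = 20000,
                         field_sd = 200, corr_length = 3,
                         pore_density = 2, pore_depth_mean = 800,
                         pore_depth_sd = 200, pore_radius = 3,
                         peak_density = 0, peak_height_mean = 800,
                         peak_height_sd = 200, peak_radius = 3,
                         edge_dropout = 0.15, seed = 1L) {
  stopifnot(is_count(nrow, 2L), is_count(ncol, 2L),
            pitch > 0, curvature_radius_um > 0,
            field_sd >= 0, corr_length > 0,
            pore_density >= 0, pore_depth_mean >= 0, pore_depth_sd >= 0,
            pore_radius > 0, peak_density >= 0, peak_radius > 0,
            edge_dropout >= 0, edge_dropout < 1)
  structure(as.list(environment()), class = "surface_spec")
}

#' Generate a synthetic height map
#'
#' Builds the surface described by a [surface_spec()]:
#' heights = spherical-cap form + correlated Gaussian field − pores +
#' peaks. The field is seeded white noise convolved with a separable
#' (isotropic) Gaussian kernel of the stated correlation length and
#' rescaled so its marginal sd is exactly `field_sd` (using the
#' theoretical kernel norm, so the field stays exactly Gaussian). Pores
#' and peaks are smooth radial-cosine bumps
#' \eqn{d\,(1+\cos(\pi r/r_0))/2} for \eqn{r \le r_0}, so they survive
#' second-order form correction. The mask invalidates `edge_dropout` of
#' the pixels, sampled with probability decaying exponentially with
#' distance from the nearest edge.
#'
#' @param spec a [surface_spec()].
#' @return a [height_map()] (uncorrected; run [plane_correct()] before
#'   [compute_texture()]).
#' @examples
#' hm <- gen_height_map(surface_spec(nrow = 64, ncol = 64, seed = 7))
#' compute_texture(plane_correct(hm))
#' @export
gen_height_map <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  with_local_seed(spec$seed, {
    nr <- as.integer(spec$nrow); nc <- as.integer(spec$ncol)
    z <- matrix(0, nr, nc)
    # spherical-cap base form (nm; pitch in um, radius in um)
    if (is.finite(spec$curvature_radius_um)) {
      R <- spec$curvature_radius_um
      x <- (seq_len(nc) - (nc + 1) / 2) * spec$pitch
      y <- (seq_len(nr) - (nr + 1) / 2) * spec$pitch
      d2 <- outer(y^2, x^2, `+`)
      if (max(d2) >= R^2)
        stop_fmt("scan field exceeds the cap: curvature radius too small")
      z <- z + 1000 * (sqrt(R^2 - d2) - R)  # dome, apex at centre, in nm
    }
    # correlated Gaussian field by separable kernel convolution
    if (spec$field_sd > 0) {
      m <- ceiling(4 * spec$corr_length)
      g <- stats::dnorm(seq(-m, m), sd = spec$corr_length)
      W <- matrix(stats::rnorm((nr + 2 * m) * (nc + 2 * m)),
                  nr + 2 * m, nc + 2 * m)
      Br <- band_matrix(nr, m, g)
      Bc <- band_matrix(nc, m, g)
      Z <- Br %*% W %*% t(Bc)
      z <- z + Z * (spec$field_sd / sum(g^2))
    }
    # pores (subtract) and peaks (add)
    z <- punch_features(z, spec$pore_density, spec$pore_depth_mean,
                        spec$pore_depth_sd, spec$pore_radius, sign = -1)
    z <- punch_features(z, spec$peak_density, spec$peak_height_mean,
                        spec$peak_height_sd, spec$peak_radius, sign = +1)
    # edge-biased dropout
    valid <- matrix(TRUE, nr, nc)
    n_drop <- round(spec$edge_dropout * nr * nc)
    if (n_drop > 0) {
      er <- pmin(seq_len(nr) - 1L, nr - seq_len(nr))
      ec <- pmin(seq_len(nc) - 1L, nc - seq_len(nc))
      dedge <- outer(er, ec, pmin)
      w <- exp(-dedge / 6)
      drop <- sample.int(nr * nc, n_drop, prob = as.vector(w))
      valid[drop] <- FALSE
    }
    z[!valid] <- NA_real_
    height_map(z, valid = valid, pitch_x = spec$pitch,
               pitch_y = spec$pitch,
               meta = list(seed = spec$seed, generator = "gen_height_map"))
  })
}

# n x (n + 2m) banded convolution matrix with kernel g (length 2m + 1)
band_matrix <- function(n, m, g) {
  B <- matrix(0, n, n + 2L * m)
  for (k in seq_along(g)) B[cbind(seq_len(n), seq_len(n) + k - 1L)] <- g[k]
  B
}

punch_features <- function(z, density, amp_mean, amp_sd, radius, sign) {
  if (density <= 0) return(z)
  nr <- nrow(z); nc <- ncol(z)
  n_feat <- stats::rpois(1L, density * nr * nc / 1000)
  if (n_feat == 0L) return(z)
  r0 <- ceiling(radius)
  off <- seq(-r0, r0)
  rad <- sqrt(outer(off^2, off^2, `+`))
  stamp <- ifelse(rad <= radius, (1 + cos(pi * rad / radius)) / 2, 0)
  ci <- sample.int(nr, n_feat, replace = TRUE)
  cj <- sample.int(nc, n_feat, replace = TRUE)
  amp <- pmax(stats::rnorm(n_feat, amp_mean, amp_sd), 0)
  for (k in seq_len(n_feat)) {
    ri <- (ci[k] - r0):(ci[k] + r0)
    rj <- (cj[k] - r0):(cj[k] + r0)
    ok_i <- ri >= 1L & ri <= nr
    ok_j <- rj >= 1L & rj <= nc
    z[ri[ok_i], rj[ok_j]] <- z[ri[ok_i], rj[ok_j]] +
      sign * amp[k] * stamp[ok_i, ok_j, drop = FALSE]
  }
  z
}
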