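#' Repeatability of scan measurements within specimens
#'
#' Intraclass correlation from the one-way random-effects model
#' \eqn{y_{ij} = \mu + b_i + e_{ij}}:
#' \eqn{R = \sigma^2_b / (\sigma^2_b + \sigma^2_w)}, the proportion of
#' variance attributable to differences between specimens. Variance
#' components come from the ANOVA estimator for balanced designs
#' (\eqn{\hat\sigma^2_w = MS_W}, \eqn{\hat\sigma^2_b = (MS_B - MS_W)/k})
#' and from REML ([lme4::lmer()]) for unbalanced ones; negative ANOVA
#' estimates are truncated at 0. Confidence intervals by parametric
#' bootstrap: data are re-simulated from the fitted Gaussian components
#' and R re-estimated per replicate.
#'
#' Specimens contributing a single scan carry no within-specimen
#' information and are dropped with a warning. If every value is
#' identical the decomposition is degenerate and R is defined as 1.
#'
#' @param values numeric vector of scan-level measurements.
#' @param specimen grouping vector (one specimen id per scan).
#' @param nboot parametric-bootstrap replicates for the CI (default
#'   1000; 0 disables the CI).
#' @param conf CI level (default 0.95).
#' @param seed optional seed for the bootstrap.
#' @return object of class `repeatability_result`: `R`, `var_between`,
#'   `var_within`, `ci` (or `NULL`), `n_specimens`, `n_scans`,
#'   `degenerate`, `method`.
#' @export
repeatability <- function(values, specimen, nboot = 1000L, conf = 0.95,
                          seed = NULL) {
  stopifnot(length(values) == length(specimen))
  ok <- !is.na(values) & !is.na(specimen)
  values <- values[ok]; specimen <- as.character(specimen[ok])
  counts <- table(specimen)
  single <- names(counts)[counts < 2L]
  if (length(single)) {
    warn_fmt("dropping %d specimen(s) with a single scan from the repeatability test",
             length(single))
    keep <- !(specimen %in% single)
    values <- values[keep]; specimen <- specimen[keep]
    counts <- table(specimen)
  }
  if (length(counts) < 2L)
    stop_fmt("repeatability needs >= 2 specimens with >= 2 scans each")
  g <- factor(specimen)
  n <- length(values); a <- nlevels(g)
  if (stats::var(values) == 0) {
    return(structure(list(R = 1, var_between = 0, var_within = 0,
                          ci = NULL, n_specimens = a, n_scans = n,
                          degenerate = TRUE, method = "degenerate"),
                     class = "repeatability_result"))
  }
  balanced <- length(unique(counts)) == 1L
  est <- function(v, grp) {
    if (balanced) {
      k <- unname(counts[1L])
      gm <- tapply(v, grp, mean)
      msb <- k * sum((gm - mean(v))^2) / (a - 1)
      msw <- sum((v - gm[grp])^2) / (n - a)
      vb <- max(0, (msb - msw) / k)
      c(vb = vb, vw = msw)
    } else {
      fit <- lme4::lmer(v ~ 1 + (1 | grp),
                        data = data.frame(v = v, grp = grp), REML = TRUE)
      vc <- as.data.frame(lme4::VarCorr(fit))
      c(vb = vc$vcov[vc$grp == "grp"], vw = vc$vcov[vc$grp == "Residual"])
    }
  }
  vc <- est(values, g)
  R <- if (sum(vc) == 0) 1 else unname(vc["vb"] / sum(vc))
  ci <- NULL
  if (nboot > 0L) {
    ci <- with_local_seed(seed, {
      k_i <- as.integer(counts[levels(g)])
      Rb <- vapply(seq_len(nboot), function(b) {
        bm <- rep(stats::rnorm(a, 0, sqrt(vc["vb"])), k_i)
        v <- bm + stats::rnorm(n, 0, sqrt(vc["vw"]))
        vcb <- est(v, factor(rep(levels(g), k_i)))
        if (sum(vcb) == 0) 1 else unname(vcb["vb"] / sum(vcb))
      }, 0)
      stats::quantile(Rb, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                      names = FALSE)
    })
  }
  structure(list(R = R, var_between = unname(vc["vb"]),
                 var_within = unname(vc["vw"]), ci = ci,
                 n_specimens = a, n_scans = n, degenerate = FALSE,
                 method = if (balanced) "ANOVA" else "REML"),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("repeatability R = %.4f (%s; %d specimens, %d scans)\n",
              x$R, x$method, x$n_specimens, x$n_scans))
  if (!is.null(x$ci))
    cat(sprintf("  CI [%.4f, %.4f]\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' Two-stage aggregation of scan-level texture values
#'
#' Scan values are first averaged per specimen across retained scans and
#' specimen means are then averaged at the species level — never a pooled
#' single-stage mean, so a specimen with many scans does not dominate its
#' species. Counts are carried through at both stages.
#'
#' @param df data frame with columns `species`, `specimen`, and the
#'   value columns named in `values`.
#' @param values character vector of value column names (default: all
#'   numeric columns other than keys).
#' @return list with data frames `specimens` (species, specimen,
#'   n_scans, means) and `species` (species, n_specimens, means).
#' @export
aggregate_texture <- function(df, values = NULL) {
  stopifnot(all(c("species", "specimen") %in% names(df)))
  if (is.null(values))
    values <- names(df)[vapply(df, is.numeric, TRUE) &
                        !names(df) %in% c("scan", "specimen")]
  if (!length(values)) stop_fmt("no value columns to aggregate")
  key1 <- interaction(df$species, df$specimen, drop = TRUE, sep = "\r")
  spec_means <- lapply(values, function(v) tapply(df[[v]], key1, mean))
  ks <- strsplit(names(spec_means[[1]]), "\r", fixed = TRUE)
  specimens <- data.frame(
    species = vapply(ks, `[`, "", 1L),
    specimen = vapply(ks, `[`, "", 2L),
    n_scans = as.integer(table(key1)[names(spec_means[[1]])]),
    stringsAsFactors = FALSE)
  for (i in seq_along(values)) specimens[[values[i]]] <-
    as.vector(spec_means[[i]])
  sp <- factor(specimens$species)
  species <- data.frame(species = levels(sp),
                        n_specimens = as.integer(table(sp)),
                        stringsAsFactors = FALSE)
  for (v in values)
    species[[v]] <- as.vector(tapply(specimens[[v]], sp, mean))
  list(specimens = specimens[order(specimens$species, specimens$specimen), ],
       species = species)
}

#' Cook's-distance influence filter with species-level retention rules
#'
#' Cook's distance is computed for every specimen value of one response
#' from the intercept-only linear model over all specimens, and specimens
#' with \eqn{D_i} above the cutoff are flagged influential. Retention
#' then follows the species-level rules: a species represented by a
#' single specimen loses it if flagged; a multi-specimen species whose
#' specimens are all flagged retains all of them (the species is
#' consistently extreme, not internally contaminated); otherwise only the
#' flagged specimens are excluded. The filter is applied once per
#' response — it is not iterated to a fixed point.
#'
#' @param values numeric vector of specimen-level values for one
#'   response.
#' @param species species id per specimen.
#' @param cutoff numeric cutoff on D, or the string `"4/n"` (default).
#' @return object of class `cooks_filter_report`: data frame `report`
#'   (species, value, D, flagged, kept, rule) plus `cutoff` and counts.
#' @export
cooks_filter <- function(values, species, cutoff = "4/n") {
  n <- length(values)
  stopifnot(length(species) == n)
  if (n < 3L) stop_fmt("Cook's filter needs >= 3 specimens, have %d", n)
  if (identical(cutoff, "4/n")) cutoff <- 4 / n
  stopifnot(is.numeric(cutoff), cutoff > 0)
  fit <- stats::lm(values ~ 1)
  D <- unname(stats::cooks.distance(fit))
  flagged <- !is.na(D) & D > cutoff
  kept <- rep(TRUE, n)
  rule <- rep("none", n)
  for (sp in unique(species)) {
    i <- which(species == sp)
    f <- flagged[i]
    if (!any(f)) next
    if (length(i) == 1L) {
      kept[i] <- FALSE
      rule[i] <- "single-egg-drop"
    } else if (all(f)) {
      rule[i] <- "all-influential-retain"
    } else {
      kept[i[f]] <- FALSE
      rule[i] <- "partial-drop"
    }
  }
  structure(
    list(report = data.frame(species = species, value = values, D = D,
                             flagged = flagged, kept = kept, rule = rule,
                             stringsAsFactors = FALSE),
         cutoff = cutoff, n = n, n_excluded = sum(!kept)),
    class = "cooks_filter_report")
}

#' @export
print.cooks_filter_report <- function(x, ...) {
  cat(sprintf("Cook's filter: %d / %d specimens excluded (cutoff D > %.4g)\n",
              x$n_excluded, x$n, x$cutoff))
  invisible(x)
}

#' Assemble the species-level study table
#'
#' Joins species mean texture values to the trait table and applies the
#' response transforms used throughout the comparative analysis: Sa and
#' Sku are log10-transformed (their cross-species distributions are
#' right-skewed), Ssk is left untouched (already approximately normal).
#' The join is inner; species present on one side only are reported.
#'
#' @param texture species-level data frame with columns `species`, `Sa`,
#'   `Ssk`, `Sku` (e.g. `aggregate_texture(...)$species`).
#' @param traits trait data frame with a `species` column
#'   (see [read_trait_table()]).
#' @return data frame: species, `log_Sa`, `Ssk`, `log_Sku`, specimen
#'   counts if present, and all trait columns.
#' @export
build_study_table <- function(texture, traits) {
  stopifnot(all(c("species", "Sa", "Ssk", "Sku") %in% names(texture)),
            "species" %in% names(traits))
  if (anyDuplicated(texture$species))
    stop_fmt("duplicated species in texture table: %s",
             texture$species[duplicated(texture$species)][1L])
  if (anyDuplicated(traits$species))
    stop_fmt("duplicated species in trait table: %s",
             traits$species[duplicated(traits$species)][1L])
  bad <- texture$species[!is.na(texture$Sa) & texture$Sa <= 0 |
                         !is.na(texture$Sku) & texture$Sku <= 0]
  if (length(bad))
    stop_fmt("non-positive Sa or Sku for species: %s (log10 undefined)",
             paste(bad, collapse = ", "))
  lost_tex <- setdiff(texture$species, traits$species)
  lost_tr <- setdiff(traits$species, texture$species)
  if (length(lost_tex))
    message(sprintf("dropping %d species without trait data: %s",
                    length(lost_tex),
                    paste(utils::head(lost_tex, 5L), collapse = ", ")))
  if (length(lost_tr))
    message(sprintf("dropping %d species without texture data: %s",
                    length(lost_tr),
                    paste(utils::head(lost_tr, 5L), collapse = ", ")))
  out <- texture[texture$species %in% traits$species, , drop = FALSE]
  out$log_Sa <- log10(out$Sa)
  out$log_Sku <- log10(out$Sku)
  keep <- c("species", "log_Sa", "Ssk", "log_Sku",
            intersect("n_specimens", names(out)))
  out <- out[, keep]
  merge(out, traits, by = "species", sort = TRUE)
}
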