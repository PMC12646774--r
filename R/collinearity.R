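#' Collinearity screen for model predictors
#'
#' Two-pass screen applied before the mixed model so that no pair of
#' retained predictors is strongly correlated and no predictor is well
#' explained by the others. Pass 1 (pairwise): while any cross-predictor
#' pair of columns has \eqn{|r| \ge} `r_max` (default 0.75), the member
#' of the worst pair with the larger mean absolute correlation to all
#' other predictors is dropped. Pass 2 (VIF): predictors are dropped one
#' at a time, highest first, until every variance inflation factor is
#' below `vif_max` (default 10). Categorical predictors enter pass 1 as
#' indicator columns (all pairwise correlations computed between columns
#' of *different* predictors) and pass 2 as whole terms via the
#' generalized VIF (GVIF; for a single-column predictor GVIF is the
#' ordinary \eqn{1/(1-R^2)} VIF).
#'
#' Constant predictors carry no information and are dropped with a
#' warning before screening.
#'
#' @param df data frame of candidate predictors (numeric and/or factor),
#'   one row per species; a `species` column, if present, is ignored.
#' @param r_max pairwise absolute-correlation threshold.
#' @param vif_max VIF threshold.
#' @return object of class `collinearity_screen`: `retained` (names),
#'   `dropped` (data frame: predictor, stage, statistic), `vif` (named
#'   GVIFs of the retained set).
#' @export
collinearity_screen <- function(df, r_max = 0.75, vif_max = 10) {
  df <- df[, setdiff(names(df), "species"), drop = FALSE]
  if (ncol(df) < 2L) stop_fmt("screen needs >= 2 predictors")
  df <- stats::na.omit(df)
  drops <- data.frame(predictor = character(), stage = character(),
                      statistic = numeric(), stringsAsFactors = FALSE)
  # constants out first
  for (v in names(df)) {
    vals <- df[[v]]
    if (length(unique(vals[!is.na(vals)])) < 2L) {
      warn_fmt("dropping constant predictor '%s'", v)
      drops <- rbind(drops, data.frame(predictor = v, stage = "constant",
                                       statistic = NA_real_))
      df[[v]] <- NULL
    }
  }
  vars <- names(df)
  ind_cols <- function(v) {
    x <- df[[v]]
    if (is.numeric(x)) {
      m <- matrix(x, ncol = 1, dimnames = list(NULL, v))
    } else {
      x <- factor(x)
      m <- stats::model.matrix(~ x - 1)
      colnames(m) <- paste0(v, ".", levels(x))
    }
    m
  }
  # pass 1: pairwise correlations between indicator columns
  repeat {
    if (length(vars) < 2L) break
    mats <- lapply(vars, ind_cols)
    owner <- rep(vars, vapply(mats, ncol, 0L))
    M <- do.call(cbind, mats)
    r <- suppressWarnings(stats::cor(M))
    r[is.na(r)] <- 0
    cross <- outer(owner, owner, `!=`)
    worst <- max(abs(r[cross]))
    if (worst < r_max) break
    idx <- which(abs(r) == worst & cross, arr.ind = TRUE)[1L, ]
    pair <- owner[idx]
    mean_abs <- vapply(pair, function(v) {
      mean(abs(r[owner == v, owner != v, drop = FALSE]))
    }, 0)
    loser <- pair[which.max(mean_abs)]
    drops <- rbind(drops, data.frame(predictor = loser, stage = "pairwise",
                                     statistic = worst))
    vars <- setdiff(vars, loser)
  }
  # pass 2: generalized VIF
  gvif_set <- function(vars) {
    X <- do.call(cbind, lapply(vars, function(v) {
      x <- df[[v]]
      if (is.numeric(x)) matrix(x, ncol = 1, dimnames = list(NULL, v))
      else {
        m <- stats::model.matrix(~ x)[, -1, drop = FALSE]
        colnames(m) <- paste0(v, ".", colnames(m))
        m
      }
    }))
    owner <- rep(vars, vapply(vars, function(v)
      if (is.numeric(df[[v]])) 1L else nlevels(factor(df[[v]])) - 1L, 0L))
    R <- suppressWarnings(stats::cor(X))
    detR <- det(R)
    vapply(vars, function(v) {
      i <- owner == v
      det(R[i, i, drop = FALSE]) * det(R[!i, !i, drop = FALSE]) / detR
    }, 0)
  }
  repeat {
    if (length(vars) < 2L) break
    vifs <- gvif_set(vars)
    if (max(vifs) < vif_max) break
    loser <- names(vifs)[which.max(vifs)]
    drops <- rbind(drops, data.frame(predictor = loser, stage = "vif",
                                     statistic = unname(max(vifs))))
    vars <- setdiff(vars, loser)
  }
  vif_final <- if (length(vars) >= 2L) gvif_set(vars)
               else stats::setNames(rep(NA_real_, length(vars)), vars)
  structure(list(retained = vars, dropped = drops, vif = vif_final,
                 r_max = r_max, vif_max = vif_max),
            class = "collinearity_screen")
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat(sprintf("collinearity screen: %d retained, %d dropped (|r| < %.2f, VIF < %.3g)\n",
              length(x$retained), nrow(x$dropped), x$r_max, x$vif_max))
  if (nrow(x$dropped)) print(x$dropped, row.names = FALSE)
  invisible(x)
}
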