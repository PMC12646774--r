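#' Gaussian phylogenetic mixed model by Gibbs sampling
#'
#' Fits the "animal model" on individual-level responses:
#' \deqn{y_i = x_i'\beta + a_{s(i)} + b_{s(i)} + e_i}
#' with a phylogenetic species effect \eqn{a \sim N(0, \sigma_p^2 A)}
#' (A = Brownian tree covariance normalised to unit maximum depth), an
#' independent species-identity effect \eqn{b \sim N(0, \sigma_s^2 I)}
#' capturing non-phylogenetic species differences, and residual
#' \eqn{e \sim N(0, \sigma_e^2)}. All full conditionals are conjugate,
#' so the sampler is a plain Gibbs scheme: multivariate-normal blocks for
#' \eqn{\beta}, a and b, inverse-gamma draws for the three variances.
#' When the design is species-balanced the phylogenetic block is sampled
#' in the eigenbasis of A (diagonal full conditional); otherwise a fresh
#' Cholesky of the precision is taken each sweep.
#'
#' Priors: independent \eqn{N(0, \tau_\beta)} on fixed effects (default
#' variance 1e8, effectively flat) and inverse-gamma(shape, rate) on each
#' variance (default 0.001, 0.001, weakly informative). The sampler is
#' deterministic under `seed`.
#'
#' @param formula fixed-effects formula, e.g.
#'   `value ~ maculation + nest_type`.
#' @param data individual-level data frame; must carry a `species`
#'   column whose values all match tree tips.
#' @param tree rooted [ape::phylo]; tips not present in `data` are
#'   pruned.
#' @param nitt total MCMC iterations.
#' @param burnin iterations discarded (`nitt > burnin >= 0`).
#' @param thin thinning interval (>= 1).
#' @param prior list with `var_shape`, `var_rate` (inverse-gamma, all
#'   three variances) and `beta_var`.
#' @param seed integer seed or `NULL`.
#' @return object of class `phylo_mm`: `draws` (retained draws x
#'   parameters: fixed effects, `var_phylo`, `var_species`,
#'   `var_resid`), `ess` (effective sample sizes), model metadata used
#'   by [posterior_predict()], and the control settings.
#' @export
fit_phylo_mm <- function(formula, data, tree, nitt = 13000L,
                         burnin = 3000L, thin = 10L,
                         prior = list(var_shape = 0.001, var_rate = 0.001,
                                      beta_var = 1e8),
                         seed = NULL) {
  stopifnot("species" %in% names(data))
  validate_tree(tree)
  if (!is_count(nitt) || !is_count(burnin, 0L) || !is_count(thin) ||
      nitt <= burnin)
    stop_fmt("need nitt > burnin >= 0 and thin >= 1")
  n_keep <- floor((nitt - burnin) / thin)
  if (n_keep < 100L)
    warn_fmt("only %d retained draws; consider longer chains", n_keep)
  # do.call so the species vector is passed by value (model.frame would
  # otherwise re-evaluate the expression inside the data mask)
  mf <- do.call(stats::model.frame,
                list(formula, data = data,
                     species = as.character(data$species)))
  sp_obs <- mf[["(species)"]]
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  mterms <- stats::terms(stats::model.frame(formula, data))
  N <- length(y); p <- ncol(X)
  sp_data <- unique(sp_obs)
  missing_sp <- setdiff(sp_data, tree$tip.label)
  if (length(missing_sp))
    stop_fmt("species not on the tree: %s",
             paste(utils::head(missing_sp, 5L), collapse = ", "))
  if (length(sp_data) < 2L) stop_fmt("need >= 2 species")
  tree <- ape::keep.tip(tree, sp_data)

  Cv <- phylo_vcv(tree)
  A <- Cv$C / Cv$depth
  tips <- Cv$tips
  q <- length(tips)
  s <- match(sp_obs, tips)
  ns <- tabulate(s, q)
  E <- eigen(A, symmetric = TRUE)
  if (min(E$values) < 1e-10 * max(E$values))
    stop_fmt("phylogenetic covariance is not positive definite")
  Q <- E$vectors; lamA <- E$values
  balanced <- length(unique(ns)) == 1L
  k_bal <- ns[1L]
  Ainv <- Q %*% (t(Q) / lamA)

  XtX <- crossprod(X)
  shape0 <- prior$var_shape; rate0 <- prior$var_rate
  tau_b <- prior$beta_var

  with_local_seed(seed, {
    beta <- stats::coef(stats::lm.fit(X, y))
    beta[is.na(beta)] <- 0
    a <- numeric(q); b <- numeric(q)
    v0 <- stats::var(y)
    sp2 <- ss2 <- se2 <- max(v0 / 3, 1e-6)
    draws <- matrix(NA_real_, n_keep,  p + 3L)
    colnames(draws) <- c(colnames(X), "var_phylo", "var_species",
                         "var_resid")
    kept <- 0L
    for (it in seq_len(nitt)) {
      # beta | rest
      res_ab <- y - a[s] - b[s]
      Qb <- XtX / se2 + diag(1 / tau_b, p)
      Lb <- chol(Qb)
      mb <- backsolve(Lb, backsolve(Lb, crossprod(X, res_ab) / se2,
                                    transpose = TRUE))
      beta <- drop(mb) + drop(backsolve(Lb, stats::rnorm(p)))
      xb <- drop(X %*% beta)
      # a | rest
      Ts <- rowsum_by(y - xb - b[s], s, q)
      if (balanced) {
        d <- k_bal / se2 + 1 / (sp2 * lamA)
        t1 <- crossprod(Q, Ts / se2)
        a <- drop(Q %*% (t1 / d + stats::rnorm(q) / sqrt(d)))
      } else {
        Qa <- Ainv / sp2
        diag(Qa) <- diag(Qa) + ns / se2
        La <- chol(Qa)
        ma <- backsolve(La, backsolve(La, Ts / se2, transpose = TRUE))
        a <- drop(ma) + drop(backsolve(La, stats::rnorm(q)))
      }
      # b | rest
      Us <- rowsum_by(y - xb - a[s], s, q)
      vb <- 1 / (ns / se2 + 1 / ss2)
      b <- vb * Us / se2 + stats::rnorm(q) * sqrt(vb)
      # variances | rest
      qa <- sum(crossprod(Q, a)^2 / lamA)
      sp2 <- 1 / stats::rgamma(1L, shape0 + q / 2, rate0 + qa / 2)
      ss2 <- 1 / stats::rgamma(1L, shape0 + q / 2, rate0 + sum(b^2) / 2)
      r <- y - xb - a[s] - b[s]
      se2 <- 1 / stats::rgamma(1L, shape0 + N / 2, rate0 + sum(r^2) / 2)
      if (it > burnin && (it - burnin) %% thin == 0L) {
        kept <- kept + 1L
        draws[kept, ] <- c(beta, sp2, ss2, se2)
      }
    }
    draws <- draws[seq_len(kept), , drop = FALSE]
    structure(
      list(draws = draws, ess = apply(draws, 2L, ess),
           terms = stats::delete.response(mterms),
           xlevels = stats::.getXlevels(mterms, mf),
           contrasts = attr(X, "contrasts"),
           fixed_names = colnames(X), tips = tips,
           n_obs = N, n_species = q,
           control = list(nitt = nitt, burnin = burnin, thin = thin,
                          prior = prior, seed = seed)),
      class = "phylo_mm")
  })
}

rowsum_by <- function(x, g, q) {
  out <- numeric(q)
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- agg
  out
}

# effective sample size by the initial positive-autocorrelation estimator
ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 2L, 1000L), plot = FALSE,
                    demean = TRUE)$acf[-1L]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' @export
print.phylo_mm <- function(x, ...) {
  cat(sprintf("phylogenetic mixed model: %d obs, %d species, %d retained draws\n",
              x$n_obs, x$n_species, nrow(x$draws)))
  sm <- t(apply(x$draws, 2L, function(d)
    c(mean = mean(d), hpd(d, 0.95))))
  colnames(sm) <- c("post.mean", "l-95% HPD", "u-95% HPD")
  pm <- vapply(x$fixed_names, function(nm) pmcmc(x, nm), 0)
  sm <- cbind(sm, pMCMC = c(pm, rep(NA, 3L)))
  print(round(sm, 4))
  invisible(x)
}

#' MCMC significance of an effect (pMCMC)
#'
#' Twice the smaller tail probability of the effect's sign among
#' posterior draws, floored at 1 / (number of retained draws): the MCMC
#' analogue of a two-sided p-value.
#'
#' @param samples a [fit_phylo_mm()] object or a draws matrix/vector.
#' @param effect column name (ignored if `samples` is a vector).
#' @return pMCMC value in (0, 1\].
#' @export
pmcmc <- function(samples, effect = NULL) {
  d <- if (inherits(samples, "phylo_mm")) samples$draws
       else samples
  if (is.matrix(d)) {
    if (is.null(effect) || !effect %in% colnames(d))
      stop_fmt("effect '%s' not found in draws",
               if (is.null(effect)) "<missing>" else effect)
    d <- d[, effect]
  }
  n <- length(d)
  if (n == 0L) stop_fmt("no draws")
  max(2 * min(mean(d > 0), mean(d < 0)), 1 / n)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval over the sorted draws containing
#' `ceiling(mass * n)` draws. Ties in width resolve to the leftmost
#' window. Intervals are nested across masses by construction of the
#' definition only approximately; the implementation guarantees the
#' shortest-window property exactly.
#'
#' @param x numeric draws (>= 2).
#' @param mass interval mass in (0, 1).
#' @return numeric `c(lower, upper)`.
#' @export
hpd <- function(x, mass = 0.95) {
  n <- length(x)
  if (n < 2L) stop_fmt("hpd needs >= 2 draws")
  if (!is.numeric(mass) || mass <= 0 || mass >= 1)
    stop_fmt("'mass' must be in (0, 1)")
  xs <- sort(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(xs[1L], xs[n]))
  w <- xs[m:n] - xs[seq_len(n - m + 1L)]
  i <- which.min(w)
  c(xs[i], xs[i + m - 1L])
}

#' Factorial predictor grid for posterior prediction
#'
#' Builds the reduced grid over which model predictions are evaluated:
#' each continuous predictor is divided into `bins` equally spaced
#' representative values spanning its observed range (3 bins = min,
#' midpoint, max), and all combinations with every level of each
#' categorical predictor are formed. Rows are in deterministic
#' lexicographic order of the predictor columns.
#'
#' @param data data frame holding the observed predictors.
#' @param predictors character vector of predictor column names.
#' @param bins representative values per continuous predictor
#'   (default 3).
#' @return data frame with one row per predictor combination.
#' @export
build_grid <- function(data, predictors, bins = 3L) {
  stopifnot(all(predictors %in% names(data)), is_count(bins))
  vals <- lapply(predictors, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      r <- range(x, na.rm = TRUE)
      if (r[1] == r[2]) {
        warn_fmt("continuous predictor '%s' is constant; single grid value",
                 v)
        r[1]
      } else seq(r[1], r[2], length.out = bins)
    } else {
      factor(levels(factor(x)), levels = levels(factor(x)))
    }
  })
  names(vals) <- predictors
  g <- expand.grid(vals, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[do.call(order, g), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Batched posterior prediction over a predictor grid
#'
#' For every grid row, forms the posterior of the fixed-effects linear
#' predictor \eqn{x'\beta} (random effects marginalised at zero) from the
#' retained draws, reporting the posterior mean and HPD intervals at the
#' requested masses (default 50%, 80% and 95%). Rows are processed in
#' batches of `batch_size` to bound memory; each row's posterior is
#' computed by an independent matrix-vector product, so results are
#' bitwise identical for any batch size.
#'
#' @param fit a [fit_phylo_mm()] object.
#' @param grid data frame of predictor values (e.g. from
#'   [build_grid()]); columns must supply every predictor of the fitted
#'   design.
#' @param batch_size rows per batch (default 500).
#' @param masses HPD masses (default `c(0.5, 0.8, 0.95)`).
#' @return data frame: the grid columns plus `post_mean` and
#'   `lwr_XX` / `upr_XX` per mass; attribute `n_batches`.
#' @export
posterior_predict <- function(fit, grid, batch_size = 500L,
                              masses = c(0.5, 0.8, 0.95)) {
  stopifnot(inherits(fit, "phylo_mm"), is_count(batch_size))
  need <- all.vars(fit$terms)
  miss <- setdiff(need, names(grid))
  if (length(miss))
    stop_fmt("grid is missing predictor column(s): %s",
             paste(miss, collapse = ", "))
  X <- stats::model.matrix(fit$terms, grid, xlev = fit$xlevels,
                           contrasts.arg = fit$contrasts)
  if (!identical(colnames(X), fit$fixed_names))
    stop_fmt("grid design columns (%s) do not match the fitted design (%s)",
             paste(colnames(X), collapse = ", "),
             paste(fit$fixed_names, collapse = ", "))
  B <- fit$draws[, fit$fixed_names, drop = FALSE]
  ng <- nrow(X)
  n_batches <- ceiling(ng / batch_size)
  out <- matrix(NA_real_, ng, 1L + 2L * length(masses))
  colnames(out) <- c("post_mean",
                     as.vector(rbind(sprintf("lwr_%d", round(100 * masses)),
                                     sprintf("upr_%d", round(100 * masses)))))
  for (bt in seq_len(n_batches)) {
    rows <- seq.int((bt - 1L) * batch_size + 1L,
                    min(bt * batch_size, ng))
    for (i in rows) {
      post <- drop(B %*% X[i, ])
      out[i, 1L] <- mean(post)
      for (j in seq_along(masses))
        out[i, (2L * j):(2L * j + 1L)] <- hpd(post, masses[j])
    }
  }
  res <- cbind(grid, as.data.frame(out))
  attr(res, "n_batches") <- n_batches
  res
}
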