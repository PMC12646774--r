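test_that("Brownian covariance matches hand-computed path depths", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_vcv(tr)
  expect_equal(C$C["A", "B"], 1)
  expect_equal(C$C["A", "C"], 0)
  expect_equal(unname(diag(C$C)), rep(2, 3))
  expect_equal(C$depth, 2)

  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  Cs <- phylo_vcv(star)$C
  expect_equal(unname(Cs[upper.tri(Cs)]), rep(0, 6))

  # permuting the data order must permute C consistently
  tr2 <- gen_tree(12, seed = 61)
  C2 <- phylo_vcv(tr2)$C
  perm <- sample(12)
  expect_equal(C2[perm, perm], C2[rownames(C2)[perm], rownames(C2)[perm]])
  expect_true(isSymmetric(C2))
  ev <- eigen(C2, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
})

test_that("lambda transform scales off-diagonals only", {
  tr <- gen_tree(10, seed = 62)
  C <- phylo_vcv(tr)$C
  Cl <- lambda_transform(C, 0.4)
  expect_equal(diag(Cl), diag(C))
  expect_equal(Cl[1, 2], 0.4 * C[1, 2])
  expect_equal(lambda_transform(C, 0), diag(diag(C)), ignore_attr = TRUE)
})

test_that("lambda optimizer beats a dense grid scan", {
  for (r in 1:5) {
    tr <- gen_tree(60, seed = 700 + r)
    y <- sim_lambda_trait(tr, lambda = c(0, 0.3, 0.6, 0.9, 1)[r],
                          seed = 800 + r)
    C <- phylo_vcv(tr)
    f <- fit_lambda(y, C)
    grid <- seq(0, 1, length.out = 1001)
    gll <- vapply(grid, function(l)
      eggtexture:::lambda_loglik(unname(y[C$tips]), C$C, l)$loglik, 0)
    expect_gte(f$loglik, max(gll) - 1e-6)
    expect_gte(f$loglik, f$loglik0 - 1e-9)
    expect_gte(f$loglik, f$loglik1 - 1e-9)
  }
})

test_that("lambda fit agrees with phytools::phylosig", {
  skip_if_not_installed("phytools")
  tr <- gen_tree(80, seed = 63)
  y <- sim_lambda_trait(tr, lambda = 0.7, seed = 64)
  f <- fit_lambda(y, phylo_vcv(tr))
  ps <- phytools::phylosig(tr, y, method = "lambda", test = TRUE)
  expect_equal(f$lambda, ps$lambda, tolerance = 1e-3)
  expect_equal(f$loglik, ps$logL, tolerance = 1e-4)
  expect_equal(f$loglik0, ps$logL0, tolerance = 1e-4)
  expect_equal(f$p_lambda0, ps$P, tolerance = 1e-3)
})

test_that("a star phylogeny leaves lambda unidentifiable and is flagged", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  set.seed(65)
  y <- stats::setNames(rnorm(6), star$tip.label)
  f <- fit_lambda(y, phylo_vcv(star))
  expect_true(f$flat)
  expect_equal(f$loglik, f$loglik0, tolerance = 1e-8)
  expect_equal(f$loglik, f$loglik1, tolerance = 1e-8)
})

test_that("lambda fit rejects tiny or mismatched inputs", {
  tr <- gen_tree(10, seed = 66)
  C <- phylo_vcv(tr)
  expect_error(fit_lambda(rnorm(3), phylo_vcv(gen_tree(3, seed = 1))),
               "n >= 4")
  y <- stats::setNames(rnorm(10), paste0("zz", 1:10))
  expect_error(fit_lambda(y, C), "do not match")
})

test_that("PGLS under an identity covariance is exactly OLS", {
  set.seed(67)
  n <- 40
  d <- data.frame(y = rnorm(n), x1 = rnorm(n), x2 = runif(n))
  f <- pgls(y ~ x1 + x2, d, diag(n), correlation = "lambda-fixed",
            lambda = 1)
  ref <- summary(stats::lm(y ~ x1 + x2, d))
  expect_equal(unclass(f$coefficients), unclass(coef(ref)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(f$r_squared, ref$r.squared, tolerance = 1e-12)
  expect_equal(f$sigma2, ref$sigma^2, tolerance = 1e-12)
})

test_that("PGLS agrees with nlme::gls under a fixed Pagel correlation", {
  skip_if_not_installed("nlme")
  tr <- gen_tree(40, seed = 68)
  set.seed(69)
  d <- data.frame(species = tr$tip.label, x = rnorm(40))
  d$y <- 1 + 0.5 * d$x + sim_lambda_trait(tr, 0.6, seed = 70)[d$species]
  f <- pgls(y ~ x, d, phylo_vcv(tr), correlation = "lambda-fixed",
            lambda = 0.6)
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corPagel(0.6, tr, form = ~species,
                                             fixed = TRUE),
                 method = "ML")
  expect_equal(unname(f$coefficients[, "Estimate"]), unname(coef(g)),
               tolerance = 1e-6)
  sm <- summary(g)$tTable
  expect_equal(unname(f$coefficients[, "Std. Error"]),
               unname(sm[, "Std.Error"]), tolerance = 1e-6)
})

test_that("PGLS recovers a generating slope under phylogenetic noise", {
  hits <- 0L
  for (r in 1:30) {
    tr <- gen_tree(60, seed = 900 + r)
    set.seed(950 + r)
    d <- data.frame(species = tr$tip.label, x = rnorm(60))
    d$y <- 2 + 3 * d$x + sim_lambda_trait(tr, 1, seed = 980 + r)
    f <- pgls(y ~ x, d, phylo_vcv(tr), correlation = "BM")
    ci <- f$coefficients["x", "Estimate"] +
      c(-1, 1) * stats::qt(0.975, f$df_residual) *
        f$coefficients["x", "Std. Error"]
    if (ci[1] <= 3 && 3 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / 30, 0.8)  # nominal 95% coverage
})

test_that("PGLS errors on aliased designs", {
  set.seed(71)
  d <- data.frame(y = rnorm(20), x = rnorm(20))
  d$x2 <- d$x
  expect_error(pgls(y ~ x + x2, d, diag(20), correlation = "lambda-fixed",
                    lambda = 1), "aliased.*x2")
})

test_that("collinearity screen drops duplicates, keeps orthogonal sets", {
  set.seed(72)
  n <- 100
  df <- data.frame(a = rnorm(n))
  df$b <- df$a
  df$c <- rnorm(n)
  sc <- collinearity_screen(df)
  expect_length(sc$retained, 2L)
  expect_true("c" %in% sc$retained)
  expect_true(sum(c("a", "b") %in% sc$retained) == 1L)

  ortho <- as.data.frame(qr.Q(qr(matrix(rnorm(n * 4), n, 4))))
  sc2 <- collinearity_screen(ortho)
  expect_length(sc2$retained, 4L)
  expect_true(all(sc2$vif >= 1 & sc2$vif < 1.05))
})

test_that("VIF pass matches the regression oracle and catches near-sums", {
  set.seed(73)
  n <- 200
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  df$x3 <- df$x1 + df$x2 + rnorm(n, 0, 0.05)
  sc <- collinearity_screen(df, r_max = 0.95, vif_max = 10)
  expect_length(sc$retained, 2L)
  expect_equal(sc$dropped$stage[nrow(sc$dropped)], "vif")
  # oracle: VIF_j = 1/(1 - R^2_j) from regressing x_j on the others
  r2 <- summary(lm(x3 ~ x1 + x2, df))$r.squared
  expect_equal(sc$dropped$statistic[sc$dropped$predictor == "x3"],
               1 / (1 - r2), tolerance = 1e-6)
})

test_that("generalized VIF of factors matches car::vif", {
  skip_if_not_installed("car")
  set.seed(74)
  n <- 150
  df <- data.frame(x = rnorm(n),
                   f = factor(sample(letters[1:3], n, TRUE)),
                   z = rnorm(n))
  sc <- collinearity_screen(df)
  fit <- lm(rnorm(n) ~ x + f + z, data = df)
  cv <- car::vif(fit)
  expect_equal(unname(sc$vif["f"]), unname(cv["f", "GVIF"]),
               tolerance = 1e-8)
  expect_equal(unname(sc$vif["x"]), unname(cv["x", "GVIF"]),
               tolerance = 1e-8)
})

test_that("constant predictors are dropped with a warning before screening", {
  df <- data.frame(x = rnorm(30), k = rep(1, 30), y = rnorm(30))
  expect_warning(sc <- collinearity_screen(df), "constant.*'k'")
  expect_setequal(sc$retained, c("x", "y"))
})
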