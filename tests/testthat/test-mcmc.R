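sim_mm_data <- function(n_sp = 30, seed = 1, sd_phylo = 0.3,
                        sd_species = 0.3, sd_resid = 0.2) {
  tr <- gen_tree(n_sp, seed = seed)
  ss <- simulate_study(tr, trait_sim_spec(
    n_sp, specimens_range = c(1, 1), scans_per_specimen = 3,
    lambda = 1, sd_phylo = sd_phylo, sd_species = sd_species,
    sd_resid = sd_resid, seed = seed + 1))
  d <- merge(ss$individuals,
             ss$species[, c("species", "maculation", "nest_type",
                            "log_body_mass")], by = "species")
  list(data = d, tree = ss$tree, truth = ss$truth)
}

test_that("the Gibbs sampler is deterministic under its seed", {
  s <- sim_mm_data(20, seed = 81)
  f1 <- fit_phylo_mm(value ~ maculation, s$data, s$tree,
                     nitt = 600, burnin = 100, thin = 5, seed = 5)
  f2 <- fit_phylo_mm(value ~ maculation, s$data, s$tree,
                     nitt = 600, burnin = 100, thin = 5, seed = 5)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_phylo_mm(value ~ maculation, s$data, s$tree,
                     nitt = 600, burnin = 100, thin = 5, seed = 6)
  expect_false(identical(f1$draws, f3$draws))
  expect_equal(nrow(f1$draws), 100L)
  expect_true(all(f1$draws[, c("var_phylo", "var_species", "var_resid")] > 0))
})

test_that("with no phylogenetic variance the fit matches a plain mixed model", {
  s <- sim_mm_data(40, seed = 82, sd_phylo = 0, sd_species = 0.4,
                   sd_resid = 0.3)
  f <- fit_phylo_mm(value ~ maculation + log_body_mass, s$data, s$tree,
                    nitt = 6000, burnin = 1000, thin = 5, seed = 7)
  ref <- lme4::lmer(value ~ maculation + log_body_mass + (1 | species),
                    data = s$data)
  b_mcmc <- colMeans(f$draws[, f$fixed_names])
  b_ref <- lme4::fixef(ref)
  se_ref <- sqrt(diag(as.matrix(vcov(ref))))
  expect_true(all(abs(b_mcmc - b_ref) < 3 * se_ref))
  # posterior phylo variance collapses toward its prior floor
  expect_lt(stats::median(f$draws[, "var_phylo"]),
            stats::median(f$draws[, "var_species"]))
})

test_that("unbalanced designs use the general sampling path and still mix", {
  tr <- gen_tree(25, seed = 83)
  ss <- simulate_study(tr, trait_sim_spec(
    25, specimens_range = c(1, 4), scans_per_specimen = 3,
    lambda = 1, sd_phylo = 0.3, sd_species = 0.2, sd_resid = 0.2,
    seed = 84))
  d <- merge(ss$individuals, ss$species[, c("species", "maculation")],
             by = "species")
  f <- fit_phylo_mm(value ~ maculation, d, tr,
                    nitt = 4000, burnin = 1000, thin = 3, seed = 8)
  est <- mean(f$draws[, "maculationmaculate"])
  expect_lt(abs(est - 0.5), 0.5)
  expect_true(all(is.finite(f$ess)))
})

test_that("model preconditions are enforced", {
  s <- sim_mm_data(10, seed = 85)
  bad <- s$data
  bad$species[1] <- "not_a_tip"
  expect_error(fit_phylo_mm(value ~ maculation, bad, s$tree,
                            nitt = 1100, burnin = 100, thin = 10,
                            seed = 1),
               "not_a_tip")
  expect_error(fit_phylo_mm(value ~ maculation, s$data, s$tree,
                            nitt = 100, burnin = 200, seed = 1),
               "nitt > burnin")
})

test_that("pMCMC matches its definition and the normal-tail oracle", {
  expect_equal(pmcmc(rep(1, 2000)), 1 / 2000)    # all positive -> floor
  set.seed(86)
  sym <- rnorm(20000)
  expect_lt(abs(pmcmc(sym) - 1), 0.05)           # symmetric about 0
  shifted <- rnorm(10000, 1, 1)
  expect_equal(pmcmc(shifted), 2 * pnorm(-1), tolerance = 0.05)
  m <- cbind(a = rnorm(100), b = rnorm(100) + 10)
  expect_equal(pmcmc(m, "b"), 1 / 100)
  expect_error(pmcmc(m, "zz"), "zz")
  expect_error(pmcmc(numeric(0)), "no draws")
})

test_that("HPD equals the window-enumeration oracle and nests across masses", {
  expect_equal(hpd(c(3, 3, 3)), c(3, 3))
  expect_equal(hpd(1:100, 0.95), c(1, 95))  # width 94 over consecutive ints
  set.seed(87)
  for (rep in 1:20) {
    x <- switch(1 + rep %% 3, rnorm(200), rexp(300), rt(150, df = 3))
    for (mass in c(0.5, 0.8, 0.95))
      expect_identical(hpd(x, mass), hpd_enum(x, mass))
    h50 <- hpd(x, 0.5); h80 <- hpd(x, 0.8); h95 <- hpd(x, 0.95)
    expect_true(h95[1] <= h80[1] && h80[2] <= h95[2])
    expect_true(h80[1] <= h50[1] && h50[2] <= h80[2])
  }
  expect_error(hpd(1), ">= 2")
  expect_error(hpd(1:10, 1.2), "mass")
})

test_that("prediction grids enumerate the factorial reduced design", {
  set.seed(88)
  d <- data.frame(u = runif(50, 2, 10), v = rnorm(50),
                  f2 = factor(sample(c("x", "y"), 50, TRUE)),
                  f3 = factor(sample(c("p", "q", "r"), 50, TRUE)))
  g <- build_grid(d, c("u", "v", "f2", "f3"), bins = 3)
  expect_equal(nrow(g), 3^2 * 2 * 3)
  expect_equal(sort(unique(g$u)), c(min(d$u), (min(d$u) + max(d$u)) / 2,
                                    max(d$u)))
  expect_equal(nrow(unique(g)), nrow(g))
  # deterministic lexicographic order
  expect_equal(g, g[do.call(order, g), ], ignore_attr = TRUE)

  g2 <- build_grid(d, "f2")
  expect_equal(nrow(g2), 2L)
  d$k <- 5
  expect_warning(g3 <- build_grid(d, c("k", "f2")), "constant")
  expect_equal(nrow(g3), 2L)
})

test_that("posterior prediction is batch-invariant and honours the design", {
  s <- sim_mm_data(20, seed = 89)
  f <- fit_phylo_mm(value ~ maculation + nest_type, s$data, s$tree,
                    nitt = 2000, burnin = 500, thin = 3, seed = 9)
  g <- build_grid(s$data, c("maculation", "nest_type"))
  p1 <- posterior_predict(f, g, batch_size = 500)
  p2 <- posterior_predict(f, g, batch_size = 1)
  expect_identical(p1$post_mean, p2$post_mean)
  expect_identical(p1$lwr_95, p2$lwr_95)
  expect_identical(p1$upr_50, p2$upr_50)
  expect_equal(attr(p1, "n_batches"), 1)
  expect_equal(attr(p2, "n_batches"), nrow(g))
  # HPD nesting per row
  expect_true(all(p1$lwr_95 <= p1$lwr_80 & p1$upr_80 <= p1$upr_95))

  expect_error(posterior_predict(f, g[, "maculation", drop = FALSE]),
               "nest_type")

  # intercept-only model predicts the intercept posterior everywhere
  f0 <- fit_phylo_mm(value ~ 1, s$data, s$tree,
                     nitt = 1000, burnin = 200, thin = 2, seed = 10)
  g0 <- build_grid(s$data, "maculation")
  p0 <- posterior_predict(f0, g0)
  expect_equal(p0$post_mean, rep(mean(f0$draws[, "(Intercept)"]), 2))
})
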