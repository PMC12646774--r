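test_that("repeatability hits the boundary cases exactly", {
  # scans identical within specimen, means differ -> all variance between
  v <- rep(c(1, 5, 9), each = 3)
  g <- rep(c("a", "b", "c"), each = 3)
  r <- repeatability(v, g, nboot = 0)
  expect_equal(r$R, 1)
  expect_equal(r$var_within, 0)

  # everything identical -> degenerate, R defined as 1
  r2 <- repeatability(rep(2, 8), rep(c("a", "b"), each = 4), nboot = 0)
  expect_equal(r2$R, 1)
  expect_true(r2$degenerate)

  # single-scan specimens are dropped with a warning
  expect_warning(
    r3 <- repeatability(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c"),
                        nboot = 0),
    "single scan")
  expect_equal(r3$n_specimens, 2L)
  expect_error(suppressWarnings(repeatability(c(1, 2), c("a", "b"))),
               ">= 2 specimens")
})

test_that("balanced repeatability matches the one-way ANOVA oracle", {
  set.seed(51)
  a <- 40; k <- 4
  g <- factor(rep(seq_len(a), each = k))
  v <- rep(rnorm(a, 0, sqrt(3)), each = k) + rnorm(a * k, 0, 1)
  r <- repeatability(v, g, nboot = 0)
  # independent oracle via aov mean squares
  ms <- summary(stats::aov(v ~ g))[[1]]$`Mean Sq`
  vb <- (ms[1] - ms[2]) / k
  expect_equal(r$var_between, vb, tolerance = 1e-10)
  expect_equal(r$var_within, ms[2], tolerance = 1e-10)
  expect_equal(r$R, vb / (vb + ms[2]), tolerance = 1e-10)
})

test_that("unbalanced repeatability agrees with REML and the CI brackets R", {
  set.seed(52)
  counts <- sample(2:6, 30, replace = TRUE)
  g <- factor(rep(seq_len(30), counts))
  v <- rep(rnorm(30, 0, sqrt(3)), counts) + rnorm(sum(counts), 0, 1)
  r <- repeatability(v, g, nboot = 200, seed = 1)
  expect_equal(r$method, "REML")
  fit <- lme4::lmer(v ~ 1 + (1 | g))
  vc <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(r$R, vc$vcov[1] / sum(vc$vcov), tolerance = 1e-6)
  expect_true(r$ci[1] <= r$R && r$R <= r$ci[2])
})

test_that("aggregation is two-stage, never pooled", {
  df <- data.frame(
    species = "sp1",
    specimen = c(rep("e1", 10), rep("e2", 2)),
    value = c(rep(2, 10), rep(4, 2)))
  agg <- aggregate_texture(df, values = "value")
  expect_equal(agg$species$value, 3)  # pooled mean would be 2.33
  expect_equal(agg$species$n_specimens, 2L)
  expect_equal(sort(agg$specimens$n_scans), c(2L, 10L))

  one <- aggregate_texture(data.frame(species = "s", specimen = "e",
                                      value = 7), values = "value")
  expect_equal(one$species$value, 7)
})

test_that("aggregation equals an independent group-by oracle on random tables", {
  set.seed(53)
  for (rep in 1:5) {
    df <- data.frame(
      species = sample(paste0("sp", 1:6), 80, TRUE),
      specimen = sample(paste0("e", 1:4), 80, TRUE),
      Sa = rexp(80, 1e-3))
    df$specimen <- paste(df$species, df$specimen, sep = "_")
    agg <- aggregate_texture(df, values = "Sa")
    oracle <- brute_species_means(df, "Sa")
    expect_equal(agg$species$Sa[match(names(oracle), agg$species$species)],
                 unname(oracle), tolerance = 1e-12)
  }
})

test_that("Cook's distances equal brute-force leave-one-out refits", {
  set.seed(54)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    y <- rnorm(n) + (runif(n) < 0.1) * rnorm(n, 0, 10)
    cf <- cooks_filter(y, rep("sp", n), cutoff = 1e9)
    expect_equal(cf$report$D, cooks_loo(y), tolerance = 1e-10)
  }
})

test_that("species retention rules follow the single-egg and all-influential cases", {
  # outlier in a single-egg species is excluded
  v <- c(1, 1.1, 0.9, 1.05, 100)
  sp <- c("a", "a", "b", "b", "solo")
  cf <- cooks_filter(v, sp, cutoff = "4/n")
  expect_true(cf$report$flagged[5])
  expect_false(cf$report$kept[5])
  expect_equal(cf$report$rule[5], "single-egg-drop")
  expect_true(all(cf$report$kept[1:4]))

  # all specimens of a multi-egg species flagged -> all retained
  v2 <- c(rep(0, 10), 50, 51, 49)
  sp2 <- c(rep(letters[1:5], 2), rep("x", 3))
  cf2 <- cooks_filter(v2, sp2, cutoff = 0.05)
  expect_true(all(cf2$report$flagged[11:13]))
  expect_true(all(cf2$report$kept[11:13]))
  expect_equal(unique(cf2$report$rule[11:13]), "all-influential-retain")

  # partial flags drop only the flagged specimens
  v3 <- c(1, 1.2, 0.8, 1.1, 30, 1.05)
  sp3 <- c("m", "m", "m", "n", "n", "n")
  cf3 <- cooks_filter(v3, sp3)
  expect_false(cf3$report$kept[5])
  expect_true(all(cf3$report$kept[-5]))
  expect_equal(cf3$report$rule[4], "partial-drop")

  # homogeneous values: nothing flagged, nothing excluded
  cf4 <- cooks_filter(rep(c(1, 1.01), 5), rep(letters[1:5], 2))
  expect_equal(cf4$n_excluded, 0L)
  expect_error(cooks_filter(c(1, 2), c("a", "b")), ">= 3")
})

test_that("study table applies the response transforms and join semantics", {
  tex <- data.frame(species = paste0("sp", 1:5),
                    Sa = c(1000, 2000, 500, 1500, 800),
                    Ssk = c(-0.5, 0.2, -1, 0, -2),
                    Sku = c(10, 3, 5, 100, 4))
  tr <- data.frame(species = paste0("sp", c(1:3, 5)),
                   maculation = factor(rep(c("maculate", "immaculate"), 2)))
  expect_message(st <- build_study_table(tex, tr), "sp4")
  expect_equal(nrow(st), 4L)
  expect_equal(st$log_Sa[st$species == "sp1"], 3)
  expect_equal(st$Ssk[st$species == "sp3"], -1)
  expect_false("sp4" %in% st$species)
  expect_equal(st$log_Sku[st$species == "sp2"], log10(3))

  tex$Sa[1] <- -5
  expect_error(build_study_table(tex, tr), "sp1")
  tex$Sa[1] <- 1000
  tex2 <- rbind(tex, tex[1, ])
  expect_error(build_study_table(tex2, tr), "duplicated")
})
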