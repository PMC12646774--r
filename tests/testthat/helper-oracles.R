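# fixture builders and independent brute-force oracles used across tests

# height map from a matrix, flagged as corrected so texture tests don't warn
make_hm <- function(z, ...) {
  hm <- height_map(z, ...)
  hm$meta$corrected <- TRUE
  hm
}

# texture moments computed directly on a vector of heights (1/n convention)
brute_texture <- function(z) {
  z <- z[!is.na(z)]
  zc <- z - mean(z)
  Sq <- sqrt(mean(zc^2))
  list(Sa = mean(abs(zc)), Sq = Sq,
       Ssk = mean(zc^3) / Sq^3, Sku = mean(zc^4) / Sq^4)
}

# Cook's distance for the intercept-only model by leave-one-out refits:
# D_i = sum_j (yhat_j - yhat_j(i))^2 / (p * s^2)
cooks_loo <- function(y) {
  n <- length(y)
  s2 <- sum((y - mean(y))^2) / (n - 1)
  vapply(seq_len(n), function(i) {
    d <- mean(y) - mean(y[-i])
    n * d^2 / s2
  }, 0)
}

# HPD by enumeration of every window of ceiling(mass*n) consecutive
# sorted draws
hpd_enum <- function(x, mass) {
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(mass * n)
  if (m >= n) return(c(xs[1], xs[n]))
  best <- c(xs[1], xs[m]); bw <- xs[m] - xs[1]
  for (i in 2:(n - m + 1)) {
    w <- xs[i + m - 1] - xs[i]
    if (w < bw) { bw <- w; best <- c(xs[i], xs[i + m - 1]) }
  }
  best
}

# species means by an independent split/apply group-by path
brute_species_means <- function(df, value) {
  spm <- sapply(split(df, paste(df$species, df$specimen, sep = "\r")),
                function(g) mean(g[[value]]))
  sp <- vapply(strsplit(names(spm), "\r", fixed = TRUE), `[`, "", 1)
  sapply(split(unname(spm), sp), mean)
}

# BM/lambda trait simulation on a tree (independent of simulate_study)
sim_lambda_trait <- function(tree, lambda, seed) {
  C <- ape::vcv.phylo(tree)
  Cn <- C / max(diag(C))
  Cl <- lambda * Cn
  diag(Cl) <- diag(Cn)
  set.seed(seed)
  stats::setNames(drop(crossprod(chol(Cl), rnorm(nrow(C)))), rownames(C))
}
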