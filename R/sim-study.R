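#' Simulate a Yule phylogeny
#'
#' Pure-birth tree via [ape::rphylo()] (which conditions on the number of
#' tips), reproducible under `seed`. Tips are labelled `sp001`, `sp002`,
#' ... so they can serve directly as species ids in simulated trait
#' tables.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth birth rate (default 1; only relative depth matters for
#'   the comparative models, which normalise tree depth).
#' @param seed integer seed or `NULL`.
#' @return an ultrametric [ape::phylo] object.
#' @export
gen_tree <- function(n_tips, birth = 1, seed = NULL) {
  if (!is_count(n_tips, 2L)) stop_fmt("'n_tips' must be an integer >= 2")
  tr <- with_local_seed(seed,
    ape::rphylo(as.integer(n_tips), birth = birth, death = 0))
  tr$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tr
}

#' Specification of a simulated comparative study
#'
#' Defines the generative model whose structure the analysis stack
#' assumes: species means follow
#' \eqn{X\beta + u_{phylo} + u_{species}} with
#' \eqn{u_{phylo} \sim N(0, \sigma_p^2 C_\lambda)} (tree covariance,
#' depth-normalised to 1, Pagel-\eqn{\lambda} transformed) and
#' \eqn{u_{species} \sim N(0, \sigma_s^2 I)}; individual scan values add
#' independent \eqn{N(0, \sigma_e^2)} noise. Fixed effects come from a
#' small default predictor set (maculation, nest type, log body mass)
#' unless overridden.
#'
#' @param n_species number of species (must not exceed the tree's tips).
#' @param specimens_range integer range (min, max) of specimens per
#'   species, sampled uniformly.
#' @param scans_per_specimen scans per specimen (>= 3, matching scans at
#'   three non-overlapping locations per fragment).
#' @param lambda generating Pagel's lambda in \[0, 1\].
#' @param sd_phylo,sd_species,sd_resid standard deviations of the
#'   phylogenetic effect, the non-phylogenetic species effect, and the
#'   scan-level residual.
#' @param beta named numeric vector of fixed effects on the model-matrix
#'   scale of `~ maculation + nest_type + log_body_mass`; names must
#'   match the model-matrix columns.
#' @param seed integer seed; expanded into fixed per-component substreams
#'   (predictors = seed, species effects = seed + 1, scan noise =
#'   seed + 2).
#' @return object of class `trait_sim_spec`.
#' @export
trait_sim_spec <- function(n_species, specimens_range = c(1L, 10L),
                           scans_per_specimen = 3L, lambda = 1,
                           sd_phylo = 1, sd_species = 0.5, sd_resid = 0.5,
                           beta = c("(Intercept)" = 3,
                                    "maculationmaculate" = 0.5,
                                    "nest_typesemi-enclosed" = -0.3,
                                    "nest_typeenclosed" = -0.3,
                                    "log_body_mass" = 0),
                           seed = 1L) {
  stopifnot(is_count(n_species, 2L),
            length(specimens_range) == 2L,
            specimens_range[1] >= 1L,
            specimens_range[2] >= specimens_range[1],
            is_count(scans_per_specimen, 1L),
            is_prob(lambda),
            sd_phylo >= 0, sd_species >= 0, sd_resid >= 0,
            !is.null(names(beta)))
  structure(as.list(environment()), class = "trait_sim_spec")
}

#' Simulate a comparative eggshell-texture study
#'
#' Draws species-level predictors, species mean responses under the
#' phylogenetic model of [trait_sim_spec()], and an individual-level scan
#' table, returning the generating parameters for recovery tests.
#'
#' @param tree ultrametric [ape::phylo] with at least `spec$n_species`
#'   tips; the first `n_species` tips (pruned) are used.
#' @param spec a [trait_sim_spec()].
#' @return list with elements
#'   \describe{
#'     \item{species}{data frame: species id, predictors, true mean and
#'       realised species mean response.}
#'     \item{individuals}{data frame: species, specimen, scan, value.}
#'     \item{tree}{the pruned tree actually used.}
#'     \item{truth}{generating parameters: `beta`, `lambda`, `sd_phylo`,
#'       `sd_species`, `sd_resid`, and the drawn `u_phylo`, `u_species`.}
#'   }
#' @export
simulate_study <- function(tree, spec) {
  stopifnot(inherits(spec, "trait_sim_spec"))
  validate_tree(tree)
  n <- spec$n_species
  if (length(tree$tip.label) < n)
    stop_fmt("tree has %d tips but %d species requested",
             length(tree$tip.label), n)
  if (length(tree$tip.label) > n)
    tree <- ape::keep.tip(tree, tree$tip.label[seq_len(n)])
  sp <- tree$tip.label

  # substream 1: predictors
  traits <- with_local_seed(spec$seed, {
    data.frame(
      species = sp,
      maculation = factor(sample(trait_levels()$maculation, n, TRUE),
                          levels = trait_levels()$maculation),
      nest_type = factor(sample(trait_levels()$nest_type, n, TRUE),
                         levels = trait_levels()$nest_type),
      log_body_mass = stats::rnorm(n, 1.5, 0.7),
      stringsAsFactors = FALSE)
  })
  X <- stats::model.matrix(~ maculation + nest_type + log_body_mass, traits)
  if (!setequal(colnames(X), names(spec$beta)))
    stop_fmt("beta names must be: %s", paste(colnames(X), collapse = ", "))
  mu <- drop(X %*% spec$beta[colnames(X)])

  # substream 2: species-level random effects
  C <- phylo_vcv(tree)
  Cn <- C$C / C$depth
  Cl <- lambda_transform(Cn, spec$lambda)
  eff <- with_local_seed(spec$seed + 1L, {
    u_p <- if (spec$sd_phylo > 0)
      drop(crossprod(chol(Cl), stats::rnorm(n))) * spec$sd_phylo
    else rep(0, n)
    u_s <- stats::rnorm(n, 0, spec$sd_species)
    list(u_p = u_p, u_s = u_s)
  })
  species_mean <- mu + eff$u_p + eff$u_s

  # substream 3: study design and scan noise
  ind <- with_local_seed(spec$seed + 2L, {
    n_spec <- sample(seq.int(spec$specimens_range[1], spec$specimens_range[2]),
                     n, replace = TRUE)
    rows <- do.call(rbind, lapply(seq_len(n), function(i) {
      expand.grid(specimen = seq_len(n_spec[i]),
                  scan = seq_len(spec$scans_per_specimen))[, 2:1]
    }))
    df <- data.frame(
      species = rep(sp, n_spec * spec$scans_per_specimen),
      specimen = NA_character_, scan = NA_integer_,
      stringsAsFactors = FALSE)
    df$scan <- rows$scan
    df$specimen <- sprintf("%s_e%02d", df$species, rows$specimen)
    i <- match(df$species, sp)
    df$value <- species_mean[i] + stats::rnorm(nrow(df), 0, spec$sd_resid)
    df
  })

  traits$true_mean <- mu
  traits$species_mean <- species_mean
  list(species = traits,
       individuals = ind[order(ind$species, ind$specimen, ind$scan), ],
       tree = tree,
       truth = list(beta = spec$beta, lambda = spec$lambda,
                    sd_phylo = spec$sd_phylo, sd_species = spec$sd_species,
                    sd_resid = spec$sd_resid,
                    u_phylo = eff$u_p, u_species = eff$u_s))
}
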