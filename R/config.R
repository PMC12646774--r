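#' Analysis run configuration
#'
#' Bundles the settings a full pipeline run needs — seed, QC thresholds,
#' transform flags, MCMC controls and prediction-grid settings — with
#' their invariants enforced at construction, so a bad configuration
#' fails before any computation starts.
#'
#' @param seed integer master seed.
#' @param coverage_threshold scan QC coverage threshold, in (0, 1].
#' @param min_area minimum accepted crop area, pixels.
#' @param cooks_cutoff Cook's-distance cutoff (`"4/n"` or a number).
#' @param log_transform logical: log10-transform Sa and Sku.
#' @param nitt,burnin,thin MCMC controls (`nitt > burnin >= 0`,
#'   `thin >= 1`).
#' @param var_shape,var_rate inverse-gamma variance prior parameters
#'   (> 0).
#' @param beta_var fixed-effect prior variance (> 0).
#' @param bins grid bins per continuous predictor.
#' @param batch_size posterior-prediction batch size.
#' @return object of class `run_config` (a validated named list).
#' @export
run_config <- function(seed = 1L, coverage_threshold = 0.40,
                       min_area = 4L, cooks_cutoff = "4/n",
                       log_transform = TRUE,
                       nitt = 80000L, burnin = 20000L, thin = 500L,
                       var_shape = 0.001, var_rate = 0.001,
                       beta_var = 1e8, bins = 3L, batch_size = 500L) {
  stopifnot(is_count(seed, 0L),
            is_prob(coverage_threshold), coverage_threshold > 0,
            is_count(min_area),
            is.logical(log_transform),
            is_count(nitt), is_count(burnin, 0L), is_count(thin),
            nitt > burnin,
            var_shape > 0, var_rate > 0, beta_var > 0,
            is_count(bins), is_count(batch_size))
  structure(as.list(environment()), class = "run_config")
}

#' Read / write a run configuration
#'
#' Plain `key: value` text (Debian-control style, via [read.dcf()]) so
#' configurations stay diffable and editable by hand.
#'
#' @param path file path.
#' @return [run_config()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  m <- read.dcf(path)
  vals <- as.list(m[1L, ])
  defaults <- formals(run_config)
  for (k in names(vals)) {
    if (k == "cooks_cutoff" && vals[[k]] != "4/n")
      vals[[k]] <- as.numeric(vals[[k]])
    else if (k == "log_transform")
      vals[[k]] <- as.logical(vals[[k]])
    else if (k != "cooks_cutoff")
      vals[[k]] <- as.numeric(vals[[k]])
  }
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown))
    stop_fmt("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  m <- matrix(vapply(config, function(v) format(v, digits = 17),
                     character(1)), nrow = 1L,
              dimnames = list(NULL, names(config)))
  write.dcf(m, path)
  invisible(path)
}
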