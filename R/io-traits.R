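#' Allowed levels of the categorical life-history predictors
#'
#' The predictor set covers the life-history and nest-environment variables
#' hypothesised to shape eggshell surface texture: maculation, diet,
#' developmental mode, nest architecture and location, habitat openness,
#' nest lining, incubation sharing, parental plumage contact and care
#' system, plus the continuous predictors body mass (g), clutch size,
#' incubation period (days), annual mean temperature and annual mean
#' precipitation of the breeding range.
#'
#' @return named list: one character vector of allowed levels per
#'   categorical predictor.
#' @export
trait_levels <- function() {
  list(
    maculation        = c("immaculate", "maculate"),
    diet              = c("plant", "insectivore", "omnivore",
                          "carnivore/scavenger"),
    development       = c("altricial", "precocial"),
    nest_type         = c("exposed", "semi-enclosed", "enclosed"),
    nest_location     = c("ground", "water", "elevated"),
    habitat           = c("open", "semi-open", "dense"),
    nest_lining       = c("lined", "not lined"),
    incubating_parent = c("not shared", "shared"),
    parental_contact  = c("wet plumage", "dry plumage"),
    parental_care     = c("uniparental", "biparental")
  )
}

#' Names of the continuous life-history predictors
#' @return character vector.
#' @export
trait_continuous <- function() {
  c("body_mass", "clutch_size", "incubation_period",
    "annual_temperature", "annual_precipitation")
}

#' Read a species trait table
#'
#' Reads a delimited text table of species-level predictors, validating
#' categorical columns against [trait_levels()]. Missing values (empty or
#' `NA`) are preserved as `NA`; unknown categorical levels are an error
#' naming the row and column, so typos never flow silently into models.
#'
#' @param path delimited text file with a header; must contain a
#'   `species` column.
#' @param sep field separator (default tab).
#' @return data frame with `species` as character, categorical predictors
#'   as factors with the canonical level sets, and remaining columns
#'   numeric.
#' @export
read_trait_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), comment.char = "#",
                          quote = "\"")
  validate_trait_table(df)
}

#' @rdname read_trait_table
#' @param df a data frame to validate in memory.
#' @export
validate_trait_table <- function(df) {
  if (!"species" %in% names(df))
    stop_fmt("trait table has no 'species' column")
  if (anyNA(df$species)) stop_fmt("species id missing in row %s",
                                  which(is.na(df$species))[1L])
  df$species <- as.character(df$species)
  lev <- trait_levels()
  for (col in intersect(names(lev), names(df))) {
    v <- as.character(df[[col]])
    bad <- which(!is.na(v) & !(v %in% lev[[col]]))
    if (length(bad))
      stop_fmt("unknown level '%s' in column '%s', row %d (allowed: %s)",
               v[bad[1L]], col, bad[1L], paste(lev[[col]], collapse = ", "))
    df[[col]] <- factor(v, levels = lev[[col]])
  }
  for (col in setdiff(names(df), c("species", names(lev)))) {
    if (!is.numeric(df[[col]])) {
      num <- suppressWarnings(as.numeric(df[[col]]))
      if (any(is.na(num) & !is.na(df[[col]])))
        stop_fmt("column '%s' is neither a known categorical predictor nor numeric",
                 col)
      df[[col]] <- num
    }
    if (any(is.infinite(df[[col]])))
      stop_fmt("non-finite value in column '%s'", col)
  }
  df
}

#' Write a trait table
#'
#' @param df trait data frame.
#' @param path output file.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}
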