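#' Packaged parameter ranges and constraint tables
#'
#' Loads one of the packaged range tables:
#' \describe{
#'   \item{`"gsa"`}{Literature uncertainty intervals over which parameters are
#'     varied for global sensitivity analysis. The minimum cyclase rate
#'     appears as the unitless coordinate `a_min` on \[0, 1\] so that all
#'     coordinates can be sampled independently.}
#'   \item{`"hard"`}{Strict constraints (on parameters and on derived dark
#'     steady-state quantities `cG_dark`, `Ca_dark`, `J_dark`) that fitted
#'     parameter sets must satisfy.}
#'   \item{`"soft"`}{Expected ranges outside which the fitting density is
#'     penalized but not forbidden.}
#'   \item{`"best_fit"`}{The single best-fit parameter vector (lo = hi).}
#' }
#'
#' @param which One of `"gsa"`, `"hard"`, `"soft"`, `"best_fit"`.
#' @return A `param_ranges` data frame with columns `name`, `lo`, `hi`,
#'   `units`, `constraint_class`, `species`.
#' @examples
#' head(param_ranges("gsa"))
#' @export
param_ranges <- function(which = c("gsa", "hard", "soft", "best_fit")) {
  which <- match.arg(which)
  file <- c(gsa = "gsa_ranges.csv", hard = "mcmc_hard_constraints.csv",
            soft = "mcmc_soft_ranges.csv", best_fit = "best_fit_params.csv")[[which]]
  read_param_ranges(system.file("extdata", file, package = "conesens",
                                mustWork = TRUE))
}

#' Read a parameter-range table from CSV
#'
#' @param file Path to a CSV with columns `name, lo, hi, units,
#'   constraint_class` (optionally `species`). A fixed parameter has
#'   `lo == hi`.
#' @return A validated `param_ranges` data frame.
#' @export
read_param_ranges <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(name = "character"))
  validate_param_ranges(df)
}

#' Write a parameter-range table to CSV
#'
#' @param ranges A `param_ranges` data frame.
#' @param file Output path.
#' @export
write_param_ranges <- function(ranges, file) {
  utils::write.csv(unclass_df(ranges), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

unclass_df <- function(x) { class(x) <- "data.frame"; x }

#- parameter fields of cone_params plus derived/constraint names that range
#- tables may legitimately reference
range_name_universe <- function() {
  c(names(cone_params()), "cG_dark", "Ca_dark", "J_dark")
}

validate_param_ranges <- function(df) {
  need <- c("name", "lo", "hi", "units", "constraint_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("range table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"species" %in% names(df)) df$species <- ""
  if (anyDuplicated(df$name)) stop("duplicated parameter names in range table")
  unknown <- setdiff(df$name, range_name_universe())
  if (length(unknown))
    stop("range table names not resolvable to model parameters: ",
         paste(unknown, collapse = ", "))
  if (any(!is.finite(df$lo)) || any(!is.finite(df$hi)) || any(df$lo > df$hi))
    stop("range table requires finite lo <= hi")
  fixed <- df$constraint_class == "fixed"
  if (any(fixed & df$lo != df$hi))
    stop("fixed parameters must carry a single value (lo == hi)")
  class(df) <- c("param_ranges", "data.frame")
  df
}

#' Interval lookup helper
#' @param ranges A `param_ranges` data frame.
#' @param name Parameter name.
#' @return Numeric length-2 vector `c(lo, hi)`.
#' @keywords internal
range_of <- function(ranges, name) {
  i <- match(name, ranges$name)
  if (is.na(i)) stop("no range for parameter '", name, "'")
  c(ranges$lo[i], ranges$hi[i])
}

#' Assemble a parameter set from named values over a base set
#'
#' Names matching [cone_params()] fields replace the base values; the name
#' `a_min` switches the set to the `a_min` parameterization of the minimum
#' cyclase rate, `alpha_ratio` to the ratio parameterization.
#'
#' @param values Named numeric vector.
#' @param base A `cone_params` object supplying unreferenced fields.
#' @return A `cone_params` object.
#' @export
params_from_values <- function(values, base = cone_params()) {
  stopifnot(inherits(base, "cone_params"), !is.null(names(values)))
  p <- unclass(base)
  for (nm in names(values)) {
    if (!nm %in% names(p)) stop("unknown parameter '", nm, "'")
    p[[nm]] <- unname(values[[nm]])
  }
  if ("a_min" %in% names(values)) p$alpha_min_mode <- "a_min"
  else if ("alpha_ratio" %in% names(values)) p$alpha_min_mode <- "ratio"
  else if ("alpha_min" %in% names(values)) p$alpha_min_mode <- "direct"
  class(p) <- "cone_params"
  validate_cone_params(p)
  p
}

#' Read/write a parameter set as CSV or JSON
#'
#' CSV uses the same schema as the range tables with `lo == hi`; JSON is a
#' flat name/value object.
#'
#' @param p A `cone_params` object.
#' @param file Path ending in `.csv` or `.json`.
#' @return `read_params` returns a `cone_params` object; writers return the
#'   path invisibly.
#' @export
write_params <- function(p, file) {
  stopifnot(inherits(p, "cone_params"))
  num <- p[vapply(p, is.numeric, logical(1))]
  num <- num[!vapply(num, is.na, logical(1))]
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::write_json(c(num, list(alpha_min_mode = p$alpha_min_mode)),
                         file, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(name = names(num), lo = unlist(num), hi = unlist(num),
                     units = "", constraint_class = "fixed", species = "")
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}

#' @rdname write_params
#' @param base Base parameter set for fields absent from the file.
#' @export
read_params <- function(file, base = cone_params()) {
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    vals <- jsonlite::read_json(file, simplifyVector = TRUE)
    mode <- vals[["alpha_min_mode"]]
    vals <- vals[setdiff(names(vals), "alpha_min_mode")]
    p <- params_from_values(unlist(vals), base = base)
    if (!is.null(mode)) p$alpha_min_mode <- mode
    validate_cone_params(p)
    return(p)
  }
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  vals <- stats::setNames(df$lo, df$name)
  vals <- vals[names(vals) %in% names(cone_params())]
  params_from_values(vals, base = base)
}
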