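## CSV interchange: documented column schemas, validation with row numbers,
## habitat label normalization.

SITE_COLUMNS <- c("site_id", "habitat_type", "latitude_proxy",
                  "substrate_cover", "exposure", "min_salinity")
QUADRAT_COLUMNS <- c("site_id", "quadrat_index", "count", "substrate_cover",
                     "is_first")
PROJECTION_COLUMNS <- c("site_id", "habitat_type", "substrate_cover",
                        "exposure", "min_salinity", "depth", "area")

normalize_habitat <- function(x) {
  x <- gsub("[ -]+", "_", tolower(trimws(x)))
  x[x %in% c("natural", "rocky", "natural_rock")] <- ifelse(
    x[x %in% c("natural", "rocky", "natural_rock")] == "natural",
    "natural", "natural_rocky")
  x
}

check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, ": missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

fail_rows <- function(bad, what, msg) {
  if (any(bad))
    stop(what, ": ", msg, " (row ", paste(utils::head(which(bad), 5),
                                          collapse = ", "), ")")
}

#' Read and validate a survey (site + quadrat CSV pair)
#'
#' Schema-validates both tables, normalizes habitat labels, and enforces the
#' survey invariants: integer non-negative counts, percent cover within
#' \[0, 100\], exactly one first quadrat per site. Violations are reported
#' with row numbers.
#'
#' @param sites_path,quadrats_path CSV paths.
#' @return List with `sites` and `quadrats` data frames.
#' @export
read_survey <- function(sites_path, quadrats_path) {
  sites <- utils::read.csv(sites_path, stringsAsFactors = FALSE)
  quadrats <- utils::read.csv(quadrats_path, stringsAsFactors = FALSE)
  check_columns(sites, SITE_COLUMNS, "sites")
  check_columns(quadrats, QUADRAT_COLUMNS, "quadrats")
  sites$habitat_type <- normalize_habitat(sites$habitat_type)
  if ("presence" %in% names(sites)) sites$presence <- as.logical(sites$presence)

  fail_rows(!is.finite(sites$substrate_cover) | sites$substrate_cover < 0 |
              sites$substrate_cover > 100, "sites",
            "substrate_cover outside [0, 100]")
  fail_rows(!is.finite(sites$exposure) | sites$exposure < 0, "sites",
            "negative or non-finite exposure")
  fail_rows(!is.finite(quadrats$count) | quadrats$count < 0 |
              quadrats$count != round(quadrats$count), "quadrats",
            "counts must be non-negative integers")
  quadrats$count <- as.integer(quadrats$count)
  fail_rows(!is.finite(quadrats$substrate_cover) |
              quadrats$substrate_cover < 0 | quadrats$substrate_cover > 100,
            "quadrats", "substrate_cover outside [0, 100]")
  quadrats$is_first <- as.logical(quadrats$is_first)
  firsts <- tapply(quadrats$is_first, quadrats$site_id, sum)
  if (any(firsts != 1))
    stop("quadrats: site(s) without exactly one first quadrat: ",
         paste(utils::head(names(firsts)[firsts != 1], 5), collapse = ", "))
  orphan <- !quadrats$site_id %in% sites$site_id
  fail_rows(orphan, "quadrats", "site_id not present in site table")
  list(sites = sites, quadrats = quadrats)
}

#' Write a survey to sites.csv and quadrats.csv
#'
#' @param survey list with `sites` and `quadrats` (as from
#'   [generate_survey()]).
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, "sites.csv"); qp <- file.path(dir, "quadrats.csv")
  utils::write.csv(survey$sites, sp, row.names = FALSE)
  utils::write.csv(survey$quadrats, qp, row.names = FALSE)
  invisible(c(sites = sp, quadrats = qp))
}

#' Read and validate a projection-site table
#'
#' @param path CSV path with the projection schema (`site_id`,
#'   `habitat_type`, covariates, `depth`, `area`).
#' @return Validated data frame.
#' @export
read_projection <- function(path) {
  proj <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(proj, PROJECTION_COLUMNS, "projection")
  proj$habitat_type <- normalize_habitat(proj$habitat_type)
  bad <- !proj$habitat_type %in% c("marina", "natural")
  fail_rows(bad, "projection", "habitat_type must be 'marina' or 'natural'")
  fail_rows(!is.finite(proj$area) | proj$area <= 0, "projection",
            "area must be positive")
  proj
}

#' @rdname read_projection
#' @param projection projection table to write.
#' @param path output CSV path.
#' @export
write_projection <- function(projection, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(projection, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may override any argument group of [pipeline_config()]
#' (`seed`, `generator`, `covariates`, `occurrence`, `abundance`,
#' `projection`); unset fields keep their defaults.
#'
#' @param path a `.yml`/`.yaml` or `.json` file.
#' @return A `pipeline_config` object.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}
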