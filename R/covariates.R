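#' Depth-attenuate surface wave exposure
#'
#' Wave action weakens with depth; surface exposure values are attenuated to
#' the sampling depth with an exponential decay, `E * exp(-k * depth)`. The
#' decay constant `k` is an external choice (the fetch-model literature does
#' not fix one); the default 0.5 per metre halves-ish exposure over the
#' 0--1 m survey band and can be overridden.
#'
#' @param exposure surface exposure (non-negative, any consistent unit).
#' @param depth depth in metres (non-negative).
#' @param k decay constant per metre.
#' @return Attenuated exposure; equals `exposure` at depth 0 and is
#'   monotonically non-increasing in depth.
#' @export
attenuate_exposure <- function(exposure, depth, k = 0.5) {
  if (any(depth < 0)) stop("depth must be non-negative")
  if (any(exposure < 0)) stop("exposure must be non-negative")
  if (k < 0) stop("attenuation coefficient k must be non-negative")
  exposure * exp(-k * depth)
}

#' Substitute implausibly exposed marina values
#'
#' Marinas are enclosed by breakwaters that regional fetch models often
#' ignore, so some marinas inherit open-water exposure values. Exposures
#' above `threshold` are replaced by the mean exposure of marinas at or
#' below it (the sheltered reference group). The operation is idempotent.
#'
#' @param marina_exposures numeric vector of marina exposure values.
#' @param threshold exposure above which a value is considered unphysical
#'   for a marina (default 10000, the "very sheltered" class boundary).
#' @return Vector with offending values replaced.
#' @export
substitute_marina_exposure <- function(marina_exposures, threshold = 10000) {
  stopifnot(is.numeric(marina_exposures), length(marina_exposures) >= 1,
            threshold > 0)
  sheltered <- marina_exposures <= threshold
  if (!any(sheltered))
    stop("no sheltered reference marinas: all exposures exceed the threshold")
  marina_exposures[!sheltered] <- mean(marina_exposures[sheltered])
  marina_exposures
}

#' Collinearity screen for candidate predictors
#'
#' Computes the pairwise Pearson correlation matrix and per-variable
#' variance inflation factors (VIF = 1 / (1 - R^2) of each variable
#' regressed on all others) and flags pairs with |r| at or above
#' `pearson_threshold` and variables with VIF at or above `vif_threshold`.
#' The screen is advisory: it reports, it does not drop columns. A constant
#' column is perfectly "explained" in no regression yet unusable, and is
#' flagged with an infinite-VIF sentinel.
#'
#' @param covariates data frame of numeric candidate predictors (>= 3 rows).
#' @param pearson_threshold pairwise |r| flag threshold (default 0.70).
#' @param vif_threshold VIF flag threshold (default 5).
#' @return Object of class `screen_report`: `correlation` (symmetric matrix,
#'   unit diagonal), `vif` (named vector, >= 1 or Inf), `flagged_pairs`,
#'   `flagged_variables`, `kept`, and the thresholds used.
#' @export
collinearity_screen <- function(covariates, pearson_threshold = 0.70,
                                vif_threshold = 5) {
  stopifnot(is.data.frame(covariates), pearson_threshold > 0, vif_threshold > 0)
  if (nrow(covariates) < 3) stop("need at least 3 rows to screen covariates")
  covariates <- covariates[vapply(covariates, is.numeric, logical(1))]
  p <- ncol(covariates)
  if (p < 2) stop("need at least two numeric columns to screen")
  vars <- names(covariates)
  constant <- vapply(covariates, function(x) stats::sd(x) == 0, logical(1))

  cmat <- diag(1, p); dimnames(cmat) <- list(vars, vars)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    r <- if (constant[i] || constant[j]) NA_real_ else
      stats::cor(covariates[[i]], covariates[[j]])
    cmat[i, j] <- cmat[j, i] <- r
  }

  vif <- vapply(seq_len(p), function(j) {
    if (constant[j]) return(Inf)
    others <- covariates[, -j, drop = FALSE]
    others <- others[!vapply(others, function(x) stats::sd(x) == 0, logical(1))]
    if (ncol(others) == 0) return(1)
    fit <- stats::lm(covariates[[j]] ~ ., data = others)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- vars

  idx <- which(abs(cmat) >= pearson_threshold & upper.tri(cmat), arr.ind = TRUE)
  flagged_pairs <- if (nrow(idx)) data.frame(
    var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
    r = cmat[idx], stringsAsFactors = FALSE) else
    data.frame(var1 = character(), var2 = character(), r = numeric())
  flagged_vars <- vars[vif >= vif_threshold | constant]

  structure(list(correlation = cmat, vif = vif,
                 flagged_pairs = flagged_pairs,
                 flagged_variables = flagged_vars,
                 kept = setdiff(vars, flagged_vars),
                 pearson_threshold = pearson_threshold,
                 vif_threshold = vif_threshold),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Collinearity screen (|r| >=", x$pearson_threshold, ", VIF >=",
      x$vif_threshold, "flagged)\n")
  cat("VIF:\n"); print(round(x$vif, 3))
  if (nrow(x$flagged_pairs)) {
    cat("Flagged pairs:\n"); print(x$flagged_pairs)
  } else cat("No correlated pairs flagged.\n")
  if (length(x$flagged_variables))
    cat("Flagged variables:", paste(x$flagged_variables, collapse = ", "), "\n")
  invisible(x)
}
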