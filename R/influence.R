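## Predictor-influence tools shared by the occurrence and abundance models.
## A "model" here is either a fitted oysterfront model (occ_ensemble on the
## probability scale, abundance_model on the bias-corrected log scale) or a
## plain function(data) -> numeric, which makes oracle checks direct.

influence_predict <- function(model, data) {
  if (is.function(model)) return(as.numeric(model(data)))
  if (inherits(model, "occ_ensemble"))
    return(predict(model, data, warn_extrapolation = FALSE)$probability)
  if (inherits(model, "abundance_model"))
    return(predict(model, data, type = "log"))
  stop("unsupported model class: ", paste(class(model), collapse = "/"))
}

model_variables <- function(model, variables) {
  if (!is.null(variables)) return(variables)
  if (is.function(model))
    stop("variables must be given explicitly for a function model")
  model$predictors
}

#' Permutation importance of each predictor
#'
#' Importance of a variable is the average, over `n_runs` seeded
#' permutations, of 1 minus the Pearson correlation between the model's
#' original predictions and its predictions after permuting that variable's
#' column. Values lie in \[0, 2\]; a variable the model ignores scores 0.
#' Importances are reported raw (they need not sum to 1). Permutations are
#' drawn independently per variable and run.
#'
#' @param model fitted `occ_ensemble`, `abundance_model`, or a
#'   `function(data)` returning predictions.
#' @param data data frame (>= 3 rows) on which influence is measured.
#' @param variables variables to assess (default: the model's predictors).
#' @param n_runs permutations per variable (default 3).
#' @param seed integer seed for the permutations.
#' @return Data frame of class `importance_table` with `variable` and
#'   `importance`, sorted decreasing.
#' @export
permutation_importance <- function(model, data, variables = NULL,
                                   n_runs = 3, seed = 1) {
  stopifnot(is.data.frame(data), nrow(data) >= 3, n_runs >= 1)
  variables <- model_variables(model, variables)
  base <- influence_predict(model, data)
  constant_base <- stats::sd(base) < 1e-12
  if (constant_base)
    warning("constant model predictions: correlations undefined, importances 0")
  set.seed(seed)
  imp <- vapply(variables, function(v) {
    vals <- vapply(seq_len(n_runs), function(run) {
      perm <- data
      perm[[v]] <- perm[[v]][sample.int(nrow(data))]
      p <- influence_predict(model, perm)
      if (constant_base || stats::sd(p) < 1e-12) {
        if (identical(p, base) || isTRUE(all.equal(p, base))) 0 else NA_real_
      } else 1 - stats::cor(base, p)
    }, numeric(1))
    mean(ifelse(is.na(vals), 0, vals))
  }, numeric(1))
  out <- data.frame(variable = variables, importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("importance_table", "data.frame"),
            n_runs = n_runs, seed = seed)
}

#' Evaluation-strip response curve
#'
#' Predicts along a strip of `n_points` values spanning the observed
#' interval of one variable, with all other predictors fixed at their
#' medians. Occurrence models respond on the probability scale, abundance
#' models on the bias-corrected log scale.
#'
#' @param model as in [permutation_importance()].
#' @param variable the variable to vary.
#' @param data data frame providing the observed interval and the medians.
#' @param n_points grid size (default 100).
#' @param range optional explicit `c(lo, hi)` overriding the observed
#'   interval (e.g. to probe slightly beyond it).
#' @return Data frame of class `response_curve` with strictly increasing
#'   `value` and the `response` at each grid point.
#' @export
response_curve <- function(model, variable, data, n_points = 100, range = NULL) {
  stopifnot(is.data.frame(data), variable %in% names(data), n_points >= 2)
  if (is.null(range)) range <- base::range(data[[variable]])
  if (diff(range) <= 0)
    stop("variable '", variable, "' has a degenerate observed range")
  grid <- seq(range[1], range[2], length.out = n_points)
  strip <- as.data.frame(lapply(data, function(col)
    rep(if (is.numeric(col)) stats::median(col) else col[1], n_points)))
  strip[[variable]] <- grid
  structure(data.frame(value = grid,
                       response = influence_predict(model, strip)),
            class = c("response_curve", "data.frame"), variable = variable)
}

#' Two-variable partial dependence surface
#'
#' Marginal joint effect of two predictors: at each point of a
#' `grid_n` x `grid_n` grid the two variables are clamped to the grid value
#' in every data row and the predictions averaged (data-averaged clamping,
#' in contrast to the median-fixing evaluation strip).
#'
#' @param model as in [permutation_importance()].
#' @param var1,var2 the two variables.
#' @param data data frame averaged over.
#' @param grid_n grid size per axis (default 20).
#' @return List of class `partial_dependence` with `x` (grid of `var1`),
#'   `y` (grid of `var2`) and matrix `z` (`x` by `y`).
#' @export
partial_dependence_2d <- function(model, var1, var2, data, grid_n = 20) {
  stopifnot(is.data.frame(data), var1 %in% names(data), var2 %in% names(data),
            grid_n >= 2)
  for (v in c(var1, var2))
    if (diff(range(data[[v]])) <= 0)
      stop("variable '", v, "' has a degenerate observed range")
  gx <- seq(min(data[[var1]]), max(data[[var1]]), length.out = grid_n)
  gy <- seq(min(data[[var2]]), max(data[[var2]]), length.out = grid_n)
  z <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
    clamped <- data
    clamped[[var1]] <- gx[i]
    clamped[[var2]] <- gy[j]
    z[i, j] <- mean(influence_predict(model, clamped))
  }
  structure(list(x = gx, y = gy, z = z, var1 = var1, var2 = var2),
            class = "partial_dependence")
}

#' @export
print.importance_table <- function(x, ...) {
  cat("Permutation importance (1 - Pearson r, mean of", attr(x, "n_runs"),
      "runs)\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
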