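#' Fit a committee of presence-absence models by repeated split-sampling
#'
#' Candidate occurrence models are fitted with four algorithm families --
#' logistic GLM, spline logistic (GAM), gradient-boosted trees, and random
#' forest -- on repeated random 80/20 train/validation splits of the
#' presence table. Each (family, split) pair yields one committee member
#' with a holdout AUC and TSS; members from splits whose training half
#' contains a single class are skipped with a warning, as are members whose
#' fit fails. Everything is deterministic given `seed`.
#'
#' The occurrence table should describe conditions where the species
#' actually sits when present: on the standard survey design this is the
#' first (targeted) quadrat's substrate together with site-level salinity
#' and exposure.
#'
#' @param data data frame with a logical/0-1 `presence` column and the
#'   predictor columns.
#' @param predictors predictor column names.
#' @param families subset of `c("glm", "gam", "gbm", "rf")`.
#' @param n_splits number of random splits (default 100).
#' @param train_frac training fraction per split (default 0.8).
#' @param seed integer seed governing all splits and stochastic fits.
#' @param control list of per-family settings: `gam_k` (spline basis
#'   dimension, default 4), `rf_trees` (default 500), `gbm_rounds` (default
#'   100), `gbm_depth` (default 2), `gbm_eta` (default 0.1). These are
#'   sensible small-sample defaults; the gate/ensemble logic, not tuning,
#'   is the point.
#' @return Object of class `occ_committee` holding the members (with
#'   validation AUC/TSS), the calibration data, and the settings.
#' @export
fit_committee <- function(data, predictors = c("substrate_cover", "min_salinity", "exposure"),
                          families = c("glm", "gam", "gbm", "rf"),
                          n_splits = 100, train_frac = 0.8, seed = 1,
                          control = list()) {
  stopifnot(is.data.frame(data), "presence" %in% names(data),
            all(predictors %in% names(data)),
            n_splits >= 1, train_frac > 0, train_frac < 1)
  families <- match.arg(families, c("glm", "gam", "gbm", "rf"), several.ok = TRUE)
  ctl <- utils::modifyList(list(gam_k = 4, rf_trees = 500, gbm_rounds = 100,
                                gbm_depth = 2, gbm_eta = 0.1), control)
  d <- data[c("presence", predictors)]
  d$presence01 <- as.integer(as.logical(d$presence))
  n1 <- sum(d$presence01); n0 <- nrow(d) - n1
  if (n1 == 0 || n0 == 0) stop("both presences and absences are required")
  if (n1 < 10 * length(predictors))
    warning("fewer than 10 presences per predictor (", n1, " presences, ",
            length(predictors), " predictors); estimates may be unstable")

  n <- nrow(d)
  n_train <- max(2L, round(train_frac * n))
  set.seed(seed)
  members <- list(); skipped <- 0L
  for (s in seq_len(n_splits)) {
    if (s %% 25L == 0L) gc(verbose = FALSE) # release dropped native handles
    idx <- sample.int(n, n_train)
    train <- d[idx, ]; valid <- d[-idx, ]
    if (length(unique(train$presence01)) < 2) {
      warning("split ", s, ": single class in training data; members skipped")
      skipped <- skipped + length(families)
      next
    }
    for (fam in families) {
      fit <- tryCatch(fit_occ_member(fam, train, predictors, ctl),
                      error = function(e) {
                        warning("split ", s, " (", fam, "): fit failed (",
                                conditionMessage(e), "); member skipped")
                        NULL
                      })
      if (is.null(fit)) { skipped <- skipped + 1L; next }
      p_val <- predict_occ_member(fit, fam, valid, predictors)
      two_class <- length(unique(valid$presence01)) == 2
      members[[length(members) + 1L]] <- list(
        family = fam, split = s, fit = fit,
        auc = if (two_class) auc_score(p_val, valid$presence01) else NA_real_,
        tss = if (two_class) tss_score(p_val, valid$presence01)$tss else NA_real_)
    }
  }
  structure(list(members = members, predictors = predictors,
                 families = families, n_splits = n_splits,
                 n_attempted = n_splits * length(families),
                 n_skipped = skipped, data = d, control = ctl, seed = seed),
            class = "occ_committee")
}

fit_occ_member <- function(family, train, predictors, ctl) {
  switch(family,
    glm = suppressWarnings(
      stats::glm(stats::reformulate(predictors, "presence01"),
                 family = stats::binomial(), data = train)),
    gam = {
      terms <- vapply(predictors, function(v) {
        k <- min(ctl$gam_k, length(unique(train[[v]])) - 1L)
        if (k >= 3) sprintf("s(%s, k = %d)", v, k) else v
      }, character(1))
      fm <- stats::as.formula(paste("presence01 ~", paste(terms, collapse = " + ")))
      suppressWarnings(mgcv::gam(fm, family = stats::binomial(), data = train,
                                 method = "REML"))
    },
    gbm = {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(train[predictors]),
                                     label = train$presence01, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = ctl$gbm_depth, eta = ctl$gbm_eta,
                      nthread = 1),
        data = dtrain, nrounds = ctl$gbm_rounds)
      # keep only the serialized model: booster handles are native memory
      # invisible to R's GC, and committees create hundreds of them
      out <- list(raw = xgboost::xgb.save.raw(fit),
                  cache = new.env(parent = emptyenv()))
      class(out) <- "of_gbm_member"
      out
    },
    rf = randomForest::randomForest(
      x = train[predictors],
      y = factor(train$presence01, levels = c(0, 1)),
      ntree = ctl$rf_trees),
    stop("unknown family: ", family))
}

predict_occ_member <- function(fit, family, newdata, predictors) {
  p <- switch(family,
    glm = stats::predict(fit, newdata = newdata, type = "response"),
    gam = as.numeric(stats::predict(fit, newdata = newdata, type = "response")),
    gbm = {
      bst <- fit$cache$booster
      if (is.null(bst)) {
        bst <- xgboost::xgb.load.raw(fit$raw)
        fit$cache$booster <- bst
      }
      stats::predict(bst, as.matrix(newdata[predictors]))
    },
    rf = stats::predict(fit, newdata = newdata[predictors], type = "prob")[, "1"])
  pmin(1, pmax(0, as.numeric(p)))
}

#' Build the gated ensemble from a fitted committee
#'
#' Members whose validation AUC and TSS both meet the inclusion gates
#' (defaults 0.70 and 0.50, the "fair" boundary) enter the ensemble; all
#' others are discarded. The ensemble prediction is the unweighted mean of
#' included members' occurrence probabilities. The ensemble is then
#' calibrated on the full fitting data: its calibration AUC, and a default
#' probability cutoff chosen to maximise sensitivity + specificity (the TSS
#' optimizer; ties broken toward 0.5).
#'
#' @param committee an [fit_committee()] result.
#' @param auc_min,tss_min inclusion gates on validation AUC and TSS.
#' @return Object of class `occ_ensemble`: included `members`,
#'   `inclusion_fraction` (of attempted fits), `calibration_auc`, `cutoff`,
#'   `sensitivity`/`specificity` at the cutoff, predictor ranges.
#' @export
build_ensemble <- function(committee, auc_min = 0.70, tss_min = 0.50) {
  stopifnot(inherits(committee, "occ_committee"))
  auc <- vapply(committee$members, `[[`, numeric(1), "auc")
  tss <- vapply(committee$members, `[[`, numeric(1), "tss")
  keep <- !is.na(auc) & !is.na(tss) & auc >= auc_min & tss >= tss_min
  if (!any(keep))
    stop(sprintf(paste0("empty ensemble: no member passed the gates ",
                        "(AUC >= %.2f, TSS >= %.2f); best achieved AUC = %.3f, ",
                        "TSS = %.3f"), auc_min, tss_min,
                 max(auc, na.rm = TRUE), max(tss, na.rm = TRUE)))
  members <- committee$members[keep]

  cal <- committee$data
  probs <- member_probability_matrix(members, cal, committee$predictors)
  p_ens <- rowMeans(probs)
  cal_auc <- auc_score(p_ens, cal$presence01)
  opt <- tss_score(p_ens, cal$presence01)
  cutoff <- min(1 - 1e-9, max(1e-9, opt$threshold))

  ranges <- lapply(cal[committee$predictors], range)
  structure(list(members = members, predictors = committee$predictors,
                 auc_min = auc_min, tss_min = tss_min,
                 n_included = length(members),
                 n_attempted = committee$n_attempted,
                 inclusion_fraction = length(members) / committee$n_attempted,
                 calibration_auc = cal_auc, cutoff = cutoff,
                 sensitivity = opt$sensitivity, specificity = opt$specificity,
                 training_ranges = ranges),
            class = "occ_ensemble")
}

member_probability_matrix <- function(members, newdata, predictors) {
  vapply(members,
         function(m) predict_occ_member(m$fit, m$family, newdata, predictors),
         numeric(nrow(newdata)))
}

#' Predict occurrence from the ensemble
#'
#' Returns the committee-mean occurrence probability and the binary
#' presence call at the ensemble's optimized cutoff. The boundary rule is
#' strict: a probability exactly equal to the cutoff is classified absent.
#' Covariates outside the training range trigger an extrapolation warning.
#'
#' @param object an `occ_ensemble`.
#' @param newdata data frame containing the predictor columns.
#' @param warn_extrapolation warn when covariates leave the training range.
#' @param ... unused.
#' @return Data frame with `probability` and logical `presence`.
#' @export
predict.occ_ensemble <- function(object, newdata, warn_extrapolation = TRUE, ...) {
  missing_cov <- setdiff(object$predictors, names(newdata))
  if (length(missing_cov))
    stop("missing covariate(s): ", paste(missing_cov, collapse = ", "))
  if (warn_extrapolation) {
    for (v in object$predictors) {
      r <- object$training_ranges[[v]]
      if (any(newdata[[v]] < r[1] | newdata[[v]] > r[2]))
        warning("covariate '", v, "' outside the training range [",
                signif(r[1], 4), ", ", signif(r[2], 4), "]; extrapolating")
    }
  }
  probs <- member_probability_matrix(object$members, newdata, object$predictors)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(newdata))
  p <- rowMeans(probs)
  data.frame(probability = p, presence = p > object$cutoff)
}

#' @export
print.occ_ensemble <- function(x, ...) {
  cat("Presence-absence ensemble\n")
  cat(sprintf("  %d of %d candidate members included (%.0f%%); gates AUC >= %.2f, TSS >= %.2f\n",
              x$n_included, x$n_attempted, 100 * x$inclusion_fraction,
              x$auc_min, x$tss_min))
  cat(sprintf("  calibration AUC = %.3f; cutoff = %.3f (sens %.2f, spec %.2f)\n",
              x$calibration_auc, x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}
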