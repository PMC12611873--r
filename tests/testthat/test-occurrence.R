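test_that("committee fitting is deterministic given the seed", {
  d <- separable_presence_table(40)
  a <- suppressWarnings(fit_committee(d, predictors = names(d)[1:3],
                                      families = c("glm", "rf"),
                                      n_splits = 6, seed = 3))
  b <- suppressWarnings(fit_committee(d, predictors = names(d)[1:3],
                                      families = c("glm", "rf"),
                                      n_splits = 6, seed = 3))
  expect_equal(vapply(a$members, `[[`, numeric(1), "auc"),
               vapply(b$members, `[[`, numeric(1), "auc"))
  expect_equal(vapply(a$members, `[[`, numeric(1), "tss"),
               vapply(b$members, `[[`, numeric(1), "tss"))
})

test_that("perfectly separable data yields perfect holdout AUC", {
  d <- separable_presence_table(40)
  cm <- suppressWarnings(fit_committee(d, predictors = names(d)[1:3],
                                       families = c("glm", "rf"),
                                       n_splits = 8, seed = 1))
  auc <- vapply(cm$members, `[[`, numeric(1), "auc")
  expect_true(all(auc[!is.na(auc)] == 1))
})

test_that("labels shuffled off the covariates give chance-level AUC", {
  # splits of one dataset share its accidental label-covariate correlation,
  # so the Monte Carlo unit is the dataset: fresh shuffle per replicate
  set.seed(20)
  dataset_mean_auc <- vapply(1:15, function(i) {
    d <- data.frame(substrate_cover = runif(60, 0, 100),
                    min_salinity = runif(60, 8, 25),
                    exposure = rlnorm(60, 9, 1),
                    presence = sample(rep(c(TRUE, FALSE), 30)))
    cm <- suppressWarnings(fit_committee(d, predictors = names(d)[1:3],
                                         families = "glm", n_splits = 10,
                                         seed = i))
    auc <- vapply(cm$members, `[[`, numeric(1), "auc")
    mean(auc, na.rm = TRUE)
  }, numeric(1))
  se <- sd(dataset_mean_auc) / sqrt(length(dataset_mean_auc))
  expect_lt(abs(mean(dataset_mean_auc) - 0.5), 3 * se)
})

test_that("ensemble averages member probabilities and respects the gates", {
  d <- separable_presence_table(40)
  cm <- suppressWarnings(fit_committee(d, predictors = names(d)[1:3],
                                       families = c("glm", "rf"),
                                       n_splits = 5, seed = 7))
  # accept-all gates: ensemble mean equals pointwise member mean
  ens <- build_ensemble(cm, auc_min = 0, tss_min = -1)
  probs <- vapply(ens$members, function(m)
    oysterfront:::predict_occ_member(m$fit, m$family, cm$data, cm$predictors),
    numeric(nrow(cm$data)))
  pred <- predict(ens, cm$data, warn_extrapolation = FALSE)
  expect_equal(pred$probability, rowMeans(probs), tolerance = 1e-12)
  # bounded by member envelope
  expect_true(all(pred$probability >= apply(probs, 1, min) - 1e-12))
  expect_true(all(pred$probability <= apply(probs, 1, max) + 1e-12))

  # tighter gates include weakly fewer members
  strict <- build_ensemble(cm, auc_min = 0.7, tss_min = 0.5)
  expect_lte(strict$n_included, ens$n_included)
  expect_true(strict$cutoff > 0 && strict$cutoff < 1)
  expect_equal(strict$inclusion_fraction, strict$n_included / cm$n_attempted)

  expect_error(build_ensemble(cm, auc_min = 1.01, tss_min = 1),
               "empty ensemble")
})

test_that("single-member ensemble reproduces that member", {
  d <- separable_presence_table(30)
  cm <- suppressWarnings(fit_committee(d, predictors = names(d)[1:3],
                                       families = "glm", n_splits = 1, seed = 4))
  ens <- build_ensemble(cm, auc_min = 0, tss_min = -1)
  expect_equal(ens$n_included, 1)
  p_member <- oysterfront:::predict_occ_member(ens$members[[1]]$fit, "glm",
                                               d, cm$predictors)
  expect_equal(predict(ens, d, warn_extrapolation = FALSE)$probability,
               p_member, tolerance = 1e-12)
})

test_that("prediction applies the strict cutoff boundary and validates inputs", {
  d <- separable_presence_table(30)
  ens <- build_ensemble(suppressWarnings(
    fit_committee(d, predictors = names(d)[1:3], families = "glm",
                  n_splits = 2, seed = 4)), auc_min = 0, tss_min = -1)
  pred <- predict(ens, d, warn_extrapolation = FALSE)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))

  # probability exactly at the cutoff classifies as absence
  ens$cutoff <- pred$probability[1]
  pred2 <- predict(ens, d[1, , drop = FALSE], warn_extrapolation = FALSE)
  expect_false(pred2$presence)

  expect_error(predict(ens, d[c("substrate_cover", "min_salinity")]),
               "exposure")
  expect_warning(
    predict(ens, transform(d[1, ], substrate_cover = 1e4)),
    "outside the training range")
})

test_that("training splits with a single class are skipped with a warning", {
  set.seed(30)
  d <- data.frame(substrate_cover = runif(12, 0, 100),
                  min_salinity = runif(12, 8, 25),
                  exposure = rlnorm(12, 9, 1),
                  presence = c(TRUE, rep(FALSE, 11)))
  expect_warning(
    cm <- fit_committee(d, predictors = names(d)[1:3], families = "glm",
                        n_splits = 25, train_frac = 0.8, seed = 1),
    "single class|fewer than 10")
  expect_lt(length(cm$members), 25)
})

test_that("fitted ensemble recovers the substrate-driven occurrence response", {
  fit <- fixture_fit()
  sites <- fit$survey$sites
  first <- fit$survey$quadrats[fit$survey$quadrats$is_first,
                               c("site_id", "substrate_cover")]
  occ_tab <- merge(sites[c("site_id", "min_salinity", "exposure")], first,
                   by = "site_id")
  curve <- response_curve(fit$ensemble, "substrate_cover", occ_tab)
  expect_gt(cor(curve$value, curve$response, method = "spearman"), 0.8)
  expect_gt(curve$response[nrow(curve)], curve$response[1])
})
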