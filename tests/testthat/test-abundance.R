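make_abundance_table <- function(n = 30, seed = 1, noise = 0.3) {
  set.seed(seed)
  d <- data.frame(substrate_cover = runif(n, 20, 100),
                  min_salinity = runif(n, 8, 25),
                  exposure = rlnorm(n, 9, 1.2))
  d$abundance <- exp(4 - 0.9 * log10(d$exposure) + rnorm(n, 0, noise))
  d
}

test_that("bias line solves the observed-on-predicted least squares", {
  expect_equal(bias_correct(c(1, 2, 3), c(1, 2, 3)),
               c(a_bc = 0, b_bc = 1), tolerance = 1e-12)
  bl <- bias_correct(c(1, 2, 3), c(2, 4, 6))
  expect_equal(bl, c(a_bc = 0, b_bc = 2), tolerance = 1e-12)
  expect_equal(bl[["a_bc"]] + bl[["b_bc"]] * 1.5, 3)
  expect_warning(bias_correct(rep(2, 5), 1:5), "constant")
  expect_error(bias_correct(1:2, 1:2), "3 points")

  # slope above 1 stretches the prediction spread
  set.seed(1)
  pred <- rnorm(20); obs <- 1.5 * pred + rnorm(20, 0, 0.1)
  bl2 <- bias_correct(pred, obs)
  corrected <- bl2[["a_bc"]] + bl2[["b_bc"]] * pred
  expect_gte(var(corrected), var(pred))
})

test_that("smearing factor is the mean of exponentiated residuals", {
  expect_equal(smearing_factor(c(0, 0, 0)), 1)
  expect_equal(smearing_factor(c(log(2), -log(2))), 1.25)
  expect_error(smearing_factor(c(0.1, NA)), "non-finite")
  expect_error(smearing_factor(numeric(0)), "no residuals")
  # Jensen: mean-zero residuals smear at or above 1
  set.seed(2)
  for (i in 1:10) {
    r <- rnorm(15); r <- r - mean(r)
    expect_gte(smearing_factor(r), 1)
  }
})

test_that("constant response collapses to near-zero CV RMSE and constant predictions", {
  d <- make_abundance_table(18, seed = 3)
  d$abundance <- 5
  fit <- suppressWarnings(fit_abundance(d, folds = 3, repeats = 2, seed = 1))
  expect_lt(fit$cv_rmse, 1e-8)
  p <- predict(fit, d)
  expect_lt(diff(range(p)), 1e-6)
  expect_equal(unname(p[1]), 5, tolerance = 1e-6)
})

test_that("a strong covariate signal beats the intercept-only baseline", {
  d <- make_abundance_table(30, seed = 4, noise = 0.3)
  fit <- fit_abundance(d, folds = 6, repeats = 2, seed = 2)
  expect_lt(fit$cv_rmse, sd(log(d$abundance)))
  expect_true(all(fit$cv_table$rmse > 0))
})

test_that("abundance fitting is deterministic and validates its inputs", {
  d <- make_abundance_table(12, seed = 5)
  a <- fit_abundance(d, folds = 3, repeats = 2, seed = 9)
  b <- fit_abundance(d, folds = 3, repeats = 2, seed = 9)
  expect_equal(a$cv_table, b$cv_table)
  expect_equal(predict(a, d), predict(b, d))
  expect_error(fit_abundance(d[1:2, ], folds = 3), "fewer folds")
  d$abundance[1] <- 0
  expect_error(fit_abundance(d, folds = 3), "positive")
})

test_that("the retransformation chain is positive and reduces to exp() in the limit", {
  d <- make_abundance_table(20, seed = 6)
  fit <- fit_abundance(d, folds = 4, repeats = 2, seed = 3)
  expect_true(all(predict(fit, d) > 0))
  expect_true(fit$smearing >= 0)
  expect_equal(fit$smearing,
               mean(exp(fit$log_observed -
                        (fit$bias_line[["a_bc"]] +
                         fit$bias_line[["b_bc"]] * fit$oob_log_predictions))))

  # frozen corrections: back-transform is plain exponentiation
  frozen <- fit
  frozen$bias_line <- c(a_bc = 0, b_bc = 1)
  frozen$smearing <- 1
  expect_equal(predict(frozen, d),
               exp(predict(frozen, d, type = "log")), tolerance = 1e-12)
  expect_error(predict(fit, d[c("substrate_cover", "min_salinity")]),
               "exposure")
})

test_that("fitted abundance declines with exposure on the evaluation strip", {
  fit <- fixture_fit()
  sites <- fit$survey$sites
  pres <- sites[sites$presence, ]
  curve <- response_curve(fit$abundance, "exposure", pres)
  expect_lt(curve$response[nrow(curve)], curve$response[1])
  expect_lt(cor(curve$value, curve$response, method = "spearman"), 0)
})
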