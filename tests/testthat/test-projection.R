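test_that("possible population size is the product of its factors", {
  expect_equal(population_size(3.0, 8.6e6), 25.8e6)
  expect_equal(population_size(5, Ah = 1000, Ph = 0), 0)
  expect_equal(population_size(2.5, 2 * 4e6), 2 * population_size(2.5, 4e6))
  expect_error(population_size(-1, 10))
})

test_that("length-weight calibration solves the allometric anchors", {
  lw <- lw_calibrate(c(62.5, 107.5), c(40, 140))
  # oracle: 2x2 solve of the log-log system
  b_oracle <- (log(140) - log(40)) / (log(107.5) - log(62.5))
  a_oracle <- exp(log(40) - b_oracle * log(62.5))
  expect_equal(lw$b, b_oracle, tolerance = 1e-12)
  expect_equal(lw$a, a_oracle, tolerance = 1e-12)
  expect_equal(lw$b, 2.31, tolerance = 0.005)
  expect_equal(predict(lw, 62.5), 40, tolerance = 1e-9)
  expect_equal(predict(lw, 107.5), 140, tolerance = 1e-9)

  expect_equal(lw_calibrate(c(50, 100), c(30, 30))$b, 0)
  expect_error(lw_calibrate(c(50, 50), c(30, 40)), "distinct")

  # >2 anchors: log-log least squares matches the lm oracle
  set.seed(1)
  L <- seq(20, 200, by = 20); W <- 0.0005 * L^2.2 * exp(rnorm(10, 0, 0.05))
  lw2 <- lw_calibrate(L, W)
  fit <- lm(log(W) ~ log(L))
  expect_equal(lw2$b, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(lw2$a, exp(unname(coef(fit)[1])), tolerance = 1e-12)
})

test_that("biomass partitions over length classes and scales with N", {
  freqs <- data.frame(midpoint = 62.5, freq = 1)
  b <- biomass_estimate(1e6, freqs)
  expect_equal(b$total_t, 40, tolerance = 1e-6)
  expect_equal(biomass_estimate(0, freqs)$total_t, 0)

  cfg <- generator_config()
  f <- length_class_freqs(cfg, "marina")
  bm <- biomass_estimate(5e5, f)
  expect_equal(sum(bm$per_class$contribution_t), bm$total_t, tolerance = 1e-12)

  bad <- data.frame(midpoint = c(60, 100), freq = c(0.5, 0.4))
  expect_error(biomass_estimate(1e3, bad), "sum to 1")
})

test_that("per-unit-area standardization reproduces hand ratios", {
  est <- data.frame(habitat = c("marina", "natural_rocky"),
                    xbar = c(10, 5), prevalence = c(0.5, 0.5),
                    biomass_t = c(2, 1), area_m2 = c(1e4, 1e4))
  class(est) <- c("habitat_estimates", "data.frame")
  pu <- per_unit_area(est)
  expect_equal(pu$abundance_ratio, 2)
  expect_equal(pu$biomass_ratio, 2)

  # prevalence 1 on both sides reduces to the ratio of means
  est$prevalence <- 1
  expect_equal(per_unit_area(est)$abundance_ratio, 10 / 5)

  # ratios invariant to a common rescaling of the areas
  est2 <- est; est2$area_m2 <- est2$area_m2 * 7
  expect_equal(per_unit_area(est2)$biomass_ratio, per_unit_area(est)$biomass_ratio)
})

test_that("bootstrap CI is percentile-based around the plug-in statistic", {
  x <- rep(4.2, 10)
  ci <- bootstrap_ci(x, mean, n_boot = 100, seed = 1)
  expect_equal(unname(ci), c(4.2, 4.2, 4.2))

  set.seed(2)
  y <- rlnorm(30, 1, 0.5)
  ci2 <- bootstrap_ci(y, mean, n_boot = 500, seed = 3)
  expect_equal(ci2[["point"]], mean(y))
  expect_lt(ci2[["lower"]], mean(y)); expect_gt(ci2[["upper"]], mean(y))
  expect_identical(ci2, bootstrap_ci(y, mean, n_boot = 500, seed = 3))

  expect_warning(ci3 <- bootstrap_ci(5, mean), "single")
  expect_equal(unname(ci3), c(5, 5, 5))
})

make_projected_toy <- function() {
  data.frame(
    site_id = paste0("s", 1:8),
    habitat_type = c(rep("marina", 3), rep("natural", 5)),
    substrate_cover = c(100, 100, 100, 50, 30, 0, 0, 80),
    area = c(300, 400, 300, 1e5, 2e5, 1e5, 1e5, 1e5),
    presence = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    possible_abundance = c(12, 8, NA, 3, NA, NA, NA, 5))
}

test_that("habitat estimates satisfy the N = xbar * Ph * Ah identity", {
  toy <- make_projected_toy()
  freqs <- list(marina = data.frame(midpoint = 107.5, freq = 1),
                natural_rocky = data.frame(midpoint = 62.5, freq = 1))
  est <- habitat_estimates(toy, freqs, n_boot = 200, seed = 4)

  m <- est[est$habitat == "marina", ]
  expect_equal(m$xbar, 10)
  expect_equal(m$prevalence, 2 / 3)
  expect_equal(m$area_m2, 1000)
  expect_equal(m$N, 10 * (2 / 3) * 1000, tolerance = 1e-12)
  expect_equal(m$invaded_area_m2, m$prevalence * m$area_m2)

  r <- est[est$habitat == "natural_rocky", ]
  rocky_frac <- 3 / 5
  expect_equal(r$area_m2, 6e5 * rocky_frac)
  expect_equal(r$prevalence, 2 / 3)             # 2 of 3 rocky sites present
  expect_equal(r$N, r$xbar * r$prevalence * r$area_m2, tolerance = 1e-12)

  o <- est[est$habitat == "natural_overall", ]
  expect_equal(o$prevalence, 2 / 5)
  expect_true(is.na(o$N))

  # degree-1 homogeneity in area
  toy2 <- toy; toy2$area <- toy2$area * 2
  est2 <- habitat_estimates(toy2, freqs, n_boot = 50, seed = 4)
  expect_equal(est2$N[1:2], 2 * est$N[1:2], tolerance = 1e-12)

  # non-degenerate bootstrap brackets the point estimate
  expect_true(all(est$N_lo[1:2] <= est$N[1:2] + 1e-9))
  expect_true(all(est$N_hi[1:2] >= est$N[1:2] - 1e-9))
})

test_that("projection applies the hurdle and validates habitat labels", {
  fit <- fixture_fit()
  proj <- generate_projection_set(fit$manifest$stage_seeds["generator"] |>
                                    (\(s) generator_config(seed = s))(),
                                  n_marinas = 10, n_natural = 20)
  proj <- prepare_covariates(proj)
  out <- project_sites(fit$ensemble, fit$abundance, proj)
  expect_true(all(is.na(out$possible_abundance[!out$presence])))
  expect_true(all(out$possible_abundance[out$presence] > 0))
  expect_equal(mean(out$presence), sum(out$presence) / nrow(out))

  # identical sites get identical predictions
  same <- out[rep(1, 4), ]
  p <- project_sites(fit$ensemble, fit$abundance, same[names(proj)])
  expect_equal(length(unique(p$probability)), 1)

  bad <- proj; bad$habitat_type[1] <- "pier"
  expect_error(project_sites(fit$ensemble, fit$abundance, bad),
               "unknown habitat")
})

test_that("zero-substrate natural sites are predicted absent under the substrate-driven truth", {
  fit <- fixture_fit()
  nat <- fit$projected[fit$projected$habitat_type == "natural", ]
  bare <- nat[nat$substrate_cover == 0, ]
  expect_gt(nrow(bare), 0)
  expect_true(mean(bare$presence) < 0.1)
})
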