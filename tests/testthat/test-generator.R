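test_that("generation is bit-reproducible given the seed", {
  cfg <- generator_config(seed = 42)
  a <- generate_survey(cfg)
  b <- generate_survey(cfg)
  expect_identical(a, b)
  expect_identical(generate_projection_set(cfg, 10, 20),
                   generate_projection_set(cfg, 10, 20))
})

test_that("survey tables satisfy the design invariants", {
  sv <- generate_survey(generator_config(seed = 3))
  expect_equal(nrow(sv$sites), 45)
  expect_equal(nrow(sv$quadrats), 45 * 5)
  expect_true(all(sv$sites$substrate_cover >= 0 & sv$sites$substrate_cover <= 100))
  expect_true(all(sv$sites$true_density >= 0))
  expect_true(all(sv$quadrats$count >= 0))
  expect_true(all(sv$quadrats$count == round(sv$quadrats$count)))

  firsts <- tapply(sv$quadrats$is_first, sv$quadrats$site_id, sum)
  expect_true(all(firsts == 1))

  # targeted placement: first quadrat holds the site maximum count
  by_site <- split(sv$quadrats, sv$quadrats$site_id)
  expect_true(all(vapply(by_site, function(q)
    q$count[q$is_first] >= max(q$count), logical(1))))

  # absence implies empty quadrats
  absent <- sv$sites$site_id[!sv$sites$presence]
  expect_true(all(sv$quadrats$count[sv$quadrats$site_id %in% absent] == 0))
})

test_that("null abundance slopes give equal habitat means up to Monte Carlo error", {
  cfg <- generator_config(
    n_sites_per_habitat = 200,
    abn_coefs = c(intercept = log(6), exposure = 0, substrate = 0),
    breakpoint_decline = 0, seed = 9)
  sv <- generate_survey(cfg)
  ab <- site_abundance_table(sv$quadrats, sv$sites, cfg$quadrat_area)
  occ <- ab[ab$abundance > 0, ]
  means <- tapply(occ$abundance, occ$habitat_type, mean)
  expect_lt(max(means) / min(means), 1.2)
})

test_that("presence rate under an intercept-only occurrence truth matches the closed form", {
  p0 <- 0.4
  cfg <- generator_config(
    n_sites_per_habitat = 300,
    occ_coefs = c(intercept = qlogis(p0), substrate = 0, salinity = 0,
                  exposure = 0),
    seed = 21)
  sv <- generate_survey(cfg)
  n <- nrow(sv$sites)
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(sv$sites$presence) - p0), 3 * se)
})

test_that("targeted first quadrat biases site abundance upward relative to truth", {
  cfg <- generator_config(n_sites_per_habitat = 200, seed = 13)
  sv <- generate_survey(cfg)
  ab <- site_abundance_table(sv$quadrats, quadrat_area = cfg$quadrat_area)
  d <- merge(ab, sv$sites[c("site_id", "true_density", "presence")], by = "site_id")
  d <- d[d$presence, ]
  expect_gt(mean(d$abundance - d$true_density), 0)
})

test_that("default truth is calibrated to the observed marina abundance anchor", {
  # mean occupied-marina abundance, averaged over 10 replicate surveys,
  # should sit within 3 MC standard errors of the 10.4 ind/m2 anchor
  # (replicate sd ~2.3 from the calibration simulation)
  means <- vapply(1:10, function(s) {
    sv <- generate_survey(generator_config(seed = s))
    ab <- site_abundance_table(sv$quadrats, sv$sites, 0.25)
    occ <- ab[ab$abundance > 0 & ab$habitat_type == "marina", ]
    mean(occ$abundance)
  }, numeric(1))
  expect_lt(abs(mean(means) - 10.4), 3 * 2.4 / sqrt(10))
})

test_that("projection set carries the assumed marina substrate and rocky prevalence", {
  cfg <- generator_config(seed = 2)
  proj <- generate_projection_set(cfg, n_marinas = 54, n_natural = 108)
  expect_true(all(proj$substrate_cover[proj$habitat_type == "marina"] == 100))
  expect_true(all(proj$area > 0))

  nat <- proj[proj$habitat_type == "natural", ]
  rocky_prevalence <- mean(nat$substrate_cover > 0)
  expect_gt(rocky_prevalence, 0); expect_lt(rocky_prevalence, 1)
  # reproducible truth, recomputable by filtering the emitted table
  proj2 <- generate_projection_set(cfg, n_marinas = 54, n_natural = 108)
  expect_identical(mean(proj2$substrate_cover[proj2$habitat_type == "natural"] > 0),
                   rocky_prevalence)
  # substrate collapses in the south: rare above 10% beyond the midpoint
  south <- nat[nat$latitude_proxy > 0.6, ]
  expect_lt(mean(south$substrate_cover > 10), 0.2)

  nat_only <- generate_projection_set(cfg, n_marinas = 0, n_natural = 20)
  expect_true(all(nat_only$habitat_type == "natural"))
})

test_that("length-class frequencies are normalized with habitat-specific modes", {
  cfg <- generator_config()
  for (h in c("marina", "pier", "natural_rocky")) {
    f <- length_class_freqs(cfg, h)
    expect_equal(sum(f$freq), 1, tolerance = 1e-12)
    expect_true(all(diff(f$midpoint) > 0))
  }
  mode_marina <- with(length_class_freqs(cfg, "marina"), midpoint[which.max(freq)])
  mode_natural <- with(length_class_freqs(cfg, "natural_rocky"),
                       midpoint[which.max(freq)])
  expect_true(mode_marina >= 100 && mode_marina <= 115)
  expect_true(mode_natural >= 55 && mode_natural <= 70)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(generator_config(salinity_endpoints = c(25, 45)), "psu")
  expect_error(generator_config(occ_coefs = c(intercept = Inf, substrate = 0,
                                              salinity = 0, exposure = 0)),
               "intercept")
  expect_error(generator_config(abn_coefs = c(intercept = 1, exposure = NA,
                                              substrate = 0)),
               "exposure")
  expect_error(generator_config(n_quadrats = 0))
})
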