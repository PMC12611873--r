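#' Project occurrence and possible abundance onto new sites
#'
#' Applies the hurdle: the ensemble predicts occurrence probability and the
#' binary presence call at its cutoff, and the abundance model predicts
#' possible abundance (ind per m2) only where presence is predicted.
#' Marina exposures are expected to be pre-processed with
#' [substitute_marina_exposure()] and [attenuate_exposure()], exactly as
#' for the training data.
#'
#' @param ensemble a fitted `occ_ensemble`.
#' @param abundance_model a fitted `abundance_model`.
#' @param sites projection-site table with `habitat_type`
#'   ("marina"/"natural") and the predictor columns.
#' @return `sites` with `probability`, `presence` and `possible_abundance`
#'   (NA at predicted-absent sites) appended.
#' @export
project_sites <- function(ensemble, abundance_model, sites) {
  stopifnot(inherits(ensemble, "occ_ensemble"),
            inherits(abundance_model, "abundance_model"),
            is.data.frame(sites), "habitat_type" %in% names(sites))
  bad <- setdiff(unique(sites$habitat_type), c("marina", "natural"))
  if (length(bad))
    stop("unknown habitat type(s) in projection table: ",
         paste(bad, collapse = ", "))
  occ <- suppressWarnings(predict(ensemble, sites))
  out <- sites
  out$probability <- occ$probability
  out$presence <- occ$presence
  out$possible_abundance <- NA_real_
  if (any(out$presence))
    out$possible_abundance[out$presence] <- suppressWarnings(
      predict(abundance_model, sites[out$presence, , drop = FALSE]))
  out
}

#' Possible population size
#'
#' `N_h = xbar_h * P_h * A_h`: mean predicted abundance over
#' predicted-present sites times predicted prevalence times areal extent.
#' Supply either the product `P_h * A_h` directly as `invaded_area` or the
#' two factors separately.
#'
#' @param mean_abundance `xbar_h`, ind per m2 (>= 0).
#' @param invaded_area `P_h * A_h` in m2 (>= 0); alternatively pass `Ah`
#'   and `Ph` and leave this NULL.
#' @param Ah,Ph areal extent (m2) and prevalence, used when `invaded_area`
#'   is NULL.
#' @return Possible population size in individuals (linear in each factor).
#' @export
population_size <- function(mean_abundance, invaded_area = NULL,
                            Ah = NULL, Ph = NULL) {
  if (is.null(invaded_area)) {
    stopifnot(!is.null(Ah), !is.null(Ph))
    invaded_area <- Ah * Ph
  }
  stopifnot(mean_abundance >= 0, invaded_area >= 0)
  mean_abundance * invaded_area
}

#' Calibrate an allometric length-weight model
#'
#' `W(L) = a * L^b` with weight in grams and shell length in mm. Two
#' anchors give the exact solution `b = log(W2/W1) / log(L2/L1)`; more
#' anchors are fitted by least squares on the log-log scale. The package
#' default ([default_length_weight()]) is calibrated from two size-class
#' anchors (62.5 mm ~ 40 g, 107.5 mm ~ 140 g) as a documented
#' approximation to an unpublished Swedish west-coast regression.
#'
#' @param lengths shell lengths, mm (distinct, positive).
#' @param weights live wet weights, g (positive).
#' @return Object of class `lw_model` with `a` (g mm^-b) and `b`.
#' @export
lw_calibrate <- function(lengths, weights) {
  stopifnot(length(lengths) == length(weights), length(lengths) >= 2,
            all(weights > 0), all(lengths > 0))
  if (anyDuplicated(lengths)) stop("anchor lengths must be distinct")
  if (length(lengths) == 2) {
    b <- log(weights[2] / weights[1]) / log(lengths[2] / lengths[1])
    a <- weights[1] / lengths[1]^b
  } else {
    fit <- stats::lm(log(weights) ~ log(lengths))
    b <- unname(stats::coef(fit)[2])
    a <- exp(unname(stats::coef(fit)[1]))
  }
  structure(list(a = a, b = b,
                 anchors = data.frame(length = lengths, weight = weights)),
            class = "lw_model")
}

#' @rdname lw_calibrate
#' @export
default_length_weight <- function() lw_calibrate(c(62.5, 107.5), c(40, 140))

#' Predicted weight at length
#'
#' @param object an `lw_model`.
#' @param newdata shell lengths in mm (vector, or data frame with a
#'   `length` column).
#' @param ... unused.
#' @return Weights in g.
#' @export
predict.lw_model <- function(object, newdata, ...) {
  L <- if (is.data.frame(newdata)) newdata$length else newdata
  object$a * L^object$b
}

#' Possible biomass from population size and length structure
#'
#' `B_h = N_h * sum(f_c * W(midpoint_c))`, converted g to tonnes live wet
#' weight, with the per-class contributions returned alongside.
#'
#' @param N possible population size, individuals.
#' @param length_freqs data frame with size-class `midpoint` (mm) and
#'   `freq` (must sum to 1 within 1e-6).
#' @param lw an `lw_model` (default [default_length_weight()]).
#' @return List with `total_t` (tonnes) and `per_class` (data frame with
#'   midpoint, freq, mean weight g, contribution in tonnes; contributions
#'   sum to `total_t`).
#' @export
biomass_estimate <- function(N, length_freqs, lw = default_length_weight()) {
  stopifnot(N >= 0, is.data.frame(length_freqs),
            all(c("midpoint", "freq") %in% names(length_freqs)))
  if (abs(sum(length_freqs$freq) - 1) > 1e-6)
    stop("length-class frequencies must sum to 1 (got ",
         signif(sum(length_freqs$freq), 8), ")")
  w <- predict(lw, length_freqs$midpoint)
  contrib_t <- N * length_freqs$freq * w / 1e6
  list(total_t = sum(contrib_t),
       per_class = data.frame(midpoint = length_freqs$midpoint,
                              freq = length_freqs$freq,
                              weight_g = w, contribution_t = contrib_t))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the rows (or elements) of `data` with replacement `n_boot`
#' times, recomputes `statistic`, and returns the percentile interval. The
#' point estimate is the plug-in statistic on the original sample.
#'
#' @param data numeric vector or data frame of resampling units (sites).
#' @param statistic function of `data` returning a single number.
#' @param n_boot bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return Named vector `c(lower, point, upper)`. With a single resampling
#'   unit the interval is degenerate (zero width, with a warning).
#' @export
bootstrap_ci <- function(data, statistic = mean, n_boot = 1000,
                         level = 0.95, seed = 1) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  stopifnot(n >= 1, n_boot >= 1, level > 0, level < 1)
  take <- if (is.data.frame(data)) function(i) data[i, , drop = FALSE]
          else function(i) data[i]
  point <- statistic(data)
  if (n == 1) {
    warning("single resampling unit: degenerate confidence interval")
    return(c(lower = point, point = point, upper = point))
  }
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b)
    statistic(take(sample.int(n, n, replace = TRUE))), numeric(1))
  q <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                       na.rm = TRUE, names = FALSE)
  c(lower = q[1], point = point, upper = q[2])
}

#' Habitat-stratified possible population size and biomass
#'
#' Summarises a projected site table into per-habitat estimates in the
#' style of an invasion-risk table: predicted prevalence `P_h`, areal
#' extent `A_h`, invaded area `P_h * A_h`, mean possible abundance
#' `xbar_h` over predicted-present sites, possible population size
#' `N_h = xbar_h * P_h * A_h`, and possible biomass from the habitat's
#' length structure. Three strata are reported: marinas, natural rocky
#' (natural sites with hard substrate, with rocky area = total natural
#' area x the fraction of natural sites with substrate cover > 0), and
#' natural overall (prevalence over all natural sites; its invaded area
#' coincides with the rocky one because predicted presence requires
#' substrate, so N and biomass are reported on the rocky row only).
#'
#' Uncertainty: percentile bootstrap over projection sites, resampled with
#' replacement within habitat (marinas; natural sites), recomputing all
#' statistics per replicate.
#'
#' @param projected output of [project_sites()] (must carry `area`).
#' @param length_freqs named list of length-class frequency tables (see
#'   [biomass_estimate()]) for `marina` and `natural_rocky`.
#' @param lw an `lw_model`.
#' @param n_boot,level,seed bootstrap settings.
#' @return Data frame of class `habitat_estimates`, one row per stratum,
#'   with point estimates and `*_lo` / `*_hi` percentile bounds.
#' @export
habitat_estimates <- function(projected, length_freqs, lw = default_length_weight(),
                              n_boot = 1000, level = 0.95, seed = 1) {
  stopifnot(is.data.frame(projected),
            all(c("habitat_type", "substrate_cover", "area",
                  "presence", "possible_abundance") %in% names(projected)),
            all(projected$area > 0))

  marina <- projected[projected$habitat_type == "marina", , drop = FALSE]
  natural <- projected[projected$habitat_type == "natural", , drop = FALSE]

  marina_stats <- function(d) {
    Ph <- mean(d$presence); Ah <- sum(d$area)
    xbar <- if (any(d$presence)) mean(d$possible_abundance[d$presence]) else NA_real_
    N <- if (is.na(xbar)) 0 else population_size(xbar, Ah = Ah, Ph = Ph)
    B <- biomass_estimate(N, length_freqs$marina, lw)$total_t
    c(xbar = xbar, prevalence = Ph, area = Ah, invaded = Ph * Ah, N = N, B = B)
  }
  rocky_stats <- function(d) {
    rocky <- d$substrate_cover > 0
    Ah_total <- sum(d$area)
    Ah_rocky <- Ah_total * mean(rocky)
    Ph <- if (any(rocky)) mean(d$presence[rocky]) else 0
    xbar <- if (any(d$presence)) mean(d$possible_abundance[d$presence]) else NA_real_
    N <- if (is.na(xbar)) 0 else population_size(xbar, Ah = Ah_rocky, Ph = Ph)
    B <- biomass_estimate(N, length_freqs$natural_rocky, lw)$total_t
    c(xbar = xbar, prevalence = Ph, area = Ah_rocky, invaded = Ph * Ah_rocky,
      N = N, B = B)
  }
  overall_stats <- function(d) {
    Ph <- mean(d$presence); Ah <- sum(d$area)
    xbar <- if (any(d$presence)) mean(d$possible_abundance[d$presence]) else NA_real_
    c(xbar = xbar, prevalence = Ph, area = Ah, invaded = Ph * Ah,
      N = NA_real_, B = NA_real_)
  }

  strata <- list(
    marina = list(data = marina, fn = marina_stats),
    natural_rocky = list(data = natural, fn = rocky_stats),
    natural_overall = list(data = natural, fn = overall_stats))

  rows <- lapply(names(strata), function(nm) {
    st <- strata[[nm]]
    d <- st$data
    if (nrow(d) == 0) return(NULL)
    pt <- st$fn(d)
    if (nrow(d) >= 2) {
      set.seed(seed)
      reps <- t(vapply(seq_len(n_boot), function(b)
        st$fn(d[sample.int(nrow(d), nrow(d), replace = TRUE), , drop = FALSE]),
        numeric(6)))
      lo <- apply(reps, 2, stats::quantile, probs = (1 - level) / 2, na.rm = TRUE)
      hi <- apply(reps, 2, stats::quantile, probs = 1 - (1 - level) / 2, na.rm = TRUE)
    } else {
      warning("stratum '", nm, "' has a single site: degenerate intervals")
      lo <- hi <- pt
    }
    data.frame(habitat = nm, n_sites = nrow(d),
               xbar = pt[["xbar"]], xbar_lo = lo[["xbar"]], xbar_hi = hi[["xbar"]],
               prevalence = pt[["prevalence"]],
               prevalence_lo = lo[["prevalence"]], prevalence_hi = hi[["prevalence"]],
               area_m2 = pt[["area"]], invaded_area_m2 = pt[["invaded"]],
               N = pt[["N"]], N_lo = lo[["N"]], N_hi = hi[["N"]],
               biomass_t = pt[["B"]], biomass_lo = lo[["B"]], biomass_hi = hi[["B"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("habitat_estimates", "data.frame"),
            n_boot = n_boot, level = level, seed = seed)
}

#' Per-unit-area standardization of two habitat estimates
#'
#' Abundance per square metre of total habitat (`xbar_h * P_h`) and biomass
#' per square metre (`B_h / A_h`), with their ratios between two strata.
#' Standardizing by total rather than invaded area is what makes small,
#' dense habitats (marinas) comparable to extensive sparse ones.
#'
#' @param estimates a [habitat_estimates()] table.
#' @param a,b stratum names to compare (ratio a:b).
#' @return List with per-stratum `abundance_per_m2`, `biomass_g_per_m2`,
#'   and `abundance_ratio`, `biomass_ratio` (a over b).
#' @export
per_unit_area <- function(estimates, a = "marina", b = "natural_rocky") {
  stopifnot(inherits(estimates, "habitat_estimates") || is.data.frame(estimates))
  pick <- function(nm) {
    row <- estimates[estimates$habitat == nm, , drop = FALSE]
    if (nrow(row) != 1) stop("stratum not found: ", nm)
    row
  }
  ra <- pick(a); rb <- pick(b)
  abn <- c(ra$xbar * ra$prevalence, rb$xbar * rb$prevalence)
  bio <- c(ra$biomass_t * 1e6 / ra$area_m2, rb$biomass_t * 1e6 / rb$area_m2)
  names(abn) <- names(bio) <- c(a, b)
  list(abundance_per_m2 = abn, biomass_g_per_m2 = bio,
       abundance_ratio = unname(abn[1] / abn[2]),
       biomass_ratio = unname(bio[1] / bio[2]))
}

#' @export
print.habitat_estimates <- function(x, ...) {
  cat("Habitat-stratified possible population estimates (",
      100 * attr(x, "level"), "% percentile bootstrap, ",
      attr(x, "n_boot"), " resamples)\n", sep = "")
  disp <- data.frame(
    habitat = x$habitat,
    `prevalence %` = round(100 * x$prevalence, 1),
    `invaded km2` = signif(x$invaded_area_m2 / 1e6, 3),
    `xbar ind/m2` = round(x$xbar, 1),
    `N x1e6` = signif(x$N / 1e6, 3),
    `N CI` = sprintf("(%s, %s)", signif(x$N_lo / 1e6, 3), signif(x$N_hi / 1e6, 3)),
    `biomass t` = signif(x$biomass_t, 3),
    check.names = FALSE)
  print(disp, row.names = FALSE)
  invisible(x)
}
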