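test_that("delta notation and TDF correction follow their definitions", {
  expect_equal(delta_from_ratio(0.011, 0.011), 0)
  expect_equal(delta_from_ratio(1.01 * 0.011, 0.011), 10)
  expect_equal(delta_from_ratio(0.98 * 0.011, 0.011), -20)
  expect_error(delta_from_ratio(1, 0), "positive")

  src <- data.frame(source = "c3_fruits", mean_d13c = -28, sd_d13c = 0.3,
                    mean_d15n = 3, sd_d15n = 0.3)
  cor <- correct_sources(src, c(d13c = 2.2, d15n = 2.6),
                         c(d13c = 0.4, d15n = 0.4))
  expect_equal(cor$mean_d15n, 5.6)
  expect_equal(cor$mean_d13c, -25.8)
  expect_equal(cor$sd_d13c, 0.5)  # sqrt(0.3^2 + 0.4^2)

  # zero TDF leaves sources untouched
  same <- correct_sources(src, c(d13c = 0, d15n = 0), c(d13c = 0, d15n = 0))
  expect_equal(same, src)
})

test_that("raw source specimens pool to group means and SDs", {
  rec <- data.frame(individual_id = paste0("i", 1:6),
                    group = rep(c("g1", "g2"), each = 3),
                    d13c = c(-20, -21, -22, -27, -28, -29),
                    d15n = c(5, 6, 7, 2, 3, 4))
  pooled <- pool_sources(rec)
  expect_equal(pooled$mean_d13c, c(-21, -28))
  expect_equal(pooled$sd_d15n, c(1, 1))
  expect_equal(pooled$n_specimens, c(3L, 3L))
})

two_source_table <- function(sep = 10, sd = 0.1) {
  data.frame(source = c("A", "B"),
             mean_d13c = c(-sep / 2, sep / 2), sd_d13c = sd,
             mean_d15n = c(-sep / 2, sep / 2), sd_d15n = sd,
             stringsAsFactors = FALSE)
}

test_that("consumers sitting on one source pin the posterior to it", {
  src <- two_source_table()
  cfg <- analysis_config(tdf_mean = c(d13c = 0, d15n = 0),
                         tdf_sd = c(d13c = 0, d15n = 0),
                         mcmc = fast_mcmc(), rng_seed = 21)
  cons <- withr::with_seed(1, data.frame(
    d13c = rep(-5, 10) + rnorm(10, 0, 1e-3),
    d15n = rep(-5, 10) + rnorm(10, 0, 1e-3)))
  fit <- fit_mixing_model(cons, src, cfg, species = "test")
  ci <- credible_intervals(fit)
  expect_gt(ci$lower[ci$source == "A"], 0.9)
})

test_that("consumers at the midpoint of symmetric sources split evenly", {
  src <- two_source_table(sep = 4, sd = 0.5)
  cfg <- analysis_config(tdf_mean = c(d13c = 0, d15n = 0),
                         tdf_sd = c(d13c = 0, d15n = 0),
                         mcmc = fast_mcmc(), rng_seed = 8)
  cons <- data.frame(d13c = c(-0.2, 0.2, -0.1, 0.1, 0, 0),
                     d15n = c(0.1, -0.1, 0.2, -0.2, 0, 0))
  fit <- fit_mixing_model(cons, src, cfg, species = "mid")
  expect_equal(unname(colMeans(fit$p)), c(0.5, 0.5), tolerance = 0.05)
})

test_that("the posterior recovers known proportions in three-source data", {
  src <- data.frame(source = c("A", "B", "C"),
                    mean_d13c = c(-28, -20, -12), sd_d13c = 0.4,
                    mean_d15n = c(2, 10, 4), sd_d15n = 0.4,
                    stringsAsFactors = FALSE)
  p_true <- c(0.6, 0.3, 0.1)
  cfg <- analysis_config(tdf_mean = c(d13c = 0, d15n = 0),
                         tdf_sd = c(d13c = 0, d15n = 0),
                         mcmc = fast_mcmc(), rng_seed = 31)
  mu <- as.matrix(src[c("mean_d13c", "mean_d15n")])
  v <- as.matrix(src[c("sd_d13c", "sd_d15n")])^2
  cons <- withr::with_seed(100, data.frame(
    d13c = rnorm(40, sum(p_true * mu[, 1]),
                 sqrt(sum(p_true^2 * v[, 1]) + 0.25)),
    d15n = rnorm(40, sum(p_true * mu[, 2]),
                 sqrt(sum(p_true^2 * v[, 2]) + 0.25))))
  fit <- fit_mixing_model(cons, src, cfg, species = "rec")
  ci <- credible_intervals(fit)
  expect_true(all(ci$lower <= p_true & p_true <= ci$upper))
  expect_true(all(fit$diagnostics$rhat < 1.1, na.rm = TRUE))
})

test_that("every retained draw lies on the simplex", {
  study <- simulate_study(scenario_config(rng_seed = 4))
  cfg <- analysis_config(mcmc = fast_mcmc(iter = 3000L, burnin = 1000L,
                                          thin = 2L), rng_seed = 4)
  iso <- study$isotopes[study$isotopes$group == "thrush_A", ]
  # a deliberately short run: the simplex property holds draw by draw
  # whether or not the chains have mixed
  fit <- suppressWarnings(suppressMessages(
    fit_mixing_model(iso, study$sources, cfg, species = "thrush_A")))
  expect_true(all(fit$p >= 0))
  expect_equal(unname(rowSums(fit$p)), rep(1, nrow(fit$p)))
  expect_true(all(fit$sigma > 0))
})

test_that("identical configuration and data give identical posteriors", {
  src <- two_source_table(sep = 6, sd = 0.5)
  cfg <- analysis_config(tdf_mean = c(d13c = 0, d15n = 0),
                         tdf_sd = c(d13c = 0, d15n = 0),
                         mcmc = fast_mcmc(iter = 2000L, burnin = 500L,
                                          thin = 1L), rng_seed = 13)
  cons <- data.frame(d13c = c(-1, 0, 1, 0.5), d15n = c(-1, 1, 0, 0.5))
  f1 <- fit_mixing_model(cons, src, cfg, species = "s")
  f2 <- fit_mixing_model(cons, src, cfg, species = "s")
  expect_identical(f1$p, f2$p)
})

test_that("credible intervals summarize draws correctly", {
  # degenerate posterior: every draw identical
  draws <- cbind(a = rep(0.3, 1500), b = rep(0.7, 1500))
  ci <- credible_intervals(stub_posterior(draws))
  expect_equal(ci$lower, ci$upper)
  expect_equal(ci$midpoint, c(0.3, 0.7))

  # uniform draws: equal-tailed percentile bounds
  draws <- withr::with_seed(5, cbind(u = runif(20000)))
  ci <- credible_intervals(stub_posterior(draws), level = 0.95)
  expect_equal(ci$lower, 0.025, tolerance = 0.01)
  expect_equal(ci$upper, 0.975, tolerance = 0.01)

  # too few draws is an explicit error
  expect_error(credible_intervals(stub_posterior(cbind(a = rep(0.5, 10)))),
               "1000")
})

test_that("a full species-by-source CI table has ordered bounds", {
  study <- simulate_study(scenario_config(rng_seed = 17))
  cfg <- analysis_config(mcmc = fast_mcmc(iter = 3000L, burnin = 1000L,
                                          thin = 2L), rng_seed = 17)
  fits <- lapply(unique(study$isotopes$group), function(sp) {
    suppressWarnings(suppressMessages(fit_mixing_model(
      study$isotopes[study$isotopes$group == sp, ],
      study$sources, cfg, species = sp)))
  })
  tab <- credible_intervals(fits)
  expect_equal(nrow(tab), 3L * 7L)
  expect_true(all(tab$lower <= tab$upper))
  expect_true(all(tab$lower >= 0 & tab$upper <= 1))
  # interval midpoints need not sum to 1, but stay in a sane band
  sums <- tapply(tab$midpoint, tab$species, sum)
  expect_true(all(sums > 0.5 & sums < 1.5))
})

test_that("the TDF-uncertainty sensitivity run leaves conclusions stable", {
  # The mixture variance weights source/TDF spread by p^2, so inflating
  # the TDF SD penalizes concentrated diets and pulls the posterior
  # toward even mixtures rather than uniformly widening every marginal
  # interval.  What the sensitivity variant must show is stability of the
  # estimated contributions: every wide-TDF posterior mean falls inside
  # the narrow-TDF credible interval, and the diet-concentration
  # statistic sum(p^2) does not increase.
  study <- simulate_study(scenario_config(rng_seed = 23))
  iso <- study$isotopes[study$isotopes$group == "thrush_B", ]
  mk_cfg <- function(tdf_sd) {
    analysis_config(tdf_sd = tdf_sd,
                    mcmc = fast_mcmc(iter = 12000L, burnin = 4000L,
                                     thin = 4L), rng_seed = 23)
  }
  fit_narrow <- suppressMessages(fit_mixing_model(
    iso, study$sources, mk_cfg(c(d13c = 0.1, d15n = 0.2)), species = "b"))
  fit_wide <- suppressMessages(fit_mixing_model(
    iso, study$sources, mk_cfg(c(d13c = 0.9, d15n = 1.0)), species = "b"))
  ci_narrow <- credible_intervals(fit_narrow)
  mean_wide <- colMeans(fit_wide$p)
  expect_true(all(mean_wide >= ci_narrow$lower &
                    mean_wide <= ci_narrow$upper))
  expect_lte(mean(rowSums(fit_wide$p^2)),
             mean(rowSums(fit_narrow$p^2)) + 0.01)
})
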