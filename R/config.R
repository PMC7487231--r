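#' Resource categories used in the consumer--resource networks
#'
#' The seven default resource groups: five arthropod guilds plus fruits
#' split by photosynthetic pathway (C3 vs C4/CAM), which separate cleanly
#' in \eqn{\delta^{13}}C.
#'
#' @return Character vector of length 7.
#' @export
default_categories <- function() {
  c("omnivorous", "predators", "herbivorous",
    "surface_detritivorous", "terrestrial_detritivorous",
    "c4cam_fruits", "c3_fruits")
}

#' Analysis configuration
#'
#' Bundles every tunable of the pipeline in one validated object: trophic
#' discrimination factors (TDFs), credible-interval level, bootstrap target
#' size, null-model randomizations, MCMC settings, proportion basis for the
#' diet-based niche indices, and the run seed from which all stage-level
#' random streams are derived (see [child_seed()]).
#'
#' @param tdf_mean Named numeric, per-element TDF mean in permil; defaults
#'   to the blood TDFs of an omnivorous passerine:
#'   2.2 for `d13c` and 2.6 for `d15n`.
#' @param tdf_sd Named numeric, per-element TDF standard deviation in
#'   permil (defaults 0.1 for `d13c`, 0.2 for `d15n`).
#' @param ci_level Credible/confidence level, a fraction in (0, 1).
#' @param bootstrap_n Target sample size when bootstrap-standardizing
#'   isotope samples across species (default 50).
#' @param n_null Number of null-model randomizations (default 1000).
#' @param mcmc List with elements `chains`, `iter` (iterations per chain),
#'   `burnin` (discarded iterations per chain) and `thin`.
#' @param proportion_basis Which diet index feeds the proportion vectors
#'   used by Levins' breadth and Pianka's overlap: `"psiri"` (default),
#'   `"n"` (numeric %) or `"v"` (volumetric %).
#' @param overlap_denominator Denominator of the ellipse-overlap
#'   percentage: `"union"` (Jaccard-style, default) or `"smaller"`
#'   (fraction of the smaller ellipse).
#' @param guild_threshold Volume % above which a guild is the predominant
#'   diet type (default 35).
#' @param guild_secondary Volume % range defining a secondary diet type
#'   (default `c(10, 35)`).
#' @param vaznull_scale Continuous interaction weights are quantized to
#'   `round(weight * vaznull_scale)` discrete interaction events before
#'   null-model randomization (default 100).
#' @param categories Resource-category vocabulary (default
#'   [default_categories()]); user-extensible.
#' @param rng_seed Integer run seed.
#' @return A list of class `"analysis_config"`.
#' @examples
#' cfg <- analysis_config(rng_seed = 7)
#' cfg$tdf_mean
#' @export
analysis_config <- function(tdf_mean = c(d13c = 2.2, d15n = 2.6),
                            tdf_sd = c(d13c = 0.1, d15n = 0.2),
                            ci_level = 0.95,
                            bootstrap_n = 50L,
                            n_null = 1000L,
                            mcmc = list(chains = 4L, iter = 20000L,
                                        burnin = 10000L, thin = 10L),
                            proportion_basis = c("psiri", "n", "v"),
                            overlap_denominator = c("union", "smaller"),
                            guild_threshold = 35,
                            guild_secondary = c(10, 35),
                            vaznull_scale = 100,
                            categories = default_categories(),
                            rng_seed = 1L) {
  assert_number(ci_level, "ci_level")
  if (ci_level <= 0 || ci_level >= 1) {
    stop("`ci_level` must lie strictly between 0 and 1", call. = FALSE)
  }
  assert_number(bootstrap_n, "bootstrap_n", lower = 1)
  assert_number(n_null, "n_null", lower = 1)
  for (nm in c("chains", "iter", "burnin", "thin")) {
    if (is.null(mcmc[[nm]])) {
      stop(sprintf("`mcmc` must contain `%s`", nm), call. = FALSE)
    }
    assert_number(mcmc[[nm]], paste0("mcmc$", nm),
                  lower = if (nm == "burnin") 0 else 1)
  }
  if (mcmc$burnin >= mcmc$iter) {
    stop("`mcmc$burnin` must be smaller than `mcmc$iter`", call. = FALSE)
  }
  stopifnot(length(tdf_mean) == 2L, length(tdf_sd) == 2L,
            all(c("d13c", "d15n") %in% names(tdf_mean)),
            all(c("d13c", "d15n") %in% names(tdf_sd)),
            all(tdf_sd >= 0))
  assert_number(rng_seed, "rng_seed")
  structure(list(
    tdf_mean = tdf_mean[c("d13c", "d15n")],
    tdf_sd = tdf_sd[c("d13c", "d15n")],
    ci_level = ci_level,
    bootstrap_n = as.integer(bootstrap_n),
    n_null = as.integer(n_null),
    mcmc = lapply(mcmc, as.integer),
    proportion_basis = match.arg(proportion_basis),
    overlap_denominator = match.arg(overlap_denominator),
    guild_threshold = guild_threshold,
    guild_secondary = guild_secondary,
    vaznull_scale = vaznull_scale,
    categories = categories,
    rng_seed = as.integer(rng_seed)
  ), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Trophic-niche analysis configuration\n")
  cat(sprintf("  TDF: d13c %.2f +/- %.2f, d15n %.2f +/- %.2f (permil)\n",
              x$tdf_mean["d13c"], x$tdf_sd["d13c"],
              x$tdf_mean["d15n"], x$tdf_sd["d15n"]))
  cat(sprintf("  CI level %.2f | bootstrap n %d | null randomizations %d\n",
              x$ci_level, x$bootstrap_n, x$n_null))
  cat(sprintf("  MCMC: %d chains x %d iter (burn-in %d, thin %d)\n",
              x$mcmc$chains, x$mcmc$iter, x$mcmc$burnin, x$mcmc$thin))
  cat(sprintf("  proportion basis: %s | seed %d\n",
              x$proportion_basis, x$rng_seed))
  invisible(x)
}
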