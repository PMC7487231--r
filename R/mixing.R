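# Bayesian stable-isotope mixing model (SIAR model class):
#   x_ij ~ Normal( sum_k p_k (mu_jk + lambda_jk),
#                  sum_k p_k^2 (omega_jk^2 + tau_jk^2) + sigma_j^2 )
# with p ~ Dirichlet(1, ..., 1) and sigma_j half-Normal(0, 5 permil),
# sampled by random-walk Metropolis on additive-log-ratio coordinates.

elements <- c("d13c", "d15n")

source_columns <- c("source", "mean_d13c", "sd_d13c", "mean_d15n", "sd_d15n")

check_sources <- function(sources) {
  stopifnot(is.data.frame(sources))
  missing <- setdiff(source_columns, names(sources))
  if (length(missing)) stop_bad_column(missing, "source table")
  if (any(sources$sd_d13c < 0) || any(sources$sd_d15n < 0)) {
    stop("source standard deviations must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(sources$source)) {
    stop("duplicated source names", call. = FALSE)
  }
  invisible(sources)
}

#' Delta notation for an isotope ratio
#'
#' Expresses an isotope ratio relative to an international standard
#' (VPDB for carbon, atmospheric air for nitrogen) in parts per thousand:
#' \deqn{\delta = (R_{sample}/R_{standard} - 1) \times 1000.}
#'
#' @param r_sample Isotope ratio of the sample (e.g. 13C/12C).
#' @param r_standard Isotope ratio of the standard; must be positive.
#' @return Delta value in permil.
#' @examples
#' delta_from_ratio(1.01, 1)  # 10 permil
#' @export
delta_from_ratio <- function(r_sample, r_standard) {
  if (any(r_standard <= 0)) {
    stop("`r_standard` must be positive", call. = FALSE)
  }
  (r_sample / r_standard - 1) * 1000
}

#' Apply trophic discrimination factors to source distributions
#'
#' Shifts each source's per-element mean by the TDF mean and combines the
#' TDF uncertainty with the source spread:
#' corrected mean \eqn{= \mu_{jk} + \lambda_{jk}}, corrected variance
#' \eqn{= \omega_{jk}^2 + \tau_{jk}^2}.
#'
#' @param sources Source table: data frame with columns `source`,
#'   `mean_d13c`, `sd_d13c`, `mean_d15n`, `sd_d15n` (permil), optionally
#'   `guild` and `n_specimens`.
#' @param tdf_mean,tdf_sd Named numeric (`d13c`, `d15n`) TDF mean and SD
#'   in permil.
#' @return The source table with corrected means and SDs.
#' @examples
#' src <- data.frame(source = "c3_fruits", mean_d13c = -28, sd_d13c = 1,
#'                   mean_d15n = 3, sd_d15n = 1)
#' correct_sources(src, c(d13c = 2.2, d15n = 2.6), c(d13c = 0.1, d15n = 0.2))
#' @export
correct_sources <- function(sources, tdf_mean, tdf_sd) {
  check_sources(sources)
  stopifnot(all(elements %in% names(tdf_mean)),
            all(elements %in% names(tdf_sd)), all(tdf_sd >= 0))
  for (el in elements) {
    sources[[paste0("mean_", el)]] <-
      sources[[paste0("mean_", el)]] + tdf_mean[[el]]
    sources[[paste0("sd_", el)]] <-
      sqrt(sources[[paste0("sd_", el)]]^2 + tdf_sd[[el]]^2)
  }
  sources
}

#' Pool raw source specimens into per-group mean and SD
#'
#' Source grouping (e.g. pooling arthropod taxa into feeding guilds) is an
#' ecological decision taken upstream; this helper only aggregates the
#' isotope values of specimens already labelled with their group.
#'
#' @param records Isotope table as returned by [read_isotope_table()],
#'   with `group` holding the source-group label.
#' @return A source table (see [correct_sources()]) with `n_specimens`.
#' @export
pool_sources <- function(records) {
  stopifnot(is.data.frame(records),
            all(isotope_columns %in% names(records)))
  out <- do.call(rbind, lapply(split(records, records$group), function(g) {
    data.frame(source = g$group[1L],
               mean_d13c = mean(g$d13c), sd_d13c = stats::sd(g$d13c),
               mean_d15n = mean(g$d15n), sd_d15n = stats::sd(g$d15n),
               n_specimens = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# additive-log-ratio back-transform: z in R^(K-1) -> p on the simplex
alr_inv <- function(z) {
  e <- exp(c(z, 0) - max(c(z, 0)))
  e / sum(e)
}

# log posterior given per-element sufficient statistics
# stats: list(n, xbar[j], ss[j]); mu: K x J corrected means; v: K x J vars
log_post <- function(z, u, stats, mu, v, sigma_prior_sd = 5) {
  p <- alr_inv(z)
  if (any(p <= 0)) return(-Inf)
  sigma2 <- exp(2 * u)
  mix_mu <- as.vector(crossprod(p, mu))        # length J
  mix_v <- as.vector(crossprod(p^2, v)) + sigma2
  n <- stats$n
  ll <- sum(-n / 2 * log(2 * pi * mix_v) -
              (stats$ss + n * (stats$xbar - mix_mu)^2) / (2 * mix_v))
  # flat Dirichlet prior on p plus alr Jacobian, half-normal prior on sigma
  # plus log-sigma Jacobian
  ll + sum(log(p)) + sum(-sigma2 / (2 * sigma_prior_sd^2) + u)
}

# Random-walk Metropolis with adaptive proposal: step sizes are tuned
# during burn-in, and from mid-burn-in onward the proportion block uses a
# proposal covariance estimated from the chain's own burn-in history
# (adaptive Metropolis), which follows the curved ridges of
# under-determined mixing posteriors far better than a spherical walk.
# Adaptation stops at the end of burn-in, so the retained chain is a
# valid fixed-kernel Metropolis sample.
run_chain <- function(stats, mu, v, n_iter, burnin, thin, seed) {
  K <- nrow(mu)
  J <- ncol(mu)
  d <- K - 1L
  with_seed(seed, {
    z <- stats::rnorm(d, 0, 0.5)
    u <- log(stats::runif(J, 0.3, 1.5))
    lp <- log_post(z, u, stats, mu, v)
    eps_z <- 0.5
    eps_u <- 0.4
    sc_z <- 1
    L <- NULL                       # chol factor of the adapted covariance
    acc_z <- acc_u <- 0L
    win_z <- win_u <- 0L
    hist_z <- matrix(NA_real_, burnin, d)
    adapt_start <- max(200L, burnin %/% 4L)
    keep <- seq.int(burnin + thin, n_iter, by = thin)
    P <- matrix(NA_real_, length(keep), K)
    S <- matrix(NA_real_, length(keep), J)
    ki <- 1L
    for (it in seq_len(n_iter)) {
      step <- if (is.null(L)) {
        eps_z * stats::rnorm(d)
      } else {
        sc_z * (2.38 / sqrt(d)) * as.vector(L %*% stats::rnorm(d))
      }
      z_new <- z + step
      lp_new <- log_post(z_new, u, stats, mu, v)
      win_z <- win_z + 1L
      if (log(stats::runif(1L)) < lp_new - lp) {
        z <- z_new; lp <- lp_new; acc_z <- acc_z + 1L
      }
      u_new <- u + eps_u * stats::rnorm(J)
      lp_new <- log_post(z, u_new, stats, mu, v)
      win_u <- win_u + 1L
      if (log(stats::runif(1L)) < lp_new - lp) {
        u <- u_new; lp <- lp_new; acc_u <- acc_u + 1L
      }
      if (it <= burnin) {
        hist_z[it, ] <- z
        if (it %% 100L == 0L) {
          if (acc_z / win_z > 0.35) { eps_z <- eps_z * 1.25; sc_z <- sc_z * 1.15 }
          if (acc_z / win_z < 0.15) { eps_z <- eps_z / 1.25; sc_z <- sc_z / 1.15 }
          if (acc_u / win_u > 0.35) eps_u <- eps_u * 1.25
          if (acc_u / win_u < 0.15) eps_u <- eps_u / 1.25
          acc_z <- acc_u <- win_z <- win_u <- 0L
        }
        if (it >= adapt_start && it %% 250L == 0L) {
          cov_z <- stats::cov(hist_z[seq.int(it %/% 2L, it), , drop = FALSE])
          L <- tryCatch(t(chol(cov_z + diag(1e-6, d))),
                        error = function(e) NULL)
        }
      }
      if (ki <= length(keep) && it == keep[ki]) {
        P[ki, ] <- alr_inv(z)
        S[ki, ] <- exp(u)
        ki <- ki + 1L
      }
    }
    list(p = P, sigma = S,
         accept = c(z = acc_z / max(win_z, 1L), u = acc_u / max(win_u, 1L)))
  })
}

# split-free potential scale reduction factor across chains
rhat <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1L]])
  if (m < 2L || n < 2L) return(NA_real_)
  means <- vapply(chains, mean, numeric(1L))
  vars <- vapply(chains, stats::var, numeric(1L))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(200L, n - 1L), plot = FALSE)$acf[-1L]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' Fit a Bayesian stable-isotope mixing model for one species
#'
#' Estimates the posterior of the source-contribution vector \eqn{p} for a
#' consumer species from its blood delta values and a table of source
#' distributions.  The likelihood treats each consumer's per-element value
#' as a draw from a normal mixture mean with mixture-weighted source
#' variance plus a residual scale \eqn{\sigma_j}:
#' \eqn{x_{ij} \sim N(\sum_k p_k \mu^*_{jk},\;
#' \sum_k p_k^2 \omega^{*2}_{jk} + \sigma_j^2)}, where \eqn{\mu^*, \omega^*}
#' are the TDF-corrected source parameters.  The prior on \eqn{p} is flat
#' Dirichlet; \eqn{\sigma_j} has a weakly informative half-normal(0, 5)
#' prior on the permil scale.  The posterior is sampled by random-walk
#' Metropolis on additive-log-ratio coordinates with step sizes adapted
#' during burn-in only.
#'
#' With more sources than isotope elements + 1 the system is
#' under-determined; the Bayesian posterior remains proper but wide, and a
#' note is emitted.  Non-convergence (any split-chain \eqn{\hat{R}} above
#' 1.1) produces a warning and a `converged = FALSE` flag; results are
#' still returned.
#'
#' @param consumers Isotope table for one species (columns `d13c`,
#'   `d15n`); at least 2 rows.
#' @param sources Source table (see [correct_sources()]); at least 2 rows.
#'   Raw (uncorrected) values; the TDF is applied internally.
#' @param config An [analysis_config()]; supplies the TDF, MCMC settings
#'   and run seed.
#' @param species Optional species label stored in the result.
#' @param seed Optional seed overriding the config-derived child seed.
#' @return An object of class `"mixing_posterior"`: a list with `species`,
#'   `sources`, `p` (retained draws x K matrix of proportions), `sigma`
#'   (draws x 2), `diagnostics` (per-source `rhat`, `ess`, acceptance
#'   rates) and `converged`.
#' @seealso [credible_intervals()], [simulate_blood()]
#' @export
fit_mixing_model <- function(consumers, sources,
                             config = analysis_config(),
                             species = NULL, seed = NULL) {
  stopifnot(is.data.frame(consumers), all(elements %in% names(consumers)))
  if (nrow(consumers) < 2L) {
    stop("need at least 2 consumers to fit the mixing model", call. = FALSE)
  }
  check_sources(sources)
  if (nrow(sources) < 2L) {
    stop("need at least 2 sources", call. = FALSE)
  }
  K <- nrow(sources)
  if (K > length(elements) + 1L) {
    message(sprintf(
      "%d sources with %d elements: under-determined system; posterior will be wide",
      K, length(elements)))
  }
  corrected <- correct_sources(sources, config$tdf_mean, config$tdf_sd)
  mu <- as.matrix(corrected[paste0("mean_", elements)])
  v <- as.matrix(corrected[paste0("sd_", elements)])^2
  X <- as.matrix(consumers[elements])
  stats_ <- list(n = nrow(X), xbar = colMeans(X),
                 ss = colSums(sweep(X, 2L, colMeans(X))^2))

  mc <- config$mcmc
  base_seed <- if (is.null(seed)) {
    child_seed(config$rng_seed,
               paste0("mcmc:", if (is.null(species)) "" else species))
  } else {
    seed
  }
  chains <- lapply(seq_len(mc$chains), function(ch) {
    run_chain(stats_, mu, v, mc$iter, mc$burnin, mc$thin,
              seed = child_seed(base_seed, paste0("chain", ch)))
  })
  P <- do.call(rbind, lapply(chains, `[[`, "p"))
  S <- do.call(rbind, lapply(chains, `[[`, "sigma"))
  colnames(P) <- sources$source
  colnames(S) <- elements

  rh <- vapply(seq_len(K), function(k) {
    rhat(lapply(chains, function(ch) ch$p[, k]))
  }, numeric(1L))
  es <- vapply(seq_len(K), function(k) ess(P[, k]), numeric(1L))
  converged <- all(is.na(rh) | rh < 1.1)
  if (!converged) {
    warning(sprintf(
      "possible non-convergence: max Rhat = %.3f for source '%s'",
      max(rh, na.rm = TRUE), sources$source[which.max(rh)]), call. = FALSE)
  }
  structure(list(
    species = species,
    sources = sources$source,
    p = P,
    sigma = S,
    diagnostics = data.frame(
      source = sources$source, rhat = rh, ess = es,
      stringsAsFactors = FALSE),
    accept = rowMeans(vapply(chains, `[[`, numeric(2L), "accept")),
    n_chains = mc$chains,
    converged = converged
  ), class = "mixing_posterior")
}

#' @export
print.mixing_posterior <- function(x, ...) {
  cat(sprintf(
    "Mixing-model posterior%s: %d draws, %d sources, %d chains%s\n",
    if (is.null(x$species)) "" else paste0(" for ", x$species),
    nrow(x$p), length(x$sources), x$n_chains,
    if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(rbind(mean = colMeans(x$p),
                    apply(x$p, 2L, stats::quantile, c(0.025, 0.975))), 3))
  invisible(x)
}

#' @export
summary.mixing_posterior <- function(object, level = 0.95, ...) {
  a <- (1 - level) / 2
  stat <- rbind(
    mean = colMeans(object$p),
    sd = apply(object$p, 2L, stats::sd),
    median = apply(object$p, 2L, stats::median),
    lower = apply(object$p, 2L, stats::quantile, a),
    upper = apply(object$p, 2L, stats::quantile, 1 - a))
  out <- expand.grid(statistic = rownames(stat), source = colnames(stat),
                     stringsAsFactors = FALSE)
  out$species <- if (is.null(object$species)) NA_character_ else object$species
  out$value <- as.vector(stat)
  out[c("species", "source", "statistic", "value")]
}

#' Equal-tailed credible intervals of source contributions
#'
#' Percentile intervals per source from the retained posterior draws, plus
#' the interval midpoint (the statistic used as the isotope-network
#' weight) and the posterior mean.  Midpoints of the per-source intervals
#' need not sum to 1 across sources, even though every posterior draw lies
#' on the simplex: each interval is a marginal summary.
#'
#' @param posterior A `"mixing_posterior"` (see [fit_mixing_model()]) or a
#'   list of them (one per species).
#' @param level Credible level (default 0.95).
#' @return A `data.frame` with columns `species`, `source`, `lower`,
#'   `upper`, `midpoint`, `mean`.
#' @export
credible_intervals <- function(posterior, level = 0.95) {
  if (!inherits(posterior, "mixing_posterior") && is.list(posterior)) {
    out <- do.call(rbind, lapply(posterior, credible_intervals, level))
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(inherits(posterior, "mixing_posterior"))
  assert_number(level, "level")
  if (nrow(posterior$p) < 1000L) {
    stop("fewer than 1000 retained draws; increase iterations or chains",
         call. = FALSE)
  }
  a <- (1 - level) / 2
  lo <- apply(posterior$p, 2L, stats::quantile, a)
  hi <- apply(posterior$p, 2L, stats::quantile, 1 - a)
  data.frame(
    species = if (is.null(posterior$species)) NA_character_
              else posterior$species,
    source = posterior$sources,
    lower = unname(lo), upper = unname(hi),
    midpoint = unname((lo + hi) / 2),
    mean = unname(colMeans(posterior$p)),
    stringsAsFactors = FALSE)
}
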