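# Synthetic study generator: sources, true diet proportions, consumer
# blood values and fecal samples with known ground truth.

default_sources <- function() {
  data.frame(
    source = default_categories(),
    guild = c("arthropod", "arthropod", "arthropod", "arthropod",
              "arthropod", "fruit", "fruit"),
    mean_d13c = c(-23.0, -23.5, -25.5, -20.5, -20.0, -13.0, -28.0),
    sd_d13c = c(0.8, 0.8, 0.8, 0.8, 0.8, 1.0, 1.0),
    mean_d15n = c(6.5, 9.0, 4.5, 5.5, 8.0, 5.0, 3.0),
    sd_d15n = c(0.8, 0.8, 0.8, 0.8, 0.8, 1.0, 1.0),
    stringsAsFactors = FALSE
  )
}

default_true_p <- function() {
  # three consumers over the seven categories: two with similar,
  # fruit-dominated mixed diets and one concentrated on predatory
  # arthropods, mirroring the estimated assimilated diets of the
  # motivating thrush community
  p <- rbind(
    thrush_A = c(0.05, 0.30, 0.07, 0.07, 0.05, 0.02, 0.44),
    thrush_B = c(0.10, 0.20, 0.15, 0.14, 0.10, 0.03, 0.28),
    thrush_C = c(0.02, 0.60, 0.03, 0.03, 0.03, 0.01, 0.28)
  )
  colnames(p) <- default_categories()
  p
}

#' Configuration of a synthetic trophic-niche study
#'
#' Defines a complete simulated study: Gaussian source distributions, true
#' diet-proportion vectors per consumer species, TDFs, residual spread,
#' sample sizes for blood and feces, and the count-to-volume scaling used
#' to turn multinomial item counts into reconstituted volumes.  Defaults
#' mirror the scale of the motivating field study: 3 consumer species, 7
#' resource groups (5 arthropod guilds, C3 fruits, C4/CAM fruits), blood
#' TDFs of 2.2 +/- 0.1 permil (d13C) and 2.6 +/- 0.2 permil (d15N),
#' fecal sample sizes (26, 20, 4) and blood sample sizes (20, 15, 8) to
#' be bootstrap-standardized to 50.
#'
#' @param n_species Number of consumer species.
#' @param species Species labels.
#' @param sources Source table (see [correct_sources()]); defaults to 7
#'   groups with mutually distinguishable means.
#' @param true_p Matrix (species x sources) of true diet proportions; rows
#'   must sum to 1.  `NULL` draws rows from a Dirichlet distribution with
#'   concentration `dirichlet_alpha`.
#' @param dirichlet_alpha Concentration for random true proportions.
#' @param tdf_mean,tdf_sd Trophic discrimination factors (permil).
#' @param sigma Named per-element residual SD of consumer values beyond
#'   the mixture variance (permil).
#' @param n_consumers Integer vector (per species) of blood samples.
#' @param n_fecal Integer vector (per species) of fecal samples.
#' @param items_per_sample Mean extra item count per fecal sample; each
#'   sample holds `1 + Poisson(items_per_sample)` items so no sample is
#'   empty.
#' @param unit_volume Named per-category volume (mm^3) of a single item;
#'   fruits are bulkier than arthropod fragments.
#' @param volume_sdlog Log-normal noise SD on item volumes.
#' @param detectability Named per-category multiplier on fecal detection:
#'   values below 1 down-weight soft, easily digested items in feces
#'   while leaving blood values untouched, reproducing the classic
#'   discordance between excreted and assimilated diets.
#' @param rng_seed Integer run seed.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_species = 3L,
                            species = c("thrush_A", "thrush_B", "thrush_C"),
                            sources = default_sources(),
                            true_p = default_true_p(),
                            dirichlet_alpha = 1,
                            tdf_mean = c(d13c = 2.2, d15n = 2.6),
                            tdf_sd = c(d13c = 0.1, d15n = 0.2),
                            sigma = c(d13c = 0.5, d15n = 0.5),
                            n_consumers = c(20L, 15L, 8L),
                            n_fecal = c(26L, 20L, 4L),
                            items_per_sample = 3.3,
                            unit_volume = c(omnivorous = 1.5,
                                            predators = 2,
                                            herbivorous = 1.5,
                                            surface_detritivorous = 1,
                                            terrestrial_detritivorous = 1.5,
                                            c4cam_fruits = 4,
                                            c3_fruits = 5),
                            volume_sdlog = 0.3,
                            detectability = NULL,
                            rng_seed = 42L) {
  check_sources(sources)
  n_species <- as.integer(n_species)
  stopifnot(length(species) == n_species)
  if (!is.null(true_p)) {
    true_p <- as.matrix(true_p)
    if (nrow(true_p) != n_species || ncol(true_p) != nrow(sources)) {
      stop("`true_p` must be n_species x n_sources", call. = FALSE)
    }
    if (any(true_p < 0) || any(abs(rowSums(true_p) - 1) > 1e-9)) {
      stop("rows of `true_p` must be proportions summing to 1",
           call. = FALSE)
    }
    rownames(true_p) <- species
    colnames(true_p) <- sources$source
  }
  stopifnot(all(sigma >= 0), all(tdf_sd >= 0))
  n_consumers <- rep_len(as.integer(n_consumers), n_species)
  n_fecal <- rep_len(as.integer(n_fecal), n_species)
  uv <- unit_volume[sources$source]
  if (anyNA(uv)) {
    stop("`unit_volume` must name every source category", call. = FALSE)
  }
  if (is.null(detectability)) {
    detectability <- stats::setNames(rep(1, nrow(sources)), sources$source)
  }
  det <- detectability[sources$source]
  if (anyNA(det) || any(det < 0)) {
    stop("`detectability` must name every source category with values >= 0",
         call. = FALSE)
  }
  structure(list(
    n_species = n_species, species = species, sources = sources,
    true_p = true_p, dirichlet_alpha = dirichlet_alpha,
    tdf_mean = tdf_mean[elements], tdf_sd = tdf_sd[elements],
    sigma = sigma[elements],
    n_consumers = n_consumers, n_fecal = n_fecal,
    items_per_sample = items_per_sample,
    unit_volume = uv, volume_sdlog = volume_sdlog,
    detectability = det,
    rng_seed = as.integer(rng_seed)
  ), class = "scenario_config")
}

# Draw true proportions when the scenario does not fix them.
scenario_true_p <- function(config) {
  if (!is.null(config$true_p)) return(config$true_p)
  K <- nrow(config$sources)
  with_seed(child_seed(config$rng_seed, "true_p"), {
    g <- matrix(stats::rgamma(config$n_species * K,
                              shape = config$dirichlet_alpha),
                config$n_species, K)
    p <- sweep(g, 1L, rowSums(g), "/")
    dimnames(p) <- list(config$species, config$sources$source)
    p
  })
}

#' Generate the source table of a scenario
#'
#' Returns the scenario's source groups, checking that the default
#' identifiability condition holds: every pair of sources at least 2
#' permil apart on at least one element.  Overlapping sources are allowed
#' but flagged with a warning and a `"non_identifiable"` attribute, since
#' a mixing model cannot separate coincident sources.
#'
#' @param config A [scenario_config()].
#' @return The source table (data frame).
#' @export
generate_sources <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  src <- config$sources
  if (nrow(src) < 2L) stop("need at least 2 sources", call. = FALSE)
  mu <- as.matrix(src[paste0("mean_", elements)])
  close_pairs <- character(0L)
  for (i in seq_len(nrow(src) - 1L)) {
    for (j in seq.int(i + 1L, nrow(src))) {
      if (all(abs(mu[i, ] - mu[j, ]) < 2)) {
        close_pairs <- c(close_pairs,
                         paste(src$source[i], src$source[j], sep = " ~ "))
      }
    }
  }
  if (length(close_pairs)) {
    warning("source pairs closer than 2 permil on both elements (non-identifiable): ",
            paste(close_pairs, collapse = "; "), call. = FALSE)
    attr(src, "non_identifiable") <- close_pairs
  }
  src
}

#' Simulate consumer blood isotope values
#'
#' Draws each consumer's per-element value from exactly the likelihood
#' assumed by [fit_mixing_model()]: normal with mean
#' \eqn{\sum_k p^*_k(\mu_{jk}+\lambda_{jk})} and variance
#' \eqn{\sum_k p^{*2}_k(\omega_{jk}^2+\tau_{jk}^2) + \sigma_j^2}.
#'
#' @param config A [scenario_config()].
#' @param sources Optional source table (default: the scenario's).
#' @return An isotope data frame (`individual_id`, `group`, `d13c`,
#'   `d15n`) with a `"true_p"` attribute holding the generating
#'   proportions.
#' @export
simulate_blood <- function(config, sources = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(sources)) sources <- config$sources
  corrected <- correct_sources(sources, config$tdf_mean, config$tdf_sd)
  mu <- as.matrix(corrected[paste0("mean_", elements)])
  v <- as.matrix(corrected[paste0("sd_", elements)])^2
  p <- scenario_true_p(config)
  with_seed(child_seed(config$rng_seed, "blood"), {
    out <- lapply(seq_len(config$n_species), function(i) {
      n <- config$n_consumers[i]
      mix_mu <- as.vector(crossprod(p[i, ], mu))
      mix_sd <- sqrt(as.vector(crossprod(p[i, ]^2, v)) + config$sigma^2)
      vals <- vapply(seq_along(elements), function(j) {
        stats::rnorm(n, mix_mu[j], mix_sd[j])
      }, numeric(n))
      data.frame(
        individual_id = sprintf("%s_%03d", config$species[i], seq_len(n)),
        group = config$species[i],
        d13c = vals[, 1L], d15n = vals[, 2L],
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    attr(out, "true_p") <- p
    out
  })
}

#' Simulate fecal samples
#'
#' For every fecal sample of every species, the number of items is
#' `1 + Poisson(items_per_sample)`, item counts are multinomial over the
#' resource categories with probabilities proportional to the true diet
#' proportions times the per-category detectability, and volumes are
#' `count * unit_volume * lognormal noise`.
#'
#' @param config A [scenario_config()].
#' @return A fecal item data frame (see [read_fecal_table()]) with a
#'   `"true_p"` attribute.
#' @export
simulate_feces <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  p <- scenario_true_p(config)
  cats <- config$sources$source
  with_seed(child_seed(config$rng_seed, "feces"), {
    rows <- list()
    for (i in seq_len(config$n_species)) {
      p_fec <- p[i, ] * config$detectability
      p_fec <- p_fec / sum(p_fec)
      for (s in seq_len(config$n_fecal[i])) {
        n_items <- 1L + stats::rpois(1L, config$items_per_sample)
        counts <- as.vector(stats::rmultinom(1L, n_items, p_fec))
        nz <- which(counts > 0)
        vol <- counts[nz] * config$unit_volume[nz] *
          stats::rlnorm(length(nz), 0, config$volume_sdlog)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_f%03d", config$species[i], s),
          species = config$species[i],
          taxon = cats[nz], category = cats[nz],
          count = counts[nz], volume = vol,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "true_p") <- p
    out
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper returning everything a pipeline run needs, plus
#' the ground truth.
#'
#' @param config A [scenario_config()].
#' @return A list with `sources`, `isotopes`, `feces` and `truth`
#'   (`true_p` and the scenario configuration).
#' @examples
#' study <- simulate_study(scenario_config(rng_seed = 1))
#' str(study$truth$true_p)
#' @export
simulate_study <- function(config = scenario_config()) {
  sources <- generate_sources(config)
  iso <- simulate_blood(config, sources)
  fec <- simulate_feces(config)
  list(sources = sources,
       isotopes = iso,
       feces = fec,
       truth = list(true_p = attr(iso, "true_p"), config = config))
}
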