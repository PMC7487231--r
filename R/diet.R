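#' Prey-specific index of relative importance (PSIRI%)
#'
#' Combines the relative frequency of occurrence of a food item with its
#' prey-specific numeric and volumetric contributions:
#' \deqn{PSIRI\% = \frac{(PN\% + PV\%) \times FO\%}{2} / 100}
#' Because \eqn{FO\% \times PN\%/100} and \eqn{FO\% \times PV\%/100} are
#' the prey-averaged numeric and volumetric contributions, PSIRI% sums to
#' 100 over all items of a species.
#'
#' @param pn_pct Prey-specific numeric contribution, percent.
#' @param pv_pct Prey-specific volumetric contribution, percent.
#' @param fo_pct Relative frequency of occurrence, percent.
#' @return PSIRI%, same length as the inputs.
#' @examples
#' psiri(pn_pct = 40, pv_pct = 60, fo_pct = 50)  # 25
#' @export
psiri <- function(pn_pct, pv_pct, fo_pct) {
  stopifnot(all(pn_pct >= 0 & pn_pct <= 100, na.rm = TRUE),
            all(pv_pct >= 0 & pv_pct <= 100, na.rm = TRUE),
            all(fo_pct >= 0 & fo_pct <= 100, na.rm = TRUE))
  (pn_pct + pv_pct) * fo_pct / 2 / 100
}

# Diet indices for the records of a single species.
tabulate_diet_one <- function(rec, species) {
  samples <- unique(rec$sample_id)
  n_samp <- length(samples)
  tot_count <- tapply(rec$count, rec$sample_id, sum)[samples]
  tot_vol <- tapply(rec$volume, rec$sample_id, sum)[samples]
  zero_count <- names(tot_count)[tot_count == 0]
  zero_vol <- names(tot_vol)[tot_vol == 0]
  if (length(zero_vol)) {
    warning(sprintf(
      "species '%s': sample(s) %s have zero total volume; excluded from PV%% averaging",
      species, paste(zero_vol, collapse = ", ")), call. = FALSE)
  }
  if (length(zero_count)) {
    warning(sprintf(
      "species '%s': sample(s) %s have zero total count; excluded from PN%% averaging",
      species, paste(zero_count, collapse = ", ")), call. = FALSE)
  }

  taxa <- unique(rec$taxon)
  cat_of <- tapply(rec$category, rec$taxon, function(x) {
    u <- unique(x)
    if (length(u) > 1L) {
      stop("taxon mapped to more than one category: ",
           paste(u, collapse = ", "), call. = FALSE)
    }
    u
  })

  grand_count <- sum(rec$count)
  grand_vol <- sum(rec$volume)
  out <- lapply(taxa, function(tx) {
    r <- rec[rec$taxon == tx, , drop = FALSE]
    present <- unique(r$sample_id)
    fo <- length(present)
    # per-sample proportions, only over samples containing the item and
    # with a defined (positive) sample total
    cnt_by_samp <- tapply(r$count, r$sample_id, sum)
    vol_by_samp <- tapply(r$volume, r$sample_id, sum)
    pn_samples <- setdiff(names(cnt_by_samp), zero_count)
    pv_samples <- setdiff(names(vol_by_samp), zero_vol)
    pn <- if (length(pn_samples)) {
      mean(cnt_by_samp[pn_samples] / tot_count[pn_samples]) * 100
    } else NA_real_
    pv <- if (length(pv_samples)) {
      mean(vol_by_samp[pv_samples] / tot_vol[pv_samples]) * 100
    } else NA_real_
    data.frame(
      species = species, taxon = tx, category = unname(cat_of[[tx]]),
      fo = fo, fo_pct = fo / n_samp * 100,
      n = sum(r$count),
      n_pct = if (grand_count > 0) sum(r$count) / grand_count * 100 else NA_real_,
      pn_pct = pn,
      v = sum(r$volume),
      v_pct = if (grand_vol > 0) sum(r$volume) / grand_vol * 100 else NA_real_,
      pv_pct = pv,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out$psiri_pct <- psiri(ifelse(is.na(out$pn_pct), 0, out$pn_pct),
                         ifelse(is.na(out$pv_pct), 0, out$pv_pct),
                         out$fo_pct)
  out[order(-out$psiri_pct, out$taxon), , drop = FALSE]
}

#' Tabulate per-species diet composition from fecal item records
#'
#' Computes, for every food item of every species, the nine standard
#' composition indices: frequency of occurrence (FO) and its relative form
#' (FO%), total and relative numeric contributions (N, N%), prey-specific
#' numeric contribution (PN%: the mean per-sample count proportion over
#' the samples that contain the item), the volumetric analogues (V, V%,
#' PV%), and PSIRI% (see [psiri()]).
#'
#' Samples whose total count (or volume) is zero have undefined per-sample
#' proportions; they are excluded from the PN% (PV%) averages with a
#' warning.
#'
#' @param records Data frame of fecal item records as returned by
#'   [read_fecal_table()] or [simulate_feces()].
#' @param species Optional single species label; default is all species
#'   present.
#' @return A `data.frame` with one row per species x taxon, columns
#'   `species`, `taxon`, `category`, `fo`, `fo_pct`, `n`, `n_pct`,
#'   `pn_pct`, `v`, `v_pct`, `pv_pct`, `psiri_pct`, sorted by decreasing
#'   PSIRI% within species.  Within each species, `n_pct`, `v_pct` and
#'   `psiri_pct` each sum to 100 (when all samples have positive totals).
#' @examples
#' rec <- data.frame(
#'   sample_id = c("s1", "s1", "s2"), species = "t1",
#'   taxon = c("A", "B", "A"), category = c("c3_fruits", "predators",
#'   "c3_fruits"), count = c(3, 1, 1), volume = c(3, 1, 1))
#' tabulate_diet(rec)
#' @export
tabulate_diet <- function(records, species = NULL) {
  stopifnot(is.data.frame(records),
            all(fecal_columns %in% names(records)))
  if (!is.null(species)) {
    if (!species %in% records$species) {
      stop("no fecal records for species '", species, "'", call. = FALSE)
    }
    records <- records[records$species == species, , drop = FALSE]
  }
  sp <- unique(records$species)
  out <- do.call(rbind, lapply(sp, function(s) {
    tabulate_diet_one(records[records$species == s, , drop = FALSE], s)
  }))
  rownames(out) <- NULL
  out
}

#' Classify the trophic guild of each species from its diet volume
#'
#' Pools the volumetric contribution (V%) of each species' food items into
#' broad guilds (e.g. fruit, insect) and applies volume thresholds: the
#' predominant diet type is the guild exceeding `threshold` (default 35%)
#' with the largest share; a secondary diet type is the largest other
#' guild within `secondary` (default 10--35%).  A frugivore with a
#' secondary insectivorous component is labelled `"FR_IN"`; a species with
#' no guild above the threshold is `"indeterminate"`.
#'
#' @param diet Diet-composition table from [tabulate_diet()].
#' @param guild_map Named character vector mapping each `category` (or
#'   `taxon`) appearing in `diet` to a guild code such as `"FR"` or
#'   `"IN"`.
#' @param threshold Predominant-guild volume threshold in percent.
#' @param secondary Length-2 numeric range for a secondary guild.
#' @return A `data.frame` with columns `species`, `predominant`,
#'   `secondary`, `label`, plus a `"basis"` attribute holding the
#'   per-species guild V% breakdown.
#' @examples
#' rec <- data.frame(
#'   sample_id = "s1", species = "t1",
#'   taxon = c("fig", "beetle"), category = c("c3_fruits", "predators"),
#'   count = c(4, 1), volume = c(8, 2))
#' classify_guild(tabulate_diet(rec),
#'                guild_map = c(c3_fruits = "FR", predators = "IN"))
#' @export
classify_guild <- function(diet, guild_map,
                           threshold = 35, secondary = c(10, 35)) {
  stopifnot(is.data.frame(diet), !is.null(names(guild_map)))
  key <- if (all(diet$category %in% names(guild_map))) "category" else "taxon"
  unmapped <- setdiff(unique(diet[[key]]), names(guild_map))
  if (length(unmapped)) {
    stop("no guild mapping for: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  basis <- list()
  rows <- lapply(split(diet, diet$species), function(d) {
    vshare <- tapply(d$v_pct, guild_map[d[[key]]], sum)
    vshare <- sort(vshare, decreasing = TRUE)
    basis[[d$species[1L]]] <<- vshare
    pred <- if (vshare[1L] > threshold) names(vshare)[1L] else NA_character_
    sec <- NA_character_
    if (!is.na(pred)) {
      others <- vshare[-1L]
      cand <- others[others >= secondary[1L] & others <= secondary[2L]]
      if (length(cand)) sec <- names(cand)[1L]
    } else {
      message("species '", d$species[1L],
              "': no guild exceeds ", threshold,
              "% of the diet volume; classification indeterminate")
    }
    data.frame(
      species = d$species[1L],
      predominant = if (is.na(pred)) "indeterminate" else pred,
      secondary = sec,
      label = if (is.na(pred)) "indeterminate"
              else if (is.na(sec)) pred else paste(pred, sec, sep = "_"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "basis") <- basis
  out
}

#' Diet proportion vectors on a common item set
#'
#' Converts a diet-composition table into per-species proportion vectors
#' (rows summing to 1) over the union of items, the common currency of
#' [levins_breadth()] and [pianka_overlap()].  The basis index is
#' switchable because composition can be measured numerically,
#' volumetrically, or by the prey-specific importance index.
#'
#' @param diet Diet-composition table from [tabulate_diet()].
#' @param basis `"psiri"` (default), `"n"` or `"v"`.
#' @param level Aggregate proportions per `"taxon"` (default) or pooled
#'   per `"category"`.
#' @return A numeric matrix, species x items; rows sum to 1; items absent
#'   from a species' diet are 0.
#' @export
diet_proportions <- function(diet, basis = c("psiri", "n", "v"),
                             level = c("taxon", "category")) {
  basis <- match.arg(basis)
  level <- match.arg(level)
  col <- switch(basis, psiri = "psiri_pct", n = "n_pct", v = "v_pct")
  sp <- unique(diet$species)
  items <- unique(diet[[level]])
  P <- matrix(0, nrow = length(sp), ncol = length(items),
              dimnames = list(sp, items))
  for (i in seq_len(nrow(diet))) {
    P[diet$species[i], diet[[level]][i]] <-
      P[diet$species[i], diet[[level]][i]] + diet[[col]][i]
  }
  sweep(P, 1L, rowSums(P), "/")
}
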