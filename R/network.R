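# Weighted bipartite consumer-resource networks: construction, weighted
# nestedness (WNODF), standardized Kullback-Leibler specialization (d'),
# and vaznull-style null-model significance.

check_interaction_matrix <- function(m, require_rows_cols = TRUE) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("interaction weights must be finite and non-negative",
         call. = FALSE)
  }
  if (require_rows_cols &&
      (any(rowSums(m) == 0) || any(colSums(m) == 0))) {
    stop("interaction matrix has an all-zero row or column", call. = FALSE)
  }
  invisible(m)
}

#' Build the diet-based interaction matrix
#'
#' Pools each species' PSIRI% values into the network resource categories:
#' cell \eqn{a_{ij}} is the summed PSIRI% of species \eqn{i}'s food items
#' in category \eqn{j}.  Rows therefore sum to 100.
#'
#' @param diet Diet-composition table from [tabulate_diet()] (all
#'   species).
#' @param category_map Optional named character vector mapping taxa to
#'   network categories; by default the table's own `category` column is
#'   used.  A taxon without a mapping is an error.
#' @param categories Optional vector fixing the column set and order.
#' @return A consumers x resources weight matrix.
#' @export
build_diet_matrix <- function(diet, category_map = NULL,
                              categories = NULL) {
  stopifnot(is.data.frame(diet), "psiri_pct" %in% names(diet))
  cat_col <- if (is.null(category_map)) {
    diet$category
  } else {
    unmapped <- setdiff(unique(diet$taxon), names(category_map))
    if (length(unmapped)) {
      stop("taxa without a category mapping: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
    unname(category_map[diet$taxon])
  }
  if (anyNA(cat_col)) {
    stop("taxa without a category mapping: ",
         paste(unique(diet$taxon[is.na(cat_col)]), collapse = ", "),
         call. = FALSE)
  }
  sp <- unique(diet$species)
  cats <- if (is.null(categories)) unique(cat_col) else categories
  m <- matrix(0, length(sp), length(cats), dimnames = list(sp, cats))
  for (i in seq_len(nrow(diet))) {
    m[diet$species[i], cat_col[i]] <-
      m[diet$species[i], cat_col[i]] + diet$psiri_pct[i]
  }
  check_interaction_matrix(m)
  m
}

#' Build the isotope-based interaction matrix
#'
#' Converts a credible-interval table (see [credible_intervals()] or
#' [thrush_isotope_ci()]) into a consumers x sources weight matrix whose
#' cells are the 95% credible-interval midpoints, \eqn{(lower+upper)/2}
#' (or, via `statistic = "mean"`, the posterior means).  Zero-midpoint
#' cells are retained as structural zeros.
#'
#' @param ci Data frame with columns `species`, `source`, `lower`,
#'   `upper` (and `mean` if `statistic = "mean"`).  Every species x
#'   source cell must be present exactly once.
#' @param statistic `"midpoint"` (default) or `"mean"`.
#' @return A consumers x sources weight matrix.
#' @export
build_isotope_matrix <- function(ci, statistic = c("midpoint", "mean")) {
  statistic <- match.arg(statistic)
  need <- c("species", "source",
            if (statistic == "midpoint") c("lower", "upper") else "mean")
  missing <- setdiff(need, names(ci))
  if (length(missing)) stop_bad_column(missing, "CI table")
  sp <- unique(ci$species)
  src <- unique(ci$source)
  if (nrow(ci) != length(sp) * length(src) ||
      anyDuplicated(ci[c("species", "source")])) {
    stop("CI table must contain every species x source cell exactly once",
         call. = FALSE)
  }
  if (statistic == "midpoint" && any(ci$lower > ci$upper)) {
    stop("lower CI bound exceeds upper bound", call. = FALSE)
  }
  w <- if (statistic == "midpoint") (ci$lower + ci$upper) / 2 else ci$mean
  m <- matrix(0, length(sp), length(src), dimnames = list(sp, src))
  m[cbind(match(ci$species, sp), match(ci$source, src))] <- w
  check_interaction_matrix(m)
  m
}

# KL distance of a use vector (row) against availabilities q
kl_distance <- function(p, q) {
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

# Integer-constrained minimum of the KL distance: allocate `total` units
# over columns with availabilities q (capacities cap) to minimize
# sum_j (a_j/T) log(a_j/(T q_j)).  The objective is separable and convex
# in the a_j, so placing units one at a time on the smallest marginal
# cost is exact (cross-checked by brute-force enumeration in the tests).
dmin_integer <- function(total, q, cap) {
  J <- length(q)
  f <- function(a, j) if (a == 0) 0 else (a / total) * log(a / (total * q[j]))
  alloc <- integer(J)
  marg <- vapply(seq_len(J), function(j) f(1, j), numeric(1L))
  marg[cap < 1] <- Inf
  for (unit in seq_len(total)) {
    j <- which.min(marg)
    alloc[j] <- alloc[j] + 1L
    marg[j] <- if (alloc[j] >= cap[j]) Inf
               else f(alloc[j] + 1L, j) - f(alloc[j], j)
  }
  kl_distance(alloc / total, q)
}

#' Standardized Kullback--Leibler specialization (d')
#'
#' For consumer row \eqn{i} of a weighted interaction matrix, the
#' Kullback--Leibler distance between its resource use
#' \eqn{p'_j = a_{ij}/A_i} and the overall resource availability
#' \eqn{q_j = A_j/m} is
#' \eqn{d_i = \sum_j p'_j \ln(p'_j/q_j)} (zero-use terms contribute 0).
#' It is standardized to \eqn{d' = (d - d_{min})/(d_{max} - d_{min})
#' \in [0, 1]}, from 0 (resource use proportional to availability, the
#' perfect generalist) to 1 (perfect specialist).
#'
#' The maximum \eqn{d_{max} = \ln(m/A_i)} is attained by complete
#' concentration on a partner used exclusively by the consumer; because
#' \eqn{p'_j/q_j \le m/A_i} cell-wise, it bounds \eqn{d_i} for every
#' matrix with the same marginals, so \eqn{d' \le 1} always.  For
#' continuous weights the proportional allocation \eqn{p' = q} is
#' feasible, hence \eqn{d_{min} = 0}; for integer count matrices the
#' integer-constrained minimum is computed by a greedy proportional fill.
#'
#' @param m Weighted interaction matrix (consumers x resources).
#' @param consumer Optional row label or index; default all rows.
#' @return A `data.frame` with columns `consumer`, `d`, `d_min`, `d_max`,
#'   `d_prime`.
#' @examples
#' m <- matrix(c(3, 1, 1, 3), 2, 2, byrow = TRUE,
#'             dimnames = list(c("u", "v"), c("x", "y")))
#' dprime(m)
#' @export
dprime <- function(m, consumer = NULL) {
  check_interaction_matrix(m)
  rows <- if (is.null(consumer)) seq_len(nrow(m)) else consumer
  tot <- sum(m)
  cs <- colSums(m)
  q <- cs / tot
  integer_weights <- all(abs(m - round(m)) < 1e-9)
  out <- lapply(rows, function(i) {
    a <- m[i, ]
    Ai <- sum(a)
    if (Ai <= 0) stop("consumer row total must be positive", call. = FALSE)
    d <- kl_distance(a / Ai, q)
    d_max <- log(tot / Ai)
    d_min <- if (integer_weights) {
      dmin_integer(round(Ai), q, round(cs))
    } else {
      0
    }
    if (d_max - d_min <= .Machine$double.eps) {
      warning("d_max equals d_min (single effective resource); d' set to 0",
              call. = FALSE)
      dp <- 0
    } else {
      dp <- (d - d_min) / (d_max - d_min)
      # d can equal d_max (or d_min) analytically; keep rounding noise
      # from pushing d' infinitesimally outside [0, 1]
      if (dp > 1 && dp - 1 < 1e-9) dp <- 1
      if (dp < 0 && dp > -1e-9) dp <- 0
    }
    nm <- rownames(m)[i]
    data.frame(consumer = if (is.null(nm)) as.character(i) else nm,
               d = d, d_min = d_min, d_max = d_max, d_prime = dp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Weighted nestedness based on overlap and decreasing fill (WNODF)
#'
#' The weighted NODF metric for a consumers x resources matrix: rows and
#' columns are sorted by decreasing fill (number of non-zero cells), ties
#' broken by decreasing marginal totals.  For an ordered pair (u above v):
#' if u's fill does not exceed v's, the pair scores 0; otherwise the score
#' is the percentage of v's non-zero cells whose value is strictly smaller
#' than the corresponding cell of u.  WNODF is the mean of all row-pair
#' and column-pair scores, from 0 (no nested structure) to 100 (every
#' poorer row/column a strictly dominated subset of every richer one).
#'
#' @param m Weighted interaction matrix, at least 2 x 2, no all-zero row
#'   or column.
#' @return WNODF in \[0, 100\], with attributes `rows` and `columns`
#'   holding the two partial means.
#' @examples
#' wnodf(matrix(c(4, 2, 1, 0), 2, 2, byrow = TRUE))  # 100
#' @export
wnodf <- function(m) {
  check_interaction_matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("WNODF needs at least a 2 x 2 matrix", call. = FALSE)
  }
  pair_scores <- function(mm) {
    fill <- rowSums(mm > 0)
    tot <- rowSums(mm)
    ord <- order(fill, tot, decreasing = TRUE)
    mm <- mm[ord, , drop = FALSE]
    fill <- fill[ord]
    n <- nrow(mm)
    scores <- numeric(n * (n - 1L) / 2L)
    k <- 0L
    for (u in seq_len(n - 1L)) {
      for (v in seq.int(u + 1L, n)) {
        k <- k + 1L
        if (fill[u] <= fill[v]) next
        lower <- mm[v, ] > 0
        scores[k] <- 100 * sum(mm[v, lower] < mm[u, lower]) / sum(lower)
      }
    }
    scores
  }
  rs <- pair_scores(m)
  cs <- pair_scores(t(m))
  out <- mean(c(rs, cs))
  attr(out, "rows") <- mean(rs)
  attr(out, "columns") <- mean(cs)
  out
}

# One vaznull-style null matrix on the quantized integer scale.
vaznull_one <- function(nr, nc, fill, total, prob) {
  cells <- integer(0L)
  for (try in seq_len(200L)) {
    cells <- sample.int(nr * nc, fill, prob = prob)
    rows <- ((cells - 1L) %% nr) + 1L
    cols <- ((cells - 1L) %/% nr) + 1L
    if (length(unique(rows)) == nr && length(unique(cols)) == nc) break
    cells <- integer(0L)
  }
  if (!length(cells)) {
    # constructive fallback: cover every row and column first
    rows <- seq_len(nr)
    cols <- sample.int(nc, nr, replace = TRUE, prob = NULL)
    cells <- (cols - 1L) * nr + rows
    missing_cols <- setdiff(seq_len(nc), cols)
    for (cc in missing_cols) {
      rr <- sample.int(nr, 1L)
      cells <- c(cells, (cc - 1L) * nr + rr)
    }
    cells <- unique(cells)
    if (length(cells) > fill) {
      stop("null model infeasible: fill too small to cover all rows and columns",
           call. = FALSE)
    }
    remaining <- setdiff(seq_len(nr * nc), cells)
    extra <- sample(remaining, fill - length(cells),
                    prob = prob[remaining])
    cells <- c(cells, extra)
  }
  null <- matrix(0L, nr, nc)
  null[cells] <- 1L
  if (total > fill) {
    add <- stats::rmultinom(1L, total - fill, prob = prob[cells])
    null[cells] <- null[cells] + as.integer(add)
  }
  null
}

#' vaznull-style null matrices for a weighted bipartite network
#'
#' Generates random interaction matrices that preserve the dimensions,
#' the number of filled cells (connectance) and the total number of
#' interaction events of the original matrix, with cell-assignment
#' probability proportional to the product of the original marginal
#' totals.  Continuous weights are first quantized to
#' `round(weight * scale)` discrete interaction events (the null model is
#' defined on countable interactions); each null then places one event in
#' every selected cell and distributes the remainder multinomially.
#'
#' @param m Weighted interaction matrix.
#' @param n_rand Number of null matrices.
#' @param seed Integer seed (deterministic output).
#' @param scale Quantization factor for continuous weights (default 100).
#'   Use `scale = 1` for matrices that are already counts.
#' @return A list of `n_rand` integer matrices.  Each null has exactly the
#'   quantized grand total and fill of the original, and no empty row or
#'   column.
#' @export
vaznull <- function(m, n_rand, seed = 1L, scale = 100) {
  check_interaction_matrix(m)
  assert_number(n_rand, "n_rand", lower = 1)
  quanta <- round(m * scale)
  if (any(rowSums(quanta) == 0) || any(colSums(quanta) == 0)) {
    stop("quantization produced an empty row/column; increase `scale`",
         call. = FALSE)
  }
  fill <- sum(quanta > 0)
  total <- sum(quanta)
  nr <- nrow(m)
  nc <- ncol(m)
  if (fill < max(nr, nc)) {
    stop("null model infeasible: fewer filled cells than rows/columns",
         call. = FALSE)
  }
  prob <- as.vector(outer(rowSums(m) / sum(m), colSums(m) / sum(m)))
  with_seed(seed, {
    lapply(seq_len(n_rand), function(r) {
      null <- vaznull_one(nr, nc, fill, total, prob)
      dimnames(null) <- dimnames(m)
      null
    })
  })
}

#' Null-model significance test of weighted nestedness
#'
#' Compares the observed WNODF of a matrix with the distribution of WNODF
#' over [vaznull()] randomizations.  Nestedness is significant when the
#' observed value exceeds the upper bound of the null 95% confidence
#' interval (2.5th--97.5th percentile band).
#'
#' @param m Weighted interaction matrix.
#' @param n_rand Number of randomizations (default 1000).
#' @param seed Integer seed.
#' @param scale Quantization factor passed to [vaznull()].
#' @param level Confidence level for the null band (default 0.95).
#' @return An object of class `"nestedness_test"`: list with `observed`,
#'   `null_values`, `null_ci` (lower, upper), `significant`.
#' @export
nestedness_test <- function(m, n_rand = 1000L, seed = 1L, scale = 100,
                            level = 0.95) {
  observed <- as.numeric(wnodf(m))
  nulls <- vaznull(m, n_rand, seed = seed, scale = scale)
  null_values <- vapply(nulls, function(x) as.numeric(wnodf(x)),
                        numeric(1L))
  a <- (1 - level) / 2
  ci <- stats::quantile(null_values, c(a, 1 - a), names = FALSE)
  structure(list(
    observed = observed,
    null_values = null_values,
    null_ci = c(lower = ci[1L], upper = ci[2L]),
    significant = observed > ci[2L],
    n_rand = as.integer(n_rand)
  ), class = "nestedness_test")
}

#' @export
print.nestedness_test <- function(x, ...) {
  cat(sprintf(
    "WNODF = %.1f | null 95%% CI [%.1f, %.1f] (%d randomizations) | %s\n",
    x$observed, x$null_ci["lower"], x$null_ci["upper"], x$n_rand,
    if (x$significant) "significantly nested" else "not significant"))
  invisible(x)
}

#' Plot a weighted bipartite web
#'
#' Draws consumers on the left, resources on the right, and links with
#' width proportional to the interaction weight.
#'
#' @param m Weighted interaction matrix.
#' @param max_lwd Line width of the strongest link (default 10).
#' @return Invisibly, `NULL`.
#' @export
plot_bipartite_web <- function(m, max_lwd = 10) {
  check_interaction_matrix(m)
  nr <- nrow(m)
  nc <- ncol(m)
  ry <- seq(0.9, 0.1, length.out = nr)
  cy <- seq(0.95, 0.05, length.out = nc)
  graphics::plot(NA, xlim = c(-0.35, 1.45), ylim = c(0, 1), axes = FALSE,
                 xlab = "", ylab = "")
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (m[i, j] > 0) {
        graphics::segments(0, ry[i], 1, cy[j],
                           lwd = max_lwd * m[i, j] / max(m),
                           col = grDevices::adjustcolor("steelblue", 0.6))
      }
    }
  }
  graphics::text(-0.02, ry, rownames(m), adj = 1, cex = 0.8)
  graphics::text(1.02, cy, colnames(m), adj = 0, cex = 0.8)
  invisible(NULL)
}
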