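# Dietary niche breadth and overlap from proportion vectors.

check_proportions <- function(p, name = "p") {
  if (!is.numeric(p) || length(p) < 1L || any(!is.finite(p)) || any(p < 0)) {
    stop(sprintf("`%s` must be non-negative finite proportions", name),
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("`%s` must sum to 1 (got %.12f)", name, sum(p)),
         call. = FALSE)
  }
  invisible(p)
}

#' Levins' niche breadth (raw and standardized)
#'
#' Levins' measure \eqn{B = 1 / \sum_i p_i^2} is the reciprocal Simpson
#' concentration of a diet-proportion vector; the standardized form
#' \eqn{\hat{B}_A = (B - 1)/(n - 1)} rescales it to \[0, 1\], where
#' \eqn{n} is the number of food items.
#'
#' @param p Numeric proportion vector (non-negative, summing to 1).
#' @return A list with `b` (Levins' B, in \[1, n\]), `b_std`
#'   (\eqn{\hat{B}_A}; `NA` with a warning when `n = 1`, where
#'   standardization is undefined) and `n_items`.
#' @examples
#' levins_breadth(c(0.5, 0.3, 0.2))
#' @export
levins_breadth <- function(p) {
  check_proportions(p)
  n <- length(p)
  b <- 1 / sum(p^2)
  if (n < 2L) {
    warning("standardized breadth undefined for a single item",
            call. = FALSE)
    b_std <- NA_real_
  } else {
    b_std <- (b - 1) / (n - 1)
  }
  list(b = b, b_std = b_std, n_items = n)
}

# Align two (possibly named) proportion vectors on the union of items.
align_items <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    items <- union(names(p1), names(p2))
    a <- stats::setNames(numeric(length(items)), items)
    b <- a
    a[names(p1)] <- p1
    b[names(p2)] <- p2
    list(a = a, b = b)
  } else {
    if (length(p1) != length(p2)) {
      stop("unnamed proportion vectors must have equal length",
           call. = FALSE)
    }
    list(a = p1, b = p2)
  }
}

#' Pianka's niche overlap between two species
#'
#' Symmetric overlap of two diet-proportion vectors,
#' \deqn{O_{kj} = \frac{\sum_i p_{ij} p_{ik}}
#'   {\sqrt{\sum_i p_{ij}^2 \sum_i p_{ik}^2}},}
#' ranging from 0 (disjoint diets) to 1 (identical diets).  Named vectors
#' are aligned on the union of their items, absent items counting as 0.
#'
#' @param p1,p2 Proportion vectors (each summing to 1 over its own items).
#' @return Overlap in \[0, 1\].
#' @examples
#' pianka_overlap(c(a = 0.5, b = 0.5), c(b = 0.5, c = 0.5))  # 0.5
#' @export
pianka_overlap <- function(p1, p2) {
  al <- align_items(p1, p2)
  check_proportions(al$a, "p1")
  check_proportions(al$b, "p2")
  den <- sqrt(sum(al$a^2) * sum(al$b^2))
  if (den == 0) stop("overlap undefined for an all-zero vector",
                     call. = FALSE)
  sum(al$a * al$b) / den
}

#' Pairwise Pianka overlap and Levins breadth for a proportion matrix
#'
#' Convenience wrappers applying [pianka_overlap()] to every species pair
#' and [levins_breadth()] to every row of a species x items proportion
#' matrix (e.g. from [diet_proportions()]).
#'
#' @param P Numeric matrix, species x items, rows summing to 1.
#' @return `pianka_matrix()`: a symmetric species x species matrix with
#'   unit diagonal.  `breadth_table()`: a data frame with one row per
#'   species (`species`, `b`, `b_std`, `n_items`).
#' @export
pianka_matrix <- function(P) {
  stopifnot(is.matrix(P), nrow(P) >= 2L)
  n <- nrow(P)
  O <- diag(1, n)
  dimnames(O) <- list(rownames(P), rownames(P))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      O[i, j] <- O[j, i] <- pianka_overlap(P[i, ], P[j, ])
    }
  }
  O
}

#' @rdname pianka_matrix
#' @export
breadth_table <- function(P) {
  stopifnot(is.matrix(P))
  out <- do.call(rbind, lapply(seq_len(nrow(P)), function(i) {
    b <- levins_breadth(P[i, ])
    data.frame(species = rownames(P)[i], b = b$b, b_std = b$b_std,
               n_items = b$n_items, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
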