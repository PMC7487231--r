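# Fixtures and independent oracles built in code.

# Two-sample fecal fixture used across diet tests:
#   s1 = {A: 3 items / 3 mm3, B: 1 item / 1 mm3}, s2 = {A: 1 item / 1 mm3}
two_sample_feces <- function() {
  data.frame(
    sample_id = c("s1", "s1", "s2"),
    species = "t1",
    taxon = c("A", "B", "A"),
    category = c("c3_fruits", "predators", "c3_fruits"),
    count = c(3, 1, 1),
    volume = c(3, 1, 1),
    stringsAsFactors = FALSE
  )
}

# The published 3 x 7 credible-interval midpoint matrix.
reference_isotope_matrix <- function() {
  build_isotope_matrix(thrush_isotope_ci())
}

# Random interaction matrix with no empty row or column.
random_matrix <- function(nr, nc, max_val = 9L, p_zero = 0.3) {
  repeat {
    m <- matrix(sample(0:max_val, nr * nc, replace = TRUE,
                       prob = c(rep(p_zero / 1, 1),
                                rep((1 - p_zero) / max_val, max_val))),
                nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# Independent naive WNODF oracle: literal transcription of the
# pairwise decreasing-fill rule, cell by cell, no vectorization.
wnodf_oracle <- function(m) {
  fill_r <- apply(m, 1, function(x) sum(x > 0))
  fill_c <- apply(m, 2, function(x) sum(x > 0))
  ord_r <- order(fill_r, rowSums(m), decreasing = TRUE)
  ord_c <- order(fill_c, colSums(m), decreasing = TRUE)
  m <- m[ord_r, ord_c, drop = FALSE]
  fill_r <- fill_r[ord_r]
  fill_c <- fill_c[ord_c]
  scores <- c()
  for (u in 1:(nrow(m) - 1)) {
    for (v in (u + 1):nrow(m)) {
      if (fill_r[u] <= fill_r[v]) {
        scores <- c(scores, 0)
      } else {
        hits <- 0
        tot <- 0
        for (j in 1:ncol(m)) {
          if (m[v, j] > 0) {
            tot <- tot + 1
            if (m[v, j] < m[u, j]) hits <- hits + 1
          }
        }
        scores <- c(scores, 100 * hits / tot)
      }
    }
  }
  for (u in 1:(ncol(m) - 1)) {
    for (v in (u + 1):ncol(m)) {
      if (fill_c[u] <= fill_c[v]) {
        scores <- c(scores, 0)
      } else {
        hits <- 0
        tot <- 0
        for (i in 1:nrow(m)) {
          if (m[i, v] > 0) {
            tot <- tot + 1
            if (m[i, v] < m[i, u]) hits <- hits + 1
          }
        }
        scores <- c(scores, 100 * hits / tot)
      }
    }
  }
  mean(scores)
}

# Brute-force minimum KL distance over all integer allocations of
# `total` units across columns with capacities `cap` (enumeration).
dmin_brute <- function(total, q, cap) {
  best <- Inf
  recurse <- function(j, left, alloc) {
    if (j == length(q)) {
      if (left <= cap[j]) {
        a <- c(alloc, left)
        p <- a / total
        nz <- p > 0
        best <<- min(best, sum(p[nz] * log(p[nz] / q[nz])))
      }
      return()
    }
    for (x in 0:min(left, cap[j])) recurse(j + 1, left - x, c(alloc, x))
  }
  recurse(1, total, c())
  best
}

# Stub posterior with externally supplied draws (for interval tests).
stub_posterior <- function(p_draws, species = "stub") {
  structure(list(
    species = species,
    sources = colnames(p_draws),
    p = p_draws,
    sigma = matrix(1, nrow(p_draws), 2),
    diagnostics = NULL, accept = NULL, n_chains = 1L,
    converged = TRUE
  ), class = "mixing_posterior")
}

# Unit circle disguised as a niche (area pi), for closed-form overlap.
unit_circle_niche <- function(cx, cy = 0, r = 1) {
  n <- 1e9  # correction factor (n-1)/(n-2) -> 1
  structure(list(species = NULL, n = n, centroid = c(cx, cy),
                 cov = diag(r^2, 2), sea = pi * r^2, seac = pi * r^2),
            class = "isotopic_niche")
}

fast_mcmc <- function(chains = 2L, iter = 6000L, burnin = 2000L,
                      thin = 4L) {
  list(chains = chains, iter = iter, burnin = burnin, thin = thin)
}
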