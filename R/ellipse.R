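# Isotopic niche: standard ellipse areas in delta-space and their overlap.

#' Bootstrap-standardize isotope samples to a common size
#'
#' Resamples a species' isotope records with replacement to a target
#' sample size, so that species with very different field sample sizes can
#' be compared on equal footing before computing ellipses, mixing models
#' or networks.
#'
#' @param records Isotope data frame (one species).
#' @param target_n Target number of records (default 50).
#' @param seed Integer seed; the resampling is deterministic given the
#'   seed.
#' @return A data frame with `target_n` rows drawn from `records`.
#' @export
bootstrap_standardize <- function(records, target_n = 50L, seed = 1L) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 2L) {
    stop("need at least 2 records to bootstrap", call. = FALSE)
  }
  assert_number(target_n, "target_n", lower = 2)
  idx <- with_seed(seed, sample.int(nrow(records), target_n, replace = TRUE))
  out <- records[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standard ellipse of a bivariate isotope sample
#'
#' Fits the standard ellipse (the 1-SD contour of the bivariate normal
#' with the sample mean and covariance) to a species'
#' (\eqn{\delta^{13}}C, \eqn{\delta^{15}}N) values.  Its area is
#' \eqn{SEA = \pi \sqrt{\det \hat\Sigma}} (equivalently
#' \eqn{\pi \sigma_1 \sigma_2 \sqrt{1 - \rho^2}}); the small-sample
#' corrected area is \eqn{SEAc = SEA \, (n-1)/(n-2)}.
#'
#' @param records Isotope data frame with columns `d13c`, `d15n`; at
#'   least 3 rows, non-collinear.
#' @param species Optional label stored in the result.
#' @return An object of class `"isotopic_niche"`: list with `species`,
#'   `n`, `centroid`, `cov`, `sea`, `seac` (permil^2).
#' @examples
#' pts <- data.frame(d13c = c(0, 2, 0, 2), d15n = c(0, 0, 2, 2))
#' standard_ellipse(pts)$seac  # 2*pi
#' @export
standard_ellipse <- function(records, species = NULL) {
  stopifnot(is.data.frame(records), all(elements %in% names(records)))
  X <- as.matrix(records[elements])
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 points for an ellipse", call. = FALSE)
  S <- stats::cov(X)
  dt <- det(S)
  scale2 <- mean(diag(S))^2
  if (!is.finite(dt) || dt <= 1e-12 * max(scale2, 1e-12)) {
    stop("degenerate niche: points are (nearly) collinear", call. = FALSE)
  }
  sea <- pi * sqrt(dt)
  structure(list(
    species = species, n = n,
    centroid = colMeans(X), cov = S,
    sea = sea, seac = sea * (n - 1) / (n - 2)
  ), class = "isotopic_niche")
}

#' @export
print.isotopic_niche <- function(x, ...) {
  cat(sprintf(
    "Isotopic niche%s: n = %d, centroid (%.2f, %.2f), SEA = %.3f, SEAc = %.3f permil^2\n",
    if (is.null(x$species)) "" else paste0(" of ", x$species),
    x$n, x$centroid[1L], x$centroid[2L], x$sea, x$seac))
  invisible(x)
}

# Boundary polygon of the ellipse whose area equals SEAc: the 1-SD
# standard ellipse scaled uniformly (radially) by sqrt((n-1)/(n-2)).
ellipse_polygon <- function(niche, n_vertices = 720L) {
  eg <- eigen(niche$cov, symmetric = TRUE)
  radial <- sqrt((niche$n - 1) / (niche$n - 2))
  ax <- sqrt(pmax(eg$values, 0)) * radial
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  unit <- rbind(ax[1L] * cos(th), ax[2L] * sin(th))
  t(eg$vectors %*% unit + niche$centroid)
}

# Sutherland-Hodgman clipping of convex polygon `subject` by convex
# polygon `clip` (both counter-clockwise, matrices with x/y columns).
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) return(out)
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    # inside = left of directed edge a -> b
    side <- function(p) (b[1L] - a[1L]) * (p[2L] - a[2L]) -
      (b[2L] - a[2L]) * (p[1L] - a[1L])
    inp <- out
    out <- matrix(numeric(0L), ncol = 2L)
    np <- nrow(inp)
    s_prev <- side(inp[np, ])
    prev <- inp[np, ]
    for (j in seq_len(np)) {
      cur <- inp[j, ]
      s_cur <- side(cur)
      if (s_cur >= 0) {
        if (s_prev < 0) {
          t <- s_prev / (s_prev - s_cur)
          out <- rbind(out, prev + t * (cur - prev))
        }
        out <- rbind(out, cur)
      } else if (s_prev >= 0) {
        t <- s_prev / (s_prev - s_cur)
        out <- rbind(out, prev + t * (cur - prev))
      }
      prev <- cur
      s_prev <- s_cur
    }
  }
  out
}

polygon_area <- function(p) {
  if (is.null(nrow(p)) || nrow(p) < 3L) return(0)
  x <- p[, 1L]
  y <- p[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Overlap of two SEAc ellipses
#'
#' Computes the area of intersection of two corrected standard ellipses by
#' polygonal approximation (each ellipse discretized into `n_vertices`
#' vertices, intersected by convex clipping) and expresses it as a
#' percentage of either the union of the two areas (symmetric,
#' Jaccard-style; the default) or the smaller ellipse.
#'
#' @param a,b `"isotopic_niche"` objects from [standard_ellipse()].
#' @param n_vertices Vertices per ellipse polygon (default 720; the
#'   polygonal area converges quadratically in this resolution).
#' @param denominator `"union"` (default) or `"smaller"`.
#' @return A list with `overlap_area` (permil^2), `overlap_pct`, `area_a`,
#'   `area_b` (the polygonal SEAc areas).  Non-intersecting ellipses give
#'   0.
#' @export
ellipse_overlap <- function(a, b, n_vertices = 720L,
                            denominator = c("union", "smaller")) {
  stopifnot(inherits(a, "isotopic_niche"), inherits(b, "isotopic_niche"))
  denominator <- match.arg(denominator)
  pa <- ellipse_polygon(a, n_vertices)
  pb <- ellipse_polygon(b, n_vertices)
  inter <- clip_convex(pa, pb)
  area <- polygon_area(inter)
  area_a <- polygon_area(pa)
  area_b <- polygon_area(pb)
  den <- switch(denominator,
                union = area_a + area_b - area,
                smaller = min(area_a, area_b))
  list(overlap_area = area,
       overlap_pct = 100 * area / den,
       area_a = area_a, area_b = area_b)
}

#' Plot a set of isotopic-niche ellipses
#'
#' Draws the SEAc ellipse boundaries and centroids of several species in
#' delta-space, optionally over the raw points.
#'
#' @param niches Named list of `"isotopic_niche"` objects.
#' @param points Optional isotope data frame with a `group` column, drawn
#'   as background points.
#' @param col Colors recycled over species.
#' @return Invisibly, `NULL`.  Called for its side effect.
#' @export
plot_ellipses <- function(niches, points = NULL,
                          col = grDevices::hcl.colors(length(niches),
                                                      "Dark 3")) {
  polys <- lapply(niches, ellipse_polygon)
  xr <- range(unlist(lapply(polys, function(p) p[, 1L])),
              points$d13c)
  yr <- range(unlist(lapply(polys, function(p) p[, 2L])),
              points$d15n)
  graphics::plot(NA, xlim = xr, ylim = yr,
                 xlab = expression(delta^13 * C ~ ("‰")),
                 ylab = expression(delta^15 * N ~ ("‰")))
  if (!is.null(points)) {
    grp <- factor(points$group)
    graphics::points(points$d13c, points$d15n,
                     col = col[as.integer(grp)], pch = 1, cex = 0.6)
  }
  for (i in seq_along(polys)) {
    graphics::polygon(polys[[i]], border = col[i], lwd = 2)
    graphics::points(niches[[i]]$centroid[1L], niches[[i]]$centroid[2L],
                     col = col[i], pch = 19)
  }
  if (!is.null(names(niches))) {
    graphics::legend("topleft", legend = names(niches), col = col,
                     lwd = 2, bty = "n", cex = 0.8)
  }
  invisible(NULL)
}
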