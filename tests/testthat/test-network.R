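test_that("diet matrices pool PSIRI by category with full row mass", {
  fec <- simulate_feces(scenario_config(rng_seed = 6))
  diet <- tabulate_diet(fec)
  m <- build_diet_matrix(diet, categories = default_categories())
  expect_equal(dim(m), c(3L, 7L))
  expect_equal(unname(rowSums(m)), rep(100, 3), tolerance = 1e-9)

  # single-species, single-category diet collapses to one cell of 100
  mono <- data.frame(sample_id = c("s1", "s2"), species = "t1",
                     taxon = "fig", category = "c3_fruits",
                     count = c(3, 2), volume = c(6, 4))
  m1 <- build_diet_matrix(tabulate_diet(mono))
  expect_equal(dim(m1), c(1L, 1L))
  expect_equal(unname(m1[1, 1]), 100)

  # unmapped taxa are an error listing the offenders
  expect_error(
    build_diet_matrix(tabulate_diet(mono), category_map = c(x = "y")),
    "fig")
})

test_that("isotope matrices are the credible-interval midpoints", {
  m <- reference_isotope_matrix()
  expect_equal(dim(m), c(3L, 7L))
  expect_equal(unname(m["T_rufiventris", "predators"]), (0.55 + 0.69) / 2)
  expect_equal(unname(m["T_rufiventris", "c4cam_fruits"]), 0)

  ci <- data.frame(species = rep(c("s1", "s2"), each = 2),
                   source = c("a", "b", "a", "b"),
                   lower = c(0.4, 0.1, 0.2, 0.3),
                   upper = c(0.4, 0.3, 0.2, 0.5))
  m2 <- build_isotope_matrix(ci)
  expect_equal(unname(m2["s1", ]), c(0.4, 0.2))  # lower = upper -> that value

  expect_error(build_isotope_matrix(ci[-2, ]), "every species x source")
})

test_that("d' is zero for proportional use and one for exclusive use", {
  # row proportional to column totals: perfect generalist
  m <- rbind(c(2, 4, 6), c(1, 2, 3), c(3, 6, 9))
  res <- dprime(m)
  expect_equal(res$d, rep(0, 3), tolerance = 1e-12)
  expect_equal(res$d_prime, rep(0, 3), tolerance = 1e-12)

  # consumer alone on a resource nobody else touches: perfect specialist
  m <- rbind(c(5, 0, 0), c(0, 3, 4), c(0, 2, 6))
  res <- dprime(m, consumer = 1)
  expect_equal(res$d_prime, 1)
})

test_that("d' matches the hand-evaluated 2x2 case", {
  m <- matrix(c(3, 1, 1, 3), 2, 2, byrow = TRUE)
  res <- dprime(m, consumer = 1)
  d_hand <- 0.75 * log(1.5) + 0.25 * log(0.5)
  expect_equal(res$d, d_hand)
  expect_equal(res$d_max, log(8 / 4))
  # integer matrix: the constrained minimum (2,2) hits proportionality
  expect_equal(res$d_min, 0)
  expect_equal(res$d_prime, d_hand / log(2))
})

test_that("integer d_min matches brute-force enumeration", {
  set.seed(14)
  for (i in 1:12) {
    m <- random_matrix(sample(2:3, 1), sample(2:4, 1), max_val = 5)
    q <- colSums(m) / sum(m)
    cap <- colSums(m)
    for (r in seq_len(nrow(m))) {
      total <- sum(m[r, ])
      got <- dprime(m, consumer = r)$d_min
      want <- dmin_brute(total, q, cap)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("d' lies in [0, 1] and d within its bounds on random matrices", {
  set.seed(100)
  for (i in 1:300) {
    m <- random_matrix(sample(2:5, 1), sample(2:8, 1))
    res <- dprime(m)
    expect_true(all(res$d_prime >= 0 & res$d_prime <= 1))
    expect_true(all(res$d >= res$d_min - 1e-12))
    expect_true(all(res$d <= res$d_max + 1e-12))
  }
})

test_that("WNODF matches hand-evaluated fixtures", {
  expect_equal(as.numeric(wnodf(matrix(c(4, 2, 1, 0), 2, 2,
                                       byrow = TRUE))), 100)
  # equal rows: the decreasing-fill condition is never met
  m <- rbind(c(2, 1), c(2, 1))
  expect_equal(attr(wnodf(m), "rows"), 0)
  expect_error(wnodf(rbind(c(1, 0), c(1, 0))), "all-zero")
  expect_error(wnodf(matrix(2, 1, 2)), "2 x 2")
})

test_that("WNODF equals an independent naive oracle on small matrices", {
  set.seed(200)
  for (i in 1:60) {
    m <- random_matrix(sample(2:5, 1), sample(2:8, 1))
    expect_equal(as.numeric(wnodf(m)), wnodf_oracle(m))
  }
})

test_that("WNODF agrees with the reference community-ecology routine", {
  set.seed(300)
  mats <- c(list(reference_isotope_matrix()),
            lapply(1:20, function(i) random_matrix(sample(2:5, 1),
                                                   sample(2:7, 1))))
  for (m in mats) {
    ref <- vegan::nestednodf(m, order = TRUE, weighted = TRUE)
    expect_equal(as.numeric(wnodf(m)),
                 unname(ref$statistic["NODF"]), tolerance = 1e-12)
  }
})

test_that("WNODF is invariant to row/column permutations of the input", {
  set.seed(400)
  m <- random_matrix(4, 6)
  for (i in 1:5) {
    pm <- m[sample(nrow(m)), sample(ncol(m))]
    expect_equal(as.numeric(wnodf(pm)), as.numeric(wnodf(m)))
  }
})

test_that("vaznull conserves totals, fill and coverage on every null", {
  m <- reference_isotope_matrix()
  nulls <- vaznull(m, 60, seed = 10, scale = 100)
  quanta <- round(m * 100)
  for (null in nulls) {
    expect_equal(sum(null), sum(quanta))
    expect_equal(sum(null > 0), sum(quanta > 0))
    expect_true(all(rowSums(null) > 0))
    expect_true(all(colSums(null) > 0))
    expect_equal(dim(null), dim(m))
  }
})

test_that("vaznull is deterministic under a fixed seed", {
  m <- reference_isotope_matrix()
  n1 <- vaznull(m, 2, seed = 7)
  n2 <- vaznull(m, 2, seed = 7)
  expect_identical(n1, n2)
})

test_that("null marginals track the original column totals", {
  m <- reference_isotope_matrix()
  nulls <- vaznull(m, 1000, seed = 12, scale = 100)
  mean_cols <- Reduce(`+`, lapply(nulls, colSums)) / length(nulls)
  expected <- colSums(m) / sum(m) * sum(round(m * 100))
  expect_equal(unname(mean_cols / sum(mean_cols)),
               unname(expected / sum(expected)), tolerance = 0.05)
})

test_that("a perfectly nested matrix tests as significantly nested", {
  m <- rbind(c(8, 4, 2, 1), c(6, 3, 1, 0), c(4, 2, 0, 0), c(2, 0, 0, 0))
  nt <- nestedness_test(m, n_rand = 200, seed = 3, scale = 1)
  expect_equal(nt$observed, 100)
  expect_true(nt$significant)
  nt2 <- nestedness_test(m, n_rand = 200, seed = 3, scale = 1)
  expect_identical(nt$null_ci, nt2$null_ci)
})

test_that("infeasible or invalid matrices are rejected", {
  expect_error(vaznull(rbind(c(0.001, 0), c(0, 0.001)), 2, scale = 100),
               "empty row")
  bad <- rbind(c(1, 0), c(1, 0))
  expect_error(vaznull(bad, 2, scale = 1), "all-zero")
})
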