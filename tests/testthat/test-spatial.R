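# Ripley's K, bivariate K, envelopes, L transform.

csr_pattern <- function(n, seed, w = c(1000, 1000)) {
  set.seed(seed)
  point_pattern(runif(n, 0, w[1]), runif(n, 0, w[2]), w)
}

test_that("points outside the window are rejected, windows must match", {
  expect_error(point_pattern(c(-1), c(5), c(10, 10)), "inside")
  a <- csr_pattern(20, 1)
  b <- csr_pattern(20, 2, c(500, 500))
  expect_error(ripley_k_bivariate(a, b), "window")
})

test_that("CSR K is close to pi r^2 with isotropic correction", {
  p <- csr_pattern(500, 3)
  r <- seq(20, 200, 20)
  k <- ripley_k(p, r)
  expect_true(all(abs(k$k_values / (pi * r^2) - 1) < 0.25))
  expect_true(all(diff(k$k_values) > 0))   # K non-decreasing
})

test_that("uncorrected K equals the brute-force pair-count oracle", {
  for (seed in 1:3) {
    p <- csr_pattern(150, 10 + seed)
    r <- c(30, 60, 120)
    k <- ripley_k(p, r, edge_correction = "none")
    d <- as.matrix(dist(cbind(p$x, p$y))); diag(d) <- Inf
    oracle <- vapply(r, function(rr) 1e6 / 150^2 * sum(d <= rr), numeric(1))
    expect_equal(k$k_values, oracle)
  }
  # a single close pair among far-apart points contributes area * 2 / n^2
  xs <- c(100, 150, seq(300, 900, 100), 900)  # one pair at distance 50
  ys <- c(100, 100, rep(500, 7), 100)
  p2 <- point_pattern(xs, ys, c(1000, 1000))
  k2 <- ripley_k(p2, c(40, 60), edge_correction = "none")
  expect_equal(k2$k_values[1], 0)
  expect_equal(k2$k_values[2], 1e6 * 2 / length(xs)^2)
})

test_that("K is scale-equivariant", {
  p <- csr_pattern(120, 9, c(800, 600))
  r <- c(30, 60, 90)
  k1 <- ripley_k(p, r)
  p2 <- point_pattern(3 * p$x, 3 * p$y, 3 * p$window_nm)
  k2 <- ripley_k(p2, 3 * r)
  expect_equal(k2$k_values, 9 * k1$k_values, tolerance = 1e-10)
})

test_that("radius and point-count preconditions are enforced", {
  p <- csr_pattern(50, 4)
  expect_error(ripley_k(p, c(100, 300)), "radius")
  expect_error(ripley_k(csr_pattern(5, 4), 50), "at least 10")
})

test_that("generator geometries behave as constructed", {
  # csr with zero mean offspring for one species -> empty pattern
  m0 <- point_pattern_model("csr", n_offspring_red = 0, seed = 2)
  expect_length(generate_point_pattern(m0)$red$x, 0)
  # one parent, radius 30: all offspring within 30 nm of the single parent
  m1 <- point_pattern_model("clustered_coassembled", n_parents = 1,
                            parent_radius_nm = 30, n_offspring_green = 40,
                            n_offspring_red = 40, seed = 3)
  pp <- generate_point_pattern(m1)
  all_pts <- cbind(c(pp$green$x, pp$red$x), c(pp$green$y, pp$red$y))
  centre_dist <- sqrt(rowSums(sweep(all_pts, 2, colMeans(all_pts))^2))
  expect_lt(max(dist(all_pts)), 60 + 1e-9)
  # same seed reproduces exactly
  pp2 <- generate_point_pattern(m1)
  expect_identical(pp$green$x, pp2$green$x)
})

test_that("co-assembled species co-cluster more than segregated ones", {
  mk <- function(kind) point_pattern_model(kind, c(1000, 1000), 20, 30,
                                           10, 10, seed = 7)
  pc <- generate_point_pattern(mk("clustered_coassembled"))
  ps <- generate_point_pattern(mk("clustered_segregated"))
  r <- c(15, 30)
  kc <- ripley_k_bivariate(pc$green, pc$red, r)
  ks <- ripley_k_bivariate(ps$green, ps$red, r)
  # at the cluster scale the segregated cross-K drops well below
  expect_gt(kc$k_values[2], ks$k_values[2])
  expect_gt(kc$k_values[2], pi * 30^2)         # co-clustering vs independence
  # relabelling null: segregated falls below the lower envelope
  es <- monte_carlo_envelope(ps$green, ps$red, r, n_sim = 99, seed = 5)
  expect_lt(es$k_values[2], es$envelope_low[2])
  # co-assembled pattern is itself a random labelling: inside the envelope
  ec <- monte_carlo_envelope(pc$green, pc$red, r, n_sim = 99, seed = 5)
  expect_true(all(ec$k_values <= ec$envelope_high * 1.05))
})

test_that("envelopes are seeded, bounded and validated", {
  a <- csr_pattern(60, 21); b <- csr_pattern(60, 22)
  expect_error(monte_carlo_envelope(a, NULL, n_sim = 10), "n_sim")
  e1 <- monte_carlo_envelope(a, b, c(50, 100), n_sim = 49, seed = 9)
  e2 <- monte_carlo_envelope(a, b, c(50, 100), n_sim = 49, seed = 9)
  expect_identical(e1$envelope_low, e2$envelope_low)
  # independent CSR species stay inside the pointwise 95% relabelling
  # envelope at (almost) all radii
  escapes <- sum(e1$k_values < e1$envelope_low |
                 e1$k_values > e1$envelope_high)
  expect_lte(escapes, 1)
})

test_that("CSR patterns stay inside the 95% envelope in most seeded runs", {
  escapes <- 0L
  for (s in 1:15) {
    p <- csr_pattern(80, 100 + s)
    e <- monte_carlo_envelope(p, NULL, 50, n_sim = 39, seed = 200 + s)
    if (e$k_values < e$envelope_low || e$k_values > e$envelope_high) {
      escapes <- escapes + 1L
    }
  }
  expect_lte(escapes, 3)   # ~10% escape rate at a single fixed radius
})

test_that("the L transform is the variance-stabilised companion", {
  r <- seq(10, 100, 10)
  res <- structure(list(radii_nm = r, k_values = pi * r^2,
                        envelope_low = NULL, envelope_high = NULL),
                   class = "kfun_result")
  expect_equal(l_transform(res)$l_minus_r, rep(0, 10))
  res$k_values <- 4 * pi * r^2
  expect_equal(l_transform(res)$l_minus_r, r)
  res$k_values[1] <- -1
  expect_error(l_transform(res), "negative")
})

test_that("point patterns and K results round-trip through CSV", {
  m <- point_pattern_model("clustered_coassembled", seed = 13)
  pp <- generate_point_pattern(m)
  path <- file.path(tempdir(), "pp.csv")
  write_point_pattern(pp, path)
  back <- read_point_pattern(path)
  expect_equal(sort(back$green$x), sort(pp$green$x))
  expect_equal(back$green$window_nm, pp$green$window_nm)
  k <- monte_carlo_envelope(pp$green, pp$red, c(30, 60), n_sim = 39, seed = 1)
  kpath <- file.path(tempdir(), "k.csv")
  write_kfun(k, kpath)
  kk <- utils::read.csv(kpath)
  expect_equal(kk$K, k$k_values)
  meta <- jsonlite::read_json(paste0(kpath, ".json"), simplifyVector = TRUE)
  expect_true(meta$verdict %in% c("co-clustered", "segregated",
                                  "consistent with null"))
  file.remove(path, paste0(path, ".json"), kpath, paste0(kpath, ".json"))
})
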