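# Leakage-corrected coincidence ratios, classification, histograms.

burst_df <- function(g, r) data.frame(photons_green = g, photons_red_raw = r)

test_that("coincidence arithmetic matches the correction formula", {
  # 3:1 green:red after 10% leakage correction
  cc <- coincidence_ratio(burst_df(300, 130), 0.1)
  expect_equal(cc$photons_red_corrected, 100)
  expect_equal(cc$ratio, 0.25)
  # pure green after correction
  expect_equal(coincidence_ratio(burst_df(200, 20), 0.1)$ratio, 0)
  # symmetric 1:1
  expect_equal(coincidence_ratio(burst_df(100, 110), 0.1)$ratio, 0.5)
  # red-only
  expect_equal(coincidence_ratio(burst_df(0, 80), 0.1)$ratio, 1)
  # clipping keeps C in [0, 1]
  expect_equal(coincidence_ratio(burst_df(1000, 50), 0.1)$ratio, 0)
})

test_that("undefined bursts are flagged, not dropped", {
  cc <- coincidence_ratio(burst_df(c(0, 10), c(0, 11)), 0.1)
  expect_true(cc$undefined[1])
  expect_true(is.na(cc$ratio[1]))
  expect_false(cc$undefined[2])
  expect_equal(nrow(cc), 2)
})

test_that("C is invariant under uniform rescaling and monotone in red", {
  set.seed(1)
  g <- sample(50:500, 30); r <- sample(10:400, 30)
  base <- coincidence_ratio(burst_df(g, r), 0.1)$ratio
  for (k in c(2, 7)) {
    expect_equal(coincidence_ratio(burst_df(k * g, k * r), 0.1)$ratio, base)
  }
  rising <- coincidence_ratio(burst_df(rep(100, 20), seq(0, 380, 20)),
                              0.1)$ratio
  expect_true(all(diff(rising) >= 0))
})

test_that("leakage bounds are enforced", {
  expect_error(coincidence_ratio(burst_df(10, 10), 1))
  expect_error(coincidence_ratio(burst_df(10, 10), -0.1))
})

test_that("classification bounds split green / coincident / red", {
  cc <- coincidence_ratio(burst_df(c(200, 100, 0), c(20, 110, 80)), 0.1)
  cc <- classify_bursts(cc, 0.25, 0.75)
  expect_equal(as.character(cc$label),
               c("green_only", "coincident", "red_only"))
  expect_equal(attr(cc, "fraction_coincident"), 1 / 3)
  expect_error(classify_bursts(cc, 0.75, 0.25))
})

test_that("histograms conserve events and record low-event warnings", {
  cc <- coincidence_ratio(burst_df(rep(200, 40), rep(20, 40)), 0.1)
  h <- coincidence_histogram(cc, 25)
  expect_equal(sum(h$counts), 40)
  expect_equal(h$counts[1], 40)          # all C = 0 in the first bin
  expect_true(h$meta$low_events)
  expect_error(coincidence_histogram(cc, 5))
  # C = 1 mass lands in the last bin
  h1 <- coincidence_histogram(coincidence_ratio(burst_df(rep(0, 120),
                                                         rep(50, 120)), 0.1))
  expect_equal(h1$counts[25], 120)
  expect_false(h1$meta$low_events)
})

test_that("segregated species give edge-only mass; mixing recovers the label fraction", {
  # segregated 1:1 -> bimodal at 0 and 1, essentially no coincident bursts
  seg <- make_coassembly_mixture(50, 0.5, "segregated", n_particles = 12)
  tr <- simulate_trace(seg, confocal_model(),
                       sim_config(duration_s = 10, fine_bin_s = 1e-4,
                                  seed = 91))
  cc <- classify_bursts(coincidence_ratio(detect_bursts(tr, 20), 0.1))
  expect_gt(nrow(cc), 200)
  expect_lt(attr(cc, "fraction_coincident"), 0.05)
  h <- coincidence_histogram(cc)
  edge_mass <- (h$counts[1] + h$counts[2] + h$counts[24] + h$counts[25]) /
    h$n_events
  expect_gt(edge_mass, 0.9)

  # mixing at f = 0.5 -> coincident peak centred near C = 0.5
  mix <- make_coassembly_mixture(50, 0.5, "mixing", n_particles = 12)
  tr2 <- simulate_trace(mix, confocal_model(),
                        sim_config(duration_s = 10, fine_bin_s = 1e-4,
                                   seed = 92))
  cc2 <- classify_bursts(coincidence_ratio(detect_bursts(tr2, 20), 0.1))
  expect_gt(attr(cc2, "fraction_coincident"), 0.8)
  mean_c <- mean(cc2$ratio[cc2$label == "coincident"], na.rm = TRUE)
  expect_equal(mean_c, 0.5, tolerance = 0.1)  # round-trip within +-0.05 abs
  expect_lt(abs(mean_c - 0.5), 0.05)
})

test_that("titration endpoints are pure and the stack is ordered", {
  factory <- function(f) make_coassembly_mixture(50, f, "mixing",
                                                 n_particles = 12)
  stack <- titration_stack(c(0, 0.5, 1), factory,
                           config = sim_config(duration_s = 4,
                                               fine_bin_s = 1e-4, seed = 17))
  expect_length(stack, 3)
  h0 <- stack[[1]]; h1 <- stack[[3]]
  # f = 0: all red -> mass at C ~ 1; f = 1: all green -> mass at C ~ 0
  # (background photons in the other channel smear a few % into the
  # neighbouring bins, so the pure-species mass is checked over C < 0.12
  # and C > 0.88)
  expect_gt(sum(h0$counts[23:25]) / h0$n_events, 0.9)
  expect_gt(sum(h1$counts[1:3]) / h1$n_events, 0.9)
  # centre histogram has its mode strictly inside
  mid <- stack[[2]]
  expect_true(which.max(mid$counts) %in% 5:21)
})
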