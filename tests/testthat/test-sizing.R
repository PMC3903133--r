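# Per-burst autocorrelation, diffusion fits, diameter conversion.

fake_burst <- function(start_s, duration_s) {
  data.frame(start_s = start_s, duration_s = duration_s, burst_id = 1)
}

test_that("a pure Poisson stream has g ~ 1 at every reported lag", {
  set.seed(8)
  tr <- photon_trace(rpois(4e5, 0.05), rep(0, 4e5), 1e-6)  # 50 kHz bg, 0.4 s
  cur <- burst_autocorrelation(tr, fake_burst(0.2, 0.001), window_s = 0.15)
  ok <- is.finite(cur$g)
  expect_gt(sum(ok), 20)
  # pointwise: within ~4 crude standard errors of 1, and tiny on average
  expect_lt(max(abs(cur$g[ok] - 1)), 0.1)
  expect_lt(abs(mean(cur$g[ok]) - 1), 0.02)
  # such a curve is either rejected as non-decaying or fits an
  # essentially-zero amplitude
  flat <- tryCatch(fit_residence_time(cur)$amplitude < 0.05,
                   error = function(e) grepl("decay", conditionMessage(e)))
  expect_true(flat)
})

test_that("a telegraph signal decays on its dwell timescale (closed form)", {
  # two-state symmetric telegraph with switching rate k has autocovariance
  # exp(-2 k T): an independent closed-form oracle
  set.seed(21)
  k_rate <- 500                       # 1/s each way -> corr time 1 ms
  n <- 1e6; dt <- 1e-5                # 10 s at 10 us
  flips <- runif(n) < k_rate * dt
  state <- as.integer(cumsum(flips) %% 2 == 0)
  counts <- rpois(n, 0.02 + 3 * state * dt * 1e4)
  tr <- photon_trace(counts, rep(0, n), dt)
  cur <- burst_autocorrelation(tr, fake_burst(5, 0.001), window_s = 4.9)
  sel <- which(is.finite(cur$g) & cur$lags_s < 5e-3)
  amp <- mean(state) * (1 - mean(state)) * (3 * dt * 1e4)^2 /
    (0.02 + 3 * mean(state) * dt * 1e4)^2
  oracle <- 1 + amp * exp(-2 * k_rate * cur$lags_s[sel])
  expect_lt(mean(abs(cur$g[sel] - oracle)), 0.05 * amp + 0.02)
  # half-decay of the measured curve sits near ln(2)/(2k)
  half <- cur$lags_s[sel][which(cur$g[sel] - 1 <= (cur$g[sel][1] - 1) / 2)[1]]
  expect_gt(half, 0.3 * log(2) / (2 * k_rate))
  expect_lt(half, 3 * log(2) / (2 * k_rate))
})

test_that("the diffusion-model fit is self-consistent and amplitude-invariant", {
  lags <- exp(seq(log(1e-6), log(1e-2), length.out = 60))
  model <- function(A, tau, S = 5) 1 + A / (1 + lags / tau) /
    sqrt(1 + lags / (S^2 * tau))
  curve <- list(lags_s = lags, g = model(0.8, 1e-4))
  fit <- fit_residence_time(curve)
  expect_equal(fit$tau_s, 1e-4, tolerance = 0.05)
  # uniform intensity scaling changes A, not tau
  fit2 <- fit_residence_time(list(lags_s = lags, g = model(3.2, 1e-4)))
  expect_equal(fit2$tau_s, fit$tau_s, tolerance = 0.02)
  # with noise, still within 5%
  set.seed(3)
  noisy <- list(lags_s = lags, g = model(0.8, 1e-4) + rnorm(60, 0, 0.005))
  expect_equal(fit_residence_time(noisy)$tau_s, 1e-4, tolerance = 0.05)
  expect_error(fit_residence_time(list(lags_s = lags[1:5], g = rep(1, 5))),
               "at least 10")
})

test_that("residence-to-diameter conversion is the linear calibration rule", {
  ref <- set_reference_tau(monomer_reference(), 1e-4)
  expect_equal(residence_to_diameter(1e-4, ref), 5)
  expect_equal(residence_to_diameter(1.2e-3, ref), 60)
  expect_equal(residence_to_diameter(4e-4, ref), 20)
  expect_error(residence_to_diameter(-1, ref))
  expect_error(residence_to_diameter(1e-4, monomer_reference()), "tau")
})

test_that("size_histogram summarises and respects bin width", {
  set.seed(4)
  est <- c(rnorm(60, 20, 1), rnorm(60, 30, 1))
  h <- size_histogram(est, 2)
  expect_equal(sum(h$counts), 120)
  expect_equal(h$median_nm, median(est))
  occupied <- which(h$counts > 5)
  expect_gt(max(occupied) - min(occupied), 3)   # bimodal spread
  expect_error(size_histogram(rnorm(10, 20)), "at least 50")
})

test_that("simulated monomer transits fit to the Stokes-Einstein residence time", {
  tr <- fixture("fine_mono_short", fine_trace(1, 8, 211, 5))
  bursts <- detect_bursts(rebin_trace(tr, 100), 20)
  expect_gt(nrow(bursts), 10)
  sizes <- size_bursts(tr, bursts, window_s = 0.3, max_bursts = 25)
  taus <- sizes$tau_s[!is.na(sizes$tau_s)]
  expect_gt(length(taus), 10)
  med <- median(taus)
  # predicted ~102 us; tight distribution around it
  expect_gt(med, 70e-6)
  expect_lt(med, 140e-6)
  expect_lt(IQR(taus) / med, 0.8)
})
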