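test_that("Poincare descriptors: degenerate and hand-computed cases", {
  pc <- poincare_descriptors(rep(800, 10))
  expect_equal(pc$sd1, 0)
  expect_equal(pc$sd2, 0)
  expect_true(is.na(pc$sd1_sd2))

  pc2 <- poincare_descriptors(c(800, 900, 800, 900, 800))
  expect_equal(pc2$sd1, sqrt(4 * 5000 / 3))
  expect_equal(pc2$sd2, 0)
})

test_that("rotation preserves total variance: sd1^2 + sd2^2 = var(x) + var(y)", {
  set.seed(61)
  for (i in 1:30) {
    x <- fuzz_rr(sample(5:200, 1))
    pc <- poincare_descriptors(x)
    n <- length(x)
    expect_equal(pc$sd1^2 + pc$sd2^2, var(x[-n]) + var(x[-1]),
                 tolerance = 1e-9)
  }
})

test_that("asymmetry indices: hand counts and monotone/alternating extremes", {
  a <- asymmetry_indices(c(800, 850, 820, 860))
  expect_equal(a$porta, 100 / 3, tolerance = 1e-10)

  up <- asymmetry_indices(c(800, 820, 850, 900))
  expect_equal(up$porta, 0)
  expect_equal(up$guzik, 100)
  expect_equal(up$slope, 100)

  alt <- asymmetry_indices(c(800, 900, 800, 900, 800))
  expect_equal(alt$guzik, 50)
  expect_equal(alt$porta, 50)
  expect_equal(alt$slope, 50)

  expect_error(asymmetry_indices(rep(800, 10)), "identity line")
})

test_that("time reversal mirrors all three asymmetry indices about 50", {
  set.seed(62)
  for (i in 1:20) {
    x <- fuzz_rr(sample(10:100, 1)) + runif(1)  # continuous: no on-line points
    if (any(diff(x) == 0)) next
    f <- asymmetry_indices(x)
    r <- asymmetry_indices(rev(x))
    expect_equal(f$guzik + r$guzik, 100, tolerance = 1e-9)
    expect_equal(f$porta + r$porta, 100, tolerance = 1e-9)
    expect_equal(f$slope + r$slope, 100, tolerance = 1e-7)
  }
})

test_that("entropies vanish on constant series and match brute force", {
  expect_equal(approximate_entropy(rep(800, 30), r = 10), 0)
  expect_equal(as.numeric(sample_entropy(rep(800, 30), r = 10)), 0)

  set.seed(63)
  x <- fuzz_rr(12)
  r <- 0.2 * sd(x)
  expect_equal(approximate_entropy(x, m = 2, r = r), apen_oracle(x, 2, r),
               tolerance = 1e-12)
  expect_equal(as.numeric(sample_entropy(x, m = 2, r = r)),
               sampen_oracle(x, 2, r), tolerance = 1e-12)
})

test_that("irregular series carry more entropy than a sinusoid", {
  set.seed(64)
  sine <- sinusoid_rr(amp = 50, freq = 0.25, duration_s = 1000)$intervals[1:1000]
  shuffled <- sample(sine)
  r <- 0.2 * sd(sine)
  expect_gt(approximate_entropy(shuffled, r = r),
            approximate_entropy(sine, r = r))
  expect_gt(as.numeric(sample_entropy(shuffled, r = r)),
            as.numeric(sample_entropy(sine, r = r)))
})

test_that("sample entropy flags an unusable tolerance instead of erroring", {
  set.seed(65)
  x <- rnorm(40)  # continuous, r = 0: no matches at all
  s <- sample_entropy(x, r = 0)
  expect_true(is.na(s))
  expect_true(isTRUE(attr(s, "undefined")))
  expect_error(sample_entropy(x, r = -1), "r must be")
})

test_that("correlation dimension: degenerate flag and the closed curve", {
  d <- correlation_dimension(rep(800, 200))
  expect_true(is.na(d))
  expect_true(isTRUE(attr(d, "undefined")))

  x <- 900 + 100 * sin(2 * pi * 0.1 * (1:2000) * 0.9)
  expect_equal(correlation_dimension(x), 1, tolerance = 0.3)
})

test_that("the correlation sum is a monotone CDF reaching 1", {
  set.seed(66)
  x <- fuzz_rr(200)
  d <- hrvaf:::cpp_embed_dists(x, 10L, 1L)
  radii <- seq(min(d), max(d) * 1.001, length.out = 20)
  cr <- vapply(radii, function(r) mean(d < r), numeric(1))
  expect_true(all(diff(cr) >= 0))
  expect_equal(cr[length(cr)], 1)
})

test_that("recurrence rate: extremes and brute-force agreement", {
  expect_equal(recurrence_rate(rep(800, 50)), 100)
  set.seed(67)
  x <- fuzz_rr(30)
  expect_equal(recurrence_rate(x, m = 2, tau = 1, threshold = 0), 0)
  thr <- sqrt(10) * sd(x)
  expect_equal(recurrence_rate(x, m = 10, tau = 1, threshold = thr),
               rec_oracle(x, 10, 1, thr), tolerance = 1e-12)
})

test_that("the battery is label-agnostic and deterministic", {
  set.seed(68)
  x <- fuzz_rr(400)
  rr1 <- rr_series(x, source_id = "a")
  rr2 <- rr_series(x, source_id = "something else")
  expect_identical(nonlinear_metrics(rr1), nonlinear_metrics(rr2))
  expect_identical(nonlinear_metrics(x), nonlinear_metrics(x))
})

test_that("halving prescribed band powers attenuates SD2 and total power", {
  d_sd2 <- numeric(0); d_tp <- numeric(0)
  for (s in 1:10) {
    r1 <- simulate_rr_series(simulation_params(duration_s = 900, seed = s))
    r2 <- simulate_rr_series(simulation_params(
      band_power = c(VLF = 900, LF = 250, HF = 100), duration_s = 900,
      seed = s))
    d_sd2 <- c(d_sd2, poincare_descriptors(r1)$sd2 - poincare_descriptors(r2)$sd2)
    f1 <- freq_domain_metrics(r1, detrend_lambda = NULL)
    f2 <- freq_domain_metrics(r2, detrend_lambda = NULL)
    d_tp <- c(d_tp, f1$total_power - f2$total_power)
  }
  expect_gt(mean(d_sd2), 0)
  expect_gt(mean(d_tp), 0)
})
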