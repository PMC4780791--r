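test_that("current is linear in the count and inverse in the duration", {
  expect_equal(permeation_current(0, 1), 0)
  expect_equal(permeation_current(10, 0.5), 2 * permeation_current(5, 0.5))
  expect_equal(permeation_current(10, 1.0), permeation_current(10, 0.5) / 2)
  expect_lt(permeation_current(-3, 0.5), 0)
  expect_error(permeation_current(5, 0), "positive")
})

test_that("free-energy differences follow the Boltzmann closed form", {
  # -R T ln 3 at 300 K
  expect_equal(delta_g(0.1, 0.3), -8.314462618e-3 * 300 * log(3),
               tolerance = 1e-12)
  expect_equal(delta_g(0.1, 0.3), -2.74, tolerance = 0.01)
  expect_equal(delta_g(0.2, 0.2), 0)

  set.seed(21)
  for (i in 1:20) {
    p <- runif(3, 0.01, 0.99)
    expect_equal(delta_g(p[1], p[2]), -delta_g(p[2], p[1]))
    expect_equal(delta_g(p[1], p[3]),
                 delta_g(p[1], p[2]) + delta_g(p[2], p[3]))
  }
  expect_error(delta_g(0, 0.5), "zero occupancy")
})

test_that("event series partition events into blocks", {
  s <- event_block_series(times_ps = c(50, 150, 151, 950),
                          signs = c(1, 1, -1, 1),
                          duration_ps = 1000, block_size_ps = 100)
  expect_length(s, 10L)
  expect_equal(s[1], 1)
  expect_equal(s[2], 0)   # +1 and -1 cancel
  expect_equal(s[10], 1)
  expect_equal(sum(s), 2)
  expect_error(event_block_series(1, 1, duration_ps = 100,
                                  block_size_ps = 100),
               "fewer than 2 blocks")
})

test_that("local block bootstrap matches the analytic i.i.d. limit", {
  expect_equal(block_bootstrap_se(rep(0, 100)), 0)

  # determinism contract
  set.seed(99); series <- rbinom(200, 1, 0.3)
  a <- block_bootstrap_se(series, n_boot = 2000, seed = 7)
  b <- block_bootstrap_se(series, n_boot = 2000, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, block_bootstrap_se(series, n_boot = 2000,
                                               seed = 8)))

  # i.i.d. Bernoulli blocks, window spanning the whole series: the SE of
  # the current equals the binomial SE of the block sum, scaled
  B <- 500L
  set.seed(42)
  s <- rbinom(B, 1, 0.2)
  duration_us <- B * 100 * 1e-6
  se <- block_bootstrap_se(s, block_size_ps = 100, n_boot = 1e4,
                           locality_window = B, seed = 1)
  phat <- mean(s)
  analytic <- sqrt(B * phat * (1 - phat)) * 1.602176634e-19 * 1e18 /
    duration_us
  expect_lt(abs(se - analytic) / analytic, 0.10)
})

test_that("bootstrap SE shrinks like one over sqrt(blocks)", {
  set.seed(4)
  p <- 0.3
  se_small <- block_bootstrap_se(rbinom(250, 1, p), n_boot = 4000,
                                 locality_window = 250, seed = 2)
  se_large <- block_bootstrap_se(rbinom(1000, 1, p), n_boot = 4000,
                                 locality_window = 1000, seed = 2)
  # SE of the current over a 4x longer span: sqrt(4*B)/4 = 1/2 the SE
  expect_equal(se_large / se_small, 0.5, tolerance = 0.2)
})

test_that("mechanism-ratio bootstrap error is a proper fraction SE", {
  set.seed(12)
  n <- 60L
  cond <- data.table::data.table(
    t_exit_ps = sort(runif(n, 0, 5e4)),
    mechanism = sample(c("III-IV-III", "III-II-III"), n, replace = TRUE))
  se <- mechanism_ratio_se(cond, duration_ps = 5e4, block_size_ps = 100,
                           n_boot = 2000, locality_window = 500, seed = 3)
  expect_gte(se, 0)
  expect_lte(se, 0.5)
})

test_that("summarize_condition assembles a coherent record", {
  sim <- simulate_hopping(hop_model(), t_end_ns = 60, seed = 5)
  s <- summarize_condition("base", sim$trajectory, default_site_model(),
                           voltage_mV = 500, n_boot = 1000, seed = 5)
  expect_equal(s$n_push + s$n_pull + s$n_unclassified,
               s$n_outward + s$n_inward)
  expect_equal(s$current_pA,
               permeation_current(s$n_outward - s$n_inward, s$duration_us))
  expect_gte(s$current_se_pA, 0)
  expect_true(s$push_ratio >= 0 && s$push_ratio <= 1)
  expect_true(s$mean_pore_ions > 2 && s$mean_pore_ions < 4.5)

  # degenerate: frozen pore, no events -> zero current, flagged ratio
  frozen <- hop_model(k0 = 0, k_in_intra = 0, k_in_extra = 0,
                      k_out_extra = 0, k_out_intra = 0, jitter_sd = 0)
  fsim <- simulate_hopping(frozen, t_end_ns = 5, seed = 1)
  fs <- summarize_condition("frozen", fsim$trajectory, default_site_model(),
                            n_boot = 100, seed = 1)
  expect_equal(fs$current_pA, 0)
  expect_true(is.na(fs$push_ratio))
  expect_match(paste(fs$flags, collapse = " "), "ratio undefined")
})
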