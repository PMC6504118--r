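make_spikes <- function(trains) {
  data.frame(time = unlist(trains),
             id = rep(seq_along(trains), lengths(trains)))
}

test_that("a clock-like train has zero CV, zero entropy and ISI-5% = period", {
  sp <- make_spikes(list(seq(100, 10000, by = 100)))
  st <- spike_statistics(sp, ids = 1, window = c(0, 10000), seed = 1)
  expect_equal(st$CV_ISI, 0)
  expect_equal(st$ISI_5, 0.1)       # seconds
  expect_equal(st$H_ISI, 0)         # single-valued ISI distribution
})

test_that("Poisson trains have unit CV and vanishing pairwise correlation", {
  set.seed(42)
  dur <- 100000  # ms
  trains <- replicate(60, sort(runif(rpois(1, 20 * dur / 1000), 0, dur)),
                      simplify = FALSE)
  st <- spike_statistics(make_spikes(trains), ids = 1:60,
                         window = c(0, dur), seed = 2)
  expect_lt(abs(st$CV_ISI - 1), 0.05)
  n_bins <- dur / st$cc_binsize
  expect_lt(abs(st$CC), 3 / sqrt(n_bins) + 0.01)
  expect_equal(st$rate, 20, tolerance = 0.05)
})

test_that("sparse neurons are excluded from ISI statistics and counted", {
  trains <- list(seq(100, 9000, by = 100), c(500, 900))
  st <- spike_statistics(make_spikes(trains), ids = 1:2,
                         window = c(0, 10000), seed = 1)
  expect_equal(st$n_excluded_isi, 1)
  expect_equal(st$CV_ISI, 0)
})

test_that("E/I balance summary behaves on constructed currents", {
  n <- 2000
  x <- rnorm(n)
  fake <- list(I_exc = rbind(x, rnorm(n)), I_inh = rbind(-x, rnorm(n)),
               record_c_idx = 1:2)
  bal <- ei_balance(fake)
  expect_equal(bal$cc[1], -1)
  expect_lt(abs(bal$cc[2]), 2 / sqrt(n) + 0.05)
  expect_equal(unname(bal$abs_diff[1]), abs(mean(-x) + mean(x)))
  expect_error(ei_balance(list(I_exc = NULL)), "not recorded")
})

test_that("intrinsic timescale is recovered on Ornstein-Uhlenbeck traces", {
  dt <- 1
  n <- 1e5
  for (tau_c in c(10, 50, 200)) {
    set.seed(tau_c)
    ar <- exp(-dt / tau_c)
    x <- as.numeric(stats::arima.sim(list(ar = ar), n, sd = 1))
    fit <- intrinsic_timescale(x, dt = dt, max_lag = 5 * tau_c)
    expect_true(fit$ok)
    expect_lt(abs(fit$tau_int - tau_c) / tau_c, 0.1)
  }
})

test_that("white noise yields a sub-sample intrinsic timescale", {
  set.seed(8)
  fit <- intrinsic_timescale(rnorm(5e4), dt = 1, max_lag = 100)
  expect_lt(fit$tau_int, 1)
})

test_that("effective time constant reduces to C_m/g_leak without synaptic input", {
  mc <- tiny_circuit(N = 60)
  res <- simulate_circuit(mc, stimulus_program(nu_in = 0), duration = 500,
                          seed = 1, record = "gtot",
                          record_c_idx = seq_len(60))
  eff <- effective_time_constant(res, mc)
  expect_equal(eff$tau_eff, eff$tau_0, tolerance = 1e-9)
  # baseline time constants of the homogeneous classes
  i1 <- class_hom_params("I1")
  expect_equal(i1$C_m / i1$g_leak, 10.72, tolerance = 0.001)
  e <- class_hom_params("E")
  expect_equal(e$C_m / e$g_leak, 25.11, tolerance = 0.001)
})

test_that("tau_eff never exceeds tau_0 under synaptic bombardment", {
  mc <- tiny_circuit(N = 100, seed = 4)
  res <- simulate_circuit(mc, stimulus_program(nu_in = 15), duration = 1000,
                          seed = 2, record = "gtot",
                          record_c_idx = seq_len(100))
  eff <- effective_time_constant(res, mc)
  expect_true(all(eff$tau_eff <= eff$tau_0 + 1e-9))
})

test_that("rate transfer is monotone for inhibitory populations and null vs itself", {
  base <- rate_transfer("Hom", nu_grid = c(5, 10, 15), N = 250,
                        duration = 1000, seeds = 21)
  expect_true(all(diff(base$rates["I1", ]) >= 0))
  expect_true(all(diff(base$rates["I2", ]) >= 0))
  self <- rate_transfer("Hom", nu_grid = c(5, 10, 15), N = 250,
                        duration = 1000, seeds = 21, baseline = base)
  expect_equal(unname(self$delta_gain), c(0, 0, 0))
  expect_equal(unname(self$delta_offset), c(0, 0, 0))
})
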