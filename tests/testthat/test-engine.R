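test_that("rest is a fixed point of the undriven circuit", {
  mc <- tiny_circuit(N = 60)
  res <- simulate_circuit(mc, stimulus_program(nu_in = 0), duration = 1000,
                          seed = 1, record = "V")
  expect_equal(nrow(res$spikes), 0)
  arr <- hetmicro:::circuit_arrays(mc)
  expect_lt(max(abs(res$final_V - arr$npar[, "E_leak"])), 1e-9)
})

test_that("identical circuit, program and seed give bit-identical results", {
  mc <- tiny_circuit(N = 80, seed = 9)
  r1 <- simulate_circuit(mc, stimulus_program(nu_in = 20), duration = 500,
                         seed = 3, record = "V")
  r2 <- simulate_circuit(mc, stimulus_program(nu_in = 20), duration = 500,
                         seed = 3, record = "V")
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$V, r2$V)
})

test_that("no inter-spike interval violates refractoriness", {
  mc <- tiny_circuit(N = 100, seed = 2)
  res <- simulate_circuit(mc, stimulus_program(nu_in = 40), duration = 2000,
                          seed = 5, record = character(0))
  expect_gt(nrow(res$spikes), 100)
  arr <- hetmicro:::circuit_arrays(mc)
  for (i in unique(res$spikes$id)) {
    isi <- diff(res$spikes$time[res$spikes$id == i])
    if (length(isi)) expect_gte(min(isi), arr$tref[i])
  }
})

test_that("a forced spike in the network reproduces the single-neuron PSP", {
  mc <- tiny_circuit(N = 60)  # quiescent: no background, nothing else fires
  tgt <- 3
  res <- simulate_circuit(mc, stimulus_program(nu_in = 0), duration = 320,
                          seed = 1, record = "V", record_every = 0.1,
                          record_v_idx = tgt,
                          ext_spikes = data.frame(time = 10, neuron = tgt,
                                                  weight = 1,
                                                  polarity = "exc"))
  expect_equal(nrow(res$spikes), 0)
  defl <- as.numeric(res$V) - (-76.43)
  oracle <- psp_response("E", "exc", holding = "rest")
  odefl <- oracle$deflection[oracle$t > 0]
  n <- min(length(odefl), sum(res$trace_times > 10))
  got <- defl[res$trace_times > 10][seq_len(n)]
  expect_lt(max(abs(got - odefl[seq_len(n)])), 1e-3)
})

test_that("doubling a small synaptic weight doubles the PSP peak", {
  p1 <- psp_response("E", "exc", weight = 0.5)
  p2 <- psp_response("E", "exc", weight = 1)
  expect_lt(abs(p2$J_syn / p1$J_syn - 2), 0.01)
})

test_that("halving the step leaves population rates approximately unchanged", {
  mc <- build_microcircuit(250, "Hom", seed = 6)
  n1 <- nrow(simulate_circuit(mc, stimulus_program(nu_in = 10),
                              duration = 4000, seed = 11,
                              record = character(0))$spikes)
  mc2 <- build_microcircuit(250, "Hom", seed = 6, resolution = 0.05)
  n2 <- nrow(simulate_circuit(mc2, stimulus_program(nu_in = 10),
                              duration = 4000, seed = 11,
                              record = character(0))$spikes)
  expect_lt(abs(n1 - n2) / n1, 0.05)
})

test_that("background generator matches its Poisson expectation", {
  cnt <- make_background(10, 1000, 3, 10000, seed = 2)
  expect_equal(dim(cnt), c(1e5, 3))
  for (j in 1:3)
    expect_lt(abs(sum(cnt[, j]) - 1e5), 3 * sqrt(1e5))
  expect_true(all(make_background(0, 1000, 2, 100) == 0))
})

test_that("input signal is uniform, bounded and piecewise constant", {
  sig <- make_input_signal(1e5, delta_t = 10, rho_u = 50, seed = 3)
  expect_true(all(sig$u >= 0 & sig$u <= 1))
  expect_lt(abs(mean(sig$u) - 0.5), 0.01)
  expect_true(all(sig$current >= 0 & sig$current <= 50))
  cur <- matrix(sig$current, nrow = 100)   # one column per input step
  expect_true(all(apply(cur[, 1:50], 2, function(x) diff(range(x))) == 0))
})

test_that("state initialization modes behave as documented", {
  mc <- tiny_circuit(N = 60)
  rest <- initialize_states(mc, "rest")
  arr <- hetmicro:::circuit_arrays(mc)
  expect_equal(rest$V, unname(arr$npar[, "E_leak"]))
  rnd1 <- initialize_states(mc, "random", seed = 4)
  rnd2 <- initialize_states(mc, "random", seed = 4)
  expect_identical(rnd1, rnd2)
  expect_true(all(rnd1$V >= arr$npar[, "E_leak"]))
  expect_true(all(rnd1$V <= arr$npar[, "V_thresh"]))
})

test_that("circuit composition follows the population fractions", {
  expect_equal(unname(population_sizes(2500)), c(2000L, 175L, 325L))
  for (N in c(100, 250, 1234)) {
    sz <- population_sizes(N)
    expect_equal(sum(sz), N)
    expect_equal(unname(sz["E"]), as.integer(round(0.8 * N)))
  }
  mc <- build_microcircuit(2500, "Hom", seed = 1)
  expect_equal(unname(mc$sizes), c(2000L, 175L, 325L))
})
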