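test_that("weight shuffling preserves the multiset and ranks the designated set", {
  mc <- build_microcircuit(250, "Syn", seed = 2)
  targets <- 1:50
  for (scheme in c("Shuffled_1", "Shuffled_2", "Shuffled_3")) {
    mc2 <- apply_shuffle(mc, scheme, targets = targets, seed = 3)
    pool <- if (scheme == "Shuffled_3") c("E->E", "E->I1", "E->I2") else "E->E"
    w1 <- sort(unname(unlist(lapply(mc$blocks[pool], `[[`, "weights"))))
    w2 <- sort(unname(unlist(lapply(mc2$blocks[pool], `[[`, "weights"))))
    expect_equal(w1, w2)
  }
  sh2 <- apply_shuffle(mc, "Shuffled_2", targets = targets, seed = 4)
  blk <- sh2$blocks[["E->E"]]
  inset <- blk$pre %in% targets
  expect_gte(min(blk$weights[inset]), max(blk$weights[!inset]))
  expect_identical(apply_shuffle(mc, "none", targets), mc)
})

test_that("conditions under one master seed share their untouched components", {
  hom <- build_microcircuit(150, "Hom", seed = 11)
  str_ <- build_microcircuit(150, "Str", seed = 11)
  neu <- build_microcircuit(150, "Neu", seed = 11)
  # Hom vs Str: identical neuron parameters and weights, adjacency differs
  expect_identical(hom$populations, str_$populations)
  expect_identical(lapply(hom$blocks, `[[`, "weights")[[1]][1],
                   lapply(str_$blocks, `[[`, "weights")[[1]][1])
  expect_false(identical(hom$blocks[["E->E"]]$pre, str_$blocks[["E->E"]]$pre))
  # Hom vs Neu: identical adjacency and weights, neuron parameters differ
  for (b in names(hom$blocks)) {
    expect_identical(hom$blocks[[b]]$pre, neu$blocks[[b]]$pre)
    expect_identical(hom$blocks[[b]]$post, neu$blocks[[b]]$post)
    expect_identical(hom$blocks[[b]]$weights, neu$blocks[[b]]$weights)
  }
  expect_false(identical(hom$populations$E$pars$C_m, neu$populations$E$pars$C_m))
})

test_that("weight correlations engage only when structural and synaptic combine", {
  syn <- build_microcircuit(150, "Syn", seed = 12)
  het <- build_microcircuit(150, "Het", seed = 12)
  # in Syn the E->E weights are plain lognormal draws; Het rescales them
  expect_false(isTRUE(all.equal(sort(syn$blocks[["E->E"]]$weights),
                                sort(het$blocks[["E->E"]]$weights))))
  # blocks without correlation parameters keep the same weight distribution
  expect_identical(syn$blocks[["I1->E"]]$weights, het$blocks[["I1->E"]]$weights)
})

test_that("an end-to-end configured run completes, validates and reruns identically", {
  out1 <- file.path(tempdir(), "run_a"); out2 <- file.path(tempdir(), "run_b")
  cfg <- list(N = 150, condition = "Hom", duration = 800, seed = 5)
  r1 <- run_experiment(c(cfg, list(out_dir = out1)))
  r2 <- run_experiment(c(cfg, list(out_dir = out2)))
  for (f in c("spikes.txt", "summary.json", "manifest.json"))
    expect_true(file.exists(file.path(out1, f)))
  expect_identical(readLines(file.path(out1, "spikes.txt")),
                   readLines(file.path(out2, "spikes.txt")))
  s <- jsonlite::read_json(file.path(out1, "summary.json"))
  expect_true(all(c("rates", "fraction_active", "ei_cc", "mean_V") %in% names(s)))
  # quiet-state depolarization ordering: I1 closest to threshold, E farthest
  expect_gt(s$mean_V$I1, s$mean_V$E)
})

test_that("input tuning fails loudly when the bounds are infeasible", {
  mc <- build_microcircuit(100, "Hom", seed = 1)
  expect_error(
    tune_active_inputs(mc, nu_grid = 5, rho_grid = 100, duration = 300,
                       bounds = rbind(lower = c(4.999, 10, 3),
                                      upper = c(5.001, 10.001, 3.001))),
    "no admissible")
  tn <- tune_active_inputs(mc, nu_grid = c(5, 10), rho_grid = 100,
                           duration = 300,
                           bounds = rbind(lower = c(0, 0, 0),
                                          upper = c(1e5, 1e5, 1e5)))
  expect_equal(tn$nu_in, 5)      # lowest admissible drive is returned
  expect_equal(nrow(tn$scan), 2)
})
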