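# Orchestration of the heterogeneity experiments: active-state input
# tuning, weight-shuffling controls, and configured end-to-end runs.

#' Tune active-state input parameters
#'
#' Scans a grid of background rates and injected-current amplitudes and
#' returns the first (lexicographically smallest, i.e. lowest-drive)
#' combination for which the population mean firing rates fall within
#' realistic bounds: E in `[0.5, 5]`, I1 in `[10, 25]`, I2 in `[3, 15]`
#' spikes/s. The full scan table is returned for inspection; if no grid
#' point is admissible an error lists the nearest misses.
#'
#' @param circuit a `microcircuit`.
#' @param nu_grid background rates (spikes/s).
#' @param rho_grid current amplitudes (pA).
#' @param delta_t input step (ms) of the piecewise-constant signal.
#' @param duration per-point simulated time (ms).
#' @param seeds seeds averaged per grid point.
#' @param bounds 2x3 matrix of rate bounds (rows lower/upper, columns E,
#'   I1, I2).
#' @return list with `nu_in`, `rho_u` (the selected point) and `scan`
#'   (data.frame of all points and rates).
#' @export
tune_active_inputs <- function(circuit, nu_grid, rho_grid, delta_t = 10,
                               duration = 2000, seeds = 1,
                               bounds = rbind(lower = c(0.5, 10, 3),
                                              upper = c(5, 25, 15))) {
  stopifnot(length(nu_grid) >= 1, length(rho_grid) >= 1)
  colnames(bounds) <- CLASSES
  cls <- neuron_classes(circuit)
  rows <- list()
  best <- NULL
  for (nu in nu_grid) for (rho in rho_grid) {
    rates <- c(E = 0, I1 = 0, I2 = 0)
    for (s in seeds) {
      sig <- make_input_signal(ceiling(duration / delta_t), delta_t, rho,
                               seed = s + 31L)
      res <- simulate_circuit(circuit,
        stimulus_program(nu_in = nu, u = sig$u, delta_t = delta_t,
                         rho_u = rho),
        duration = duration, seed = s, record = character(0))
      for (k in CLASSES) {
        ids <- which(cls == k)
        rates[k] <- rates[k] +
          sum(res$spikes$id %in% ids) / length(ids) / (duration / 1000)
      }
    }
    rates <- rates / length(seeds)
    ok <- all(rates >= bounds["lower", ] & rates <= bounds["upper", ])
    rows[[length(rows) + 1]] <- data.frame(nu_in = nu, rho_u = rho,
      rate_E = rates["E"], rate_I1 = rates["I1"], rate_I2 = rates["I2"],
      admissible = ok, row.names = NULL)
    if (ok && is.null(best)) best <- list(nu_in = nu, rho_u = rho)
  }
  scan <- do.call(rbind, rows)
  if (is.null(best)) {
    miss <- scan[order(pmax(0, bounds["lower", 1] - scan$rate_E) +
                         pmax(0, scan$rate_E - bounds["upper", 1])), ]
    stop("no admissible (nu_in, rho_u) point; nearest misses:\n",
         paste(utils::capture.output(print(head(miss, 3))), collapse = "\n"))
  }
  c(best, list(scan = scan, bounds = bounds))
}

#' Weight-shuffling control schemes
#'
#' Permutes the synaptic weights of the circuit, preserving the weight
#' multiset exactly, so that the largest values occupy a designated
#' connection set: among the input-driven E neurons (`Shuffled_1`), from
#' the input-driven neurons to all E neurons (`Shuffled_2`), or from the
#' input-driven neurons to all neurons (`Shuffled_3`). The shuffling pool
#' is the E->E block for schemes 1-2 and all E-originating blocks for
#' scheme 3; orders inside and outside the designated set are randomized.
#'
#' @param circuit a `microcircuit` (weights should be heterogeneous for
#'   the control to be meaningful).
#' @param scheme `"none"`, `"Shuffled_1"`, `"Shuffled_2"`, `"Shuffled_3"`.
#' @param targets input-population indices (E population, 1-based).
#' @param seed integer seed for the randomized orders.
#' @return the circuit with permuted weights.
#' @export
apply_shuffle <- function(circuit, scheme = c("none", "Shuffled_1",
                                              "Shuffled_2", "Shuffled_3"),
                          targets, seed = 1) {
  scheme <- match.arg(scheme)
  if (scheme == "none") return(circuit)
  set.seed(seed)
  pool_blocks <- if (scheme == "Shuffled_3")
    which(vapply(circuit$blocks, function(b) b$pre_class == "E", logical(1)))
  else which(names(circuit$blocks) == "E->E")
  w <- unlist(lapply(circuit$blocks[pool_blocks], `[[`, "weights"))
  in_set <- unlist(lapply(circuit$blocks[pool_blocks], function(b) {
    pre_in <- b$pre %in% targets
    switch(scheme,
      Shuffled_1 = pre_in & b$post_class == "E" & b$post %in% targets,
      Shuffled_2 = pre_in & b$post_class == "E",
      Shuffled_3 = pre_in)
  }))
  n_in <- sum(in_set)
  ord <- order(w, decreasing = TRUE)
  top <- ord[seq_len(n_in)]
  rest <- if (n_in < length(w)) ord[(n_in + 1):length(w)] else integer(0)
  new_w <- numeric(length(w))
  new_w[which(in_set)[sample.int(n_in)]] <- w[top]
  if (length(rest))
    new_w[which(!in_set)[sample.int(length(rest))]] <- w[rest]
  # write back per block
  pos <- 0
  for (bi in pool_blocks) {
    nb <- length(circuit$blocks[[bi]]$weights)
    circuit$blocks[[bi]]$weights <- new_w[pos + seq_len(nb)]
    pos <- pos + nb
  }
  circuit
}

#' Run a configured experiment end-to-end
#'
#' Builds the circuit, runs the quiet- and/or active-state simulation,
#' computes the requested profiles and (optionally) the memory capacity,
#' and writes plain-text outputs (spike table, JSON profiles, manifest)
#' to `out_dir`.
#'
#' @param config list with elements `condition`, `N`, `state` ("quiet" or
#'   "active"), `nu_in`, `rho_u`, `delta_t`, `duration` (ms, quiet) or
#'   `T_steps` (input steps, active), `k_max`, `seed`, and `out_dir`.
#' @return (invisibly) a list with the in-memory results.
#' @export
run_experiment <- function(config) {
  defaults <- list(condition = "Hom", N = 250, state = "quiet", nu_in = 10,
                   rho_u = 0, delta_t = 20, duration = 2000, T_steps = NULL,
                   k_max = 20, seed = 1, out_dir = tempfile("hetmicro_run_"))
  config <- utils::modifyList(defaults, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  circuit <- build_microcircuit(config$N, config$condition,
                                seed = config$seed)
  cls <- neuron_classes(circuit)
  out <- list(config = config)
  if (identical(config$state, "quiet")) {
    res <- simulate_circuit(circuit, stimulus_program(nu_in = config$nu_in),
                            duration = config$duration, seed = config$seed,
                            record = c("V", "currents"))
    prof <- lapply(stats::setNames(CLASSES, CLASSES), function(k)
      spike_statistics(res$spikes, which(cls == k),
                       window = c(0, config$duration), seed = config$seed))
    bal <- ei_balance(res)
    out$profiles <- prof
    out$balance <- bal
    summary <- list(
      rates = lapply(prof, `[[`, "rate"),
      fraction_active = lapply(prof, `[[`, "fraction_active"),
      ei_cc = bal$CC,
      mean_V = lapply(stats::setNames(CLASSES, CLASSES), function(k)
        mean(res$V[cls[res$record_v_idx] == k, ])))
  } else {
    T_steps <- config$T_steps %||% 2000
    hv <- harvest_states(circuit, T_steps, config$delta_t, config$rho_u,
                         nu_in = config$nu_in, seed = config$seed)
    mem <- memory_capacity(hv$X, hv$u, k_max = config$k_max)
    out$memory <- mem
    res <- NULL
    summary <- list(C_M = mem$C_M, threshold = mem$threshold)
  }
  # plain-text outputs
  if (!is.null(res))
    write.table(res$spikes, file.path(config$out_dir, "spikes.txt"),
                row.names = FALSE, quote = FALSE, sep = "\t")
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(config = config[setdiff(names(config), "out_dir")],
                   package_version = as.character(utils::packageVersion("hetmicro")),
                   r_version = R.version.string,
                   wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$summary <- summary
  invisible(out)
}
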