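# Microcircuit assembly and simulation.

CLASSES <- c("E", "I1", "I2")

derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  sample.int(2147483646L, n)
}

#' Population sizes for a circuit of N neurons
#'
#' 80% excitatory; the inhibitory 20% split 35%/65% into fast-spiking (I1)
#' and non-fast-spiking (I2) interneurons. Rounding uses the
#' largest-remainder rule so the sizes always sum to `N`.
#'
#' @param N total number of neurons.
#' @return named integer vector `c(E=, I1=, I2=)`.
#' @export
population_sizes <- function(N) {
  frac <- c(E = 0.8, I1 = 0.2 * 0.35, I2 = 0.2 * 0.65)
  raw <- frac * N
  base <- floor(raw)
  rem <- N - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(frac))
}

condition_flags <- function(condition) {
  condition <- match.arg(condition, c("Hom", "Str", "Neu", "Syn", "Het"))
  list(neuronal = condition %in% c("Neu", "Het"),
       synaptic = condition %in% c("Syn", "Het"),
       structural = condition %in% c("Str", "Het"))
}

#' Build a microcircuit for a heterogeneity condition
#'
#' Assembles the three neuron populations and the nine connection blocks.
#' The condition toggles the three heterogeneity sources: `Hom` (all
#' homogeneous), `Neu` (distributed neuron parameters), `Syn` (lognormal
#' weights/delays), `Str` (skewed degrees), `Het` (all three; weight
#' correlations are applied only in this combined case, i.e. when
#' structural and synaptic heterogeneity are both active).
#'
#' Component generators draw from independent sub-seeds derived from the
#' master seed, so circuits for different conditions under the same master
#' seed share every component their flags leave untouched (e.g. `Hom` and
#' `Str` differ only in adjacency).
#'
#' @param N total neuron count (default 2500).
#' @param condition one of `"Hom"`, `"Str"`, `"Neu"`, `"Syn"`, `"Het"`.
#' @param seed master integer seed.
#' @param tau_w adaptation time constant (ms).
#' @param resolution simulation resolution (ms), used to round delays.
#' @return a `microcircuit` object.
#' @export
build_microcircuit <- function(N = 2500, condition = "Hom", seed = 1,
                               tau_w = 90, resolution = 0.1) {
  flags <- condition_flags(condition)
  sizes <- population_sizes(N)
  if (any(sizes == 0)) stop("N too small: every population must be nonempty")
  sd <- derive_seeds(seed, 4)
  pops <- lapply(seq_along(CLASSES), function(k)
    sample_population(neuron_class_spec(CLASSES[k], tau_w = tau_w),
                      sizes[k], heterogeneous = flags$neuronal,
                      seed = sd[1] %% 100000L * 10L + k))
  names(pops) <- CLASSES
  ctab <- connection_params()
  blocks <- vector("list", nrow(ctab))
  for (b in seq_len(nrow(ctab))) {
    row <- ctab[b, ]
    n_pre <- sizes[[row$pre]]; n_post <- sizes[[row$post]]
    same <- row$pre == row$post
    s_struct <- sd[2] %% 100000L * 100L + b
    s_syn <- sd[3] %% 100000L * 100L + b
    s_corr <- sd[4] %% 100000L * 100L + b
    skew <- flags$structural && (row$k_in > 0 || row$k_out > 0)
    blk <- if (skew)
      build_block_skewed(n_pre, n_post, row$p, k_out = row$k_out,
                         k_in = row$k_in, same_pop = same, seed = s_struct,
                         pre_class = row$pre, post_class = row$post)
    else
      build_block_uniform(n_pre, n_post, row$p, same_pop = same,
                          seed = s_struct, pre_class = row$pre,
                          post_class = row$post)
    wd <- sample_weights_delays(row, length(blk$pre),
                                heterogeneous = flags$synaptic,
                                seed = s_syn, resolution = resolution)
    blk$weights <- wd$weights
    blk$delays <- wd$delays
    if (flags$structural && flags$synaptic && (row$c_in > 0 || row$c_out > 0))
      blk <- apply_weight_correlations(blk, row$c_in, row$c_out,
                                       n_pre = n_pre, n_post = n_post,
                                       seed = s_corr)
    blocks[[b]] <- blk
  }
  names(blocks) <- paste0(ctab$pre, "->", ctab$post)
  structure(list(N = as.integer(N), sizes = sizes, condition = condition,
                 flags = flags, populations = pops, blocks = blocks,
                 resolution = resolution, tau_w = tau_w, seed = seed),
            class = "microcircuit")
}

#' @export
print.microcircuit <- function(x, ...) {
  ne <- sum(vapply(x$blocks, function(b) length(b$pre), numeric(1)))
  cat(sprintf("<microcircuit> N = %d (E %d, I1 %d, I2 %d), condition %s, %d synapses\n",
              x$N, x$sizes["E"], x$sizes["I1"], x$sizes["I2"], x$condition, ne))
  invisible(x)
}

class_offsets <- function(sizes) {
  stats::setNames(c(0L, cumsum(sizes)[-3]), CLASSES)
}

#' Neuron class of each global index
#' @param circuit a `microcircuit`.
#' @return character vector length N.
#' @export
neuron_classes <- function(circuit) {
  rep(CLASSES, circuit$sizes)
}

# flatten per-population parameter arrays into the engine layout
circuit_arrays <- function(circuit) {
  pops <- circuit$populations
  grab <- function(f) unlist(lapply(pops, function(p) p$pars[[f]]), use.names = FALSE)
  npar <- cbind(E_leak = grab("E_leak"), V_thresh = grab("V_thresh"),
                V_reset = grab("V_reset"), g_leak = grab("g_leak"),
                C_m = grab("C_m"),
                a = unlist(lapply(pops, function(p) rep(p$a, p$n)),
                           use.names = FALSE),
                b = unlist(lapply(pops, function(p) rep(p$b, p$n)),
                           use.names = FALSE),
                tau_w = unlist(lapply(pops, function(p) rep(p$tau_w, p$n)),
                               use.names = FALSE))
  tref <- grab("t_ref")
  class_id <- rep(0:2, circuit$sizes)
  list(npar = npar, tref = tref, class_id = class_id)
}

receptor_engine_tables <- function(dt) {
  coef <- matrix(0, 12, 4); decay <- matrix(1, 12, 4)
  erev <- numeric(12); nmda <- logical(12)
  for (k in 1:3) {
    tab <- receptor_params(CLASSES[k])
    for (r in 1:4) {
      cmp <- receptor_components(tab[r, ])
      row <- (k - 1) * 4 + r
      coef[row, ] <- cmp$coef * tab$g_bar[r]
      decay[row, ] <- exp(-dt / cmp$tau)
      erev[row] <- tab$E_rev[r]
      nmda[row] <- tab$voltage_gated[r]
    }
  }
  list(coef = coef, decay = decay, erev = erev, nmda = nmda)
}

edges_csr <- function(circuit, dt) {
  off <- class_offsets(circuit$sizes)
  pre <- integer(0); post <- integer(0); w <- numeric(0); d <- numeric(0)
  for (blk in circuit$blocks) {
    pre <- c(pre, blk$pre + off[[blk$pre_class]])
    post <- c(post, blk$post + off[[blk$post_class]])
    w <- c(w, blk$weights); d <- c(d, blk$delays)
  }
  ord <- order(pre)
  pre <- pre[ord]; post <- post[ord]; w <- w[ord]; d <- d[ord]
  if (any(d < dt - 1e-9)) stop("synaptic delay below simulation resolution")
  ptr <- c(0L, cumsum(tabulate(pre, nbins = circuit$N)))
  list(ptr = as.integer(ptr), post = as.integer(post - 1L), w = w,
       delay = as.integer(round(d / dt)))
}

#' Stimulus program
#'
#' Bundles the background drive and the (optional) piecewise-constant
#' injected current signal. Background: independent Poisson bombardment at
#' rate `K_in * nu_in` per neuron, delivered through an excitatory synapse
#' with the class mean E-weight. Signal: `u[n]` in `[0, 1]`, held for
#' `delta_t` ms, scaled by `rho_u` (pA) and injected into a random subset
#' (`target_fraction`) of the E population.
#'
#' @param nu_in background rate per source (spikes/s).
#' @param K_in effective number of background synapses per neuron.
#' @param u numeric input sequence in `[0,1]` (or `NULL` for none).
#' @param delta_t input step (ms); must be a multiple of the resolution.
#' @param rho_u current scale (pA).
#' @param target_fraction fraction of E neurons receiving the current.
#' @param targets explicit E-population indices (1-based, global), or
#'   `NULL` to sample them from the simulation seed.
#' @return a `stimulus_program` list.
#' @export
stimulus_program <- function(nu_in = 10, K_in = 1000, u = NULL,
                             delta_t = NULL, rho_u = 0,
                             target_fraction = 0.25, targets = NULL) {
  stopifnot(nu_in >= 0, K_in >= 0)
  if (!is.null(u)) {
    stopifnot(all(u >= 0 & u <= 1), !is.null(delta_t), delta_t > 0)
  }
  structure(list(nu_in = nu_in, K_in = K_in, u = u, delta_t = delta_t,
                 rho_u = rho_u, target_fraction = target_fraction,
                 targets = targets),
            class = "stimulus_program")
}

#' Initial neuron states
#'
#' `rest`: membrane at the leak reversal, adaptation at zero. `random`:
#' membrane uniform between each neuron's `E_leak` and `V_thresh`.
#'
#' @param circuit a `microcircuit`.
#' @param mode `"rest"` or `"random"`.
#' @param seed optional integer seed.
#' @return list with numeric vectors `V` and `I_adapt` of length N.
#' @export
initialize_states <- function(circuit, mode = c("rest", "random"),
                              seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  arr <- circuit_arrays(circuit)
  EL <- arr$npar[, "E_leak"]; Vth <- arr$npar[, "V_thresh"]
  V <- if (mode == "rest") EL else runif(circuit$N, EL, Vth)
  list(V = V, I_adapt = numeric(circuit$N))
}

#' Simulate a microcircuit
#'
#' Advances the coupled dynamics on a fixed 0.1 ms grid: RK4 for membrane
#' potential and adaptation current with receptor conductances (and NMDA
#' gating) held per step, exact exponential decay of the receptor state
#' variables, delayed spike delivery, per-neuron Poisson background and
#' piecewise-constant current injection. All randomness (background,
#' initial states, input-target choice) flows from `seed`.
#'
#' @param circuit a `microcircuit`.
#' @param program a [stimulus_program()].
#' @param duration simulated time (ms).
#' @param seed integer seed.
#' @param init `"rest"`, `"random"`, or a list with `V` and `I_adapt`.
#' @param record character subset of `c("V", "currents", "gtot")`.
#' @param record_every trace sampling interval (ms).
#' @param record_v_idx,record_c_idx global neuron indices (1-based) for the
#'   voltage and current/conductance traces; defaults: all neurons for V,
#'   the E population for currents.
#' @param ext_spikes optional data.frame (`time`, `neuron`, `weight`,
#'   `polarity`) of forced synaptic events delivered to the listed neurons.
#' @return a `simulation_result` list: `spikes` (data.frame time/id),
#'   traces (`V`, `I_exc`, `I_inh`, `G_total`; neurons x samples),
#'   `trace_times`, `u`, bookkeeping fields.
#' @export
simulate_circuit <- function(circuit, program = stimulus_program(),
                             duration = 1000, seed = 1, init = "rest",
                             record = c("V", "currents"),
                             record_every = 1,
                             record_v_idx = NULL, record_c_idx = NULL,
                             ext_spikes = NULL) {
  stopifnot(inherits(circuit, "microcircuit"), duration > 0)
  dt <- circuit$resolution
  n_steps <- round(duration / dt)
  set.seed(seed)
  # target subset for current injection (drawn before any other use of RNG)
  targets <- program$targets
  if (is.null(targets) && !is.null(program$u) && program$rho_u != 0) {
    ne <- circuit$sizes[["E"]]
    targets <- sort(sample.int(ne, round(program$target_fraction * ne)))
  }
  st <- if (is.list(init)) init else {
    initialize_states(circuit, init)  # uses the RNG stream seeded above
  }
  arr <- circuit_arrays(circuit)
  rt <- receptor_engine_tables(dt)
  csr <- edges_csr(circuit, dt)
  cls <- neuron_classes(circuit)
  mu_wE <- stats::setNames(connection_params()$mu_w[1:3],
                           connection_params()$post[1:3])
  bg_lambda <- rep(program$K_in * program$nu_in * dt / 1000, circuit$N)
  bg_w <- unname(mu_wE[cls])
  u <- program$u %||% numeric(0)
  u_steps <- if (length(u)) {
    us <- program$delta_t / dt
    if (abs(us - round(us)) > 1e-9)
      stop("delta_t must be a multiple of the resolution")
    as.integer(round(us))
  } else 0L
  if (is.null(ext_spikes))
    ext_spikes <- data.frame(time = numeric(0), neuron = integer(0),
                             weight = numeric(0), polarity = character(0))
  ext_ord <- order(ext_spikes$time)
  ext_spikes <- ext_spikes[ext_ord, , drop = FALSE]
  rec_every_steps <- if (is.null(record_every)) 0L else {
    res <- record_every / dt
    as.integer(round(res))
  }
  if (is.null(record_v_idx)) record_v_idx <- seq_len(circuit$N)
  if (is.null(record_c_idx))
    record_c_idx <- which(cls == "E")
  want <- function(x) x %in% record
  out <- engine_run(
    npar = arr$npar, tref_steps = as.integer(ceiling(arr$tref / dt - 1e-9)),
    class_id = as.integer(arr$class_id),
    pre_exc = cls == "E",
    rec_coef = rt$coef, rec_decay = rt$decay, rec_erev = rt$erev,
    rec_nmda = rt$nmda,
    ptr = csr$ptr, epost = csr$post, ew = csr$w, edelay = csr$delay,
    bg_lambda = bg_lambda, bg_w = bg_w,
    I_const = numeric(circuit$N),
    u = as.numeric(u), rho_u = program$rho_u, u_steps = u_steps,
    targets = as.integer((targets %||% integer(0)) - 1L),
    ext_step = as.integer(round(ext_spikes$time / dt)),
    ext_target = as.integer(ext_spikes$neuron - 1L),
    ext_w = as.numeric(ext_spikes$weight),
    ext_exc = ext_spikes$polarity == "exc",
    n_steps = n_steps, dt = dt, mg = 1,
    V0 = st$V, W0 = st$I_adapt,
    rec_every = if (length(record)) rec_every_steps else 0L,
    rec_v_idx = if (want("V")) as.integer(record_v_idx - 1L) else integer(0),
    rec_c_idx = if (want("currents") || want("gtot"))
      as.integer(record_c_idx - 1L) else integer(0),
    record_currents = want("currents"), record_gtot = want("gtot"))
  n_samp <- if (rec_every_steps > 0) n_steps %/% rec_every_steps else 0
  structure(list(
    spikes = data.frame(time = out$spike_times, id = out$spike_ids),
    V = if (want("V")) out$V else NULL,
    I_exc = if (want("currents")) out$I_exc else NULL,
    I_inh = if (want("currents")) out$I_inh else NULL,
    G_total = if (want("gtot")) out$G_total else NULL,
    trace_times = if (n_samp > 0) seq_len(n_samp) * rec_every_steps * dt
                  else numeric(0),
    record_v_idx = record_v_idx, record_c_idx = record_c_idx,
    classes = cls, u = u, targets = targets, duration = duration,
    resolution = dt, seed = seed, condition = circuit$condition,
    final_V = out$final_V, final_I_adapt = out$final_W),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %s, %.0f ms, %d spikes from %d neurons\n",
              x$condition, x$duration, nrow(x$spikes),
              length(unique(x$spikes$id))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-neuron simulation used by fi_curve and psp_response
simulate_single <- function(params, I_const = 0, duration = 1000, dt = 0.1,
                            V0 = NULL, I_adapt0 = 0, ext_spikes = NULL,
                            record_every = 10, class_label = NULL) {
  cls_id <- if (is.null(class_label)) 0L
            else match(class_label, CLASSES) - 1L
  npar <- cbind(params$E_leak, params$V_thresh, params$V_reset,
                params$g_leak, params$C_m, params$a, params$b, params$tau_w)
  rt <- receptor_engine_tables(dt)
  if (is.null(ext_spikes))
    ext_spikes <- data.frame(time = numeric(0), weight = numeric(0),
                             polarity = character(0))
  out <- engine_run(
    npar = npar, tref_steps = as.integer(ceiling(params$t_ref / dt - 1e-9)),
    class_id = cls_id, pre_exc = TRUE,
    rec_coef = rt$coef, rec_decay = rt$decay, rec_erev = rt$erev,
    rec_nmda = rt$nmda,
    ptr = c(0L, 0L), epost = integer(0), ew = numeric(0),
    edelay = integer(0),
    bg_lambda = 0, bg_w = 0, I_const = I_const,
    u = numeric(0), rho_u = 0, u_steps = 0L, targets = integer(0),
    ext_step = as.integer(round(ext_spikes$time / dt)),
    ext_target = rep(0L, nrow(ext_spikes)),
    ext_w = as.numeric(ext_spikes$weight),
    ext_exc = ext_spikes$polarity == "exc",
    n_steps = as.integer(round(duration / dt)), dt = dt, mg = 1,
    V0 = V0 %||% params$E_leak, W0 = I_adapt0,
    rec_every = as.integer(record_every),
    rec_v_idx = 0L, rec_c_idx = integer(0),
    record_currents = FALSE, record_gtot = FALSE)
  n_samp <- as.integer(round(duration / dt)) %/% as.integer(record_every)
  list(spike_times = out$spike_times, V = as.numeric(out$V),
       trace_times = seq_len(n_samp) * record_every * dt)
}

#' Poisson background event counts
#'
#' Per-neuron event counts per time step for the collapsed background
#' bombardment (mean `K_in * nu_in * dt / 1000` per step). Intended for
#' small diagnostic cases; the simulation engine draws the identical
#' process internally.
#'
#' @param nu_in per-source rate (spikes/s).
#' @param K_in number of collapsed sources per neuron.
#' @param n_neurons,duration,dt dimensions (ms).
#' @param seed optional integer seed.
#' @return integer matrix, `n_steps` rows x `n_neurons` columns.
#' @export
make_background <- function(nu_in, K_in, n_neurons, duration, dt = 0.1,
                            seed = NULL) {
  stopifnot(nu_in >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- round(duration / dt)
  matrix(rpois(n_steps * n_neurons, K_in * nu_in * dt / 1000),
         nrow = n_steps)
}

#' Piecewise-constant uniform input signal
#'
#' `u[n] ~ U[0, 1]` i.i.d., each value held for `delta_t` ms and scaled by
#' `rho_u`.
#'
#' @param T_steps number of input steps.
#' @param delta_t step duration (ms).
#' @param rho_u current scale (pA).
#' @param seed optional integer seed.
#' @param resolution grid (ms) for the expanded current trace.
#' @return list with `u` (length `T_steps`), `current` (trace on the
#'   grid), `delta_t`, `rho_u`.
#' @export
make_input_signal <- function(T_steps, delta_t, rho_u, seed = NULL,
                              resolution = 0.1) {
  stopifnot(T_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- runif(T_steps)
  list(u = u, current = rep(rho_u * u, each = round(delta_t / resolution)),
       delta_t = delta_t, rho_u = rho_u)
}
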