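# Receptor conductance kinetics, PSP characterization and sampling of
# per-connection weights and delays.

#' NMDA magnesium-block gating factor
#'
#' Voltage dependence of the NMDA receptor conductance:
#' \deqn{n(V) = (1 + ([Mg^{2+}]/3.57) e^{-0.062 V})^{-1}}
#' Strictly increasing in `V`; approaches 0 for strongly hyperpolarized
#' membranes (full block) and 1 for depolarized ones.
#'
#' @param V membrane potential (mV).
#' @param Mg_conc magnesium concentration (mM), default 1.
#' @return gating factor in (0, 1).
#' @export
nmda_gating <- function(V, Mg_conc = 1) {
  1 / (1 + (Mg_conc / 3.57) * exp(-0.062 * V))
}

# decompose the single-spike waveform into exponentially decaying
# components: shape(t) = sum coef_i * exp(-t/tau_i) for t > 0, with a jump
# of sum(coef) = 0 at t = 0 (continuous rise from zero).
receptor_components <- function(rec) {
  r <- rec$r
  tf <- if (is.na(rec$tau_decay_fast)) 1 else rec$tau_decay_fast
  ts <- if (is.na(rec$tau_decay_slow)) 1 else rec$tau_decay_slow
  tr <- rec$tau_rise
  list(tau = c(tf, ts, 1 / (1 / tf + 1 / tr), 1 / (1 / ts + 1 / tr)),
       coef = c(r, 1 - r, -r, -(1 - r)))
}

#' Single-spike conductance transient
#'
#' Conductance elicited by one presynaptic event at `t = 0`:
#' \deqn{g(t) = \bar g\, n(V) [1-e^{-t/\tau_{rise}}]
#'       [r e^{-t/\tau_f} + (1-r) e^{-t/\tau_s}] \Theta(t)}
#' The waveform is used exactly as written: `g_bar` scales the transient,
#' whose realized peak is below `g_bar` because the rise gate has not
#' saturated when decay sets in. (An optional peak normalization is
#' provided for diagnostics; the circuit model does not use it, as the
#' reference PSP amplitudes are only reproduced by the raw waveform.)
#'
#' @param rec one row of [receptor_params()] (data.frame or list).
#' @param t time since the event (ms); vectorized.
#' @param V membrane potential (mV), used only for NMDA gating.
#' @param Mg_conc magnesium concentration (mM).
#' @param normalize if `TRUE`, rescale so the single-spike peak equals
#'   `g_bar` exactly.
#' @return conductance in nS, 0 for `t <= 0`.
#' @export
conductance_waveform <- function(rec, t, V = -65, Mg_conc = 1,
                                 normalize = FALSE) {
  cmp <- receptor_components(rec)
  g <- numeric(length(t))
  p <- t > 0
  if (any(p)) {
    m <- exp(-outer(t[p], 1 / cmp$tau))
    g[p] <- as.vector(m %*% cmp$coef)
  }
  if (normalize) g <- g / waveform_peak(rec)
  gate <- if (isTRUE(rec$voltage_gated)) nmda_gating(V, Mg_conc) else 1
  rec$g_bar * gate * g
}

# peak of the unnormalized shape (numeric maximization)
waveform_peak <- function(rec) {
  cmp <- receptor_components(rec)
  f <- function(t) -as.vector(exp(-outer(t, 1 / cmp$tau)) %*% cmp$coef)
  tmax <- 10 * max(cmp$tau)
  -optimize(f, c(1e-6, tmax), tol = 1e-10)$objective
}

#' Initialize / update / drive a bank of receptor states
#'
#' Reference implementation of the exponential state-variable realization
#' of the receptor kinetics: each receptor's conductance is a linear
#' combination of exponentially decaying components, so that summing
#' spike-triggered jumps reproduces the superposition of single-spike
#' waveforms exactly (up to floating point). The compiled simulation
#' engine implements the same scheme; this R version backs the unit tests.
#'
#' @param receptors data.frame from [receptor_params()].
#' @return for `receptor_states_init`, a state object; the other two
#'   return the updated state object.
#' @export
receptor_states_init <- function(receptors) {
  comps <- lapply(seq_len(nrow(receptors)), function(i)
    receptor_components(receptors[i, ]))
  structure(list(receptors = receptors, comps = comps,
                 x = lapply(comps, function(cmp) numeric(length(cmp$tau)))),
            class = "receptor_states")
}

#' @rdname receptor_states_init
#' @param states a `receptor_states` object.
#' @param dt time step (ms); components decay exactly by `exp(-dt/tau)`.
#' @export
update_receptor_states <- function(states, dt) {
  for (i in seq_along(states$x))
    states$x[[i]] <- states$x[[i]] * exp(-dt / states$comps[[i]]$tau)
  states
}

#' @rdname receptor_states_init
#' @param receptor receptor name (`"AMPA"`, `"NMDA"`, `"GABA_A"`,
#'   `"GABA_B"`).
#' @param weight synaptic weight multiplying the jump.
#' @export
deliver_spike <- function(states, receptor, weight = 1) {
  i <- match(receptor, states$receptors$receptor)
  if (is.na(i)) stop("unknown receptor: ", receptor)
  states$x[[i]] <- states$x[[i]] + weight * states$comps[[i]]$coef
  states
}

#' Receptor conductances from a state bank
#'
#' @param states a `receptor_states` object.
#' @param V membrane potential (for NMDA gating).
#' @param Mg_conc magnesium concentration (mM).
#' @return named vector of conductances (nS), one per receptor.
#' @export
receptor_conductances <- function(states, V = -65, Mg_conc = 1) {
  g <- vapply(seq_along(states$x), function(i) {
    gi <- states$receptors$g_bar[i] * sum(states$x[[i]])
    if (states$receptors$voltage_gated[i]) gi <- gi * nmda_gating(V, Mg_conc)
    gi
  }, numeric(1))
  stats::setNames(g, states$receptors$receptor)
}

#' Fit a difference of exponentials to a PSP trace
#'
#' Fits `A (exp(-t/tau_decay) - exp(-t/tau_rise))` by nonlinear least
#' squares, initialized from the post-peak log-slope and the time to peak.
#'
#' @param t time since spike arrival (ms).
#' @param y voltage deflection (mV).
#' @return list with `J_syn` (signed trace peak), `tau_rise`, `tau_decay`,
#'   `residual` (RMS of fit residuals) and `ok` flag.
#' @export
fit_double_exp <- function(t, y) {
  ipk <- which.max(abs(y))
  pk <- y[ipk]
  out <- list(J_syn = pk, tau_rise = NA_real_, tau_decay = NA_real_,
              residual = NA_real_, ok = FALSE)
  if (abs(pk) < 1e-12 || ipk >= length(y) - 5) return(out)
  post <- seq(min(ipk + 2, length(y)), length(y))
  sl <- coef(lm(log(pmax(abs(y[post]), 1e-12)) ~ t[post]))[2]
  td0 <- if (is.finite(sl) && sl < 0) min(-1 / sl, 10 * max(t)) else max(t) / 3
  tr0 <- max(t[ipk] / 3, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (exp(-t / td) - exp(-t / tr)),
                      start = list(A = pk * 1.5, td = td0, tr = tr0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  cf <- coef(fit)
  tds <- sort(c(cf[["td"]], cf[["tr"]]))  # enforce rise < decay labelling
  list(J_syn = pk, tau_rise = tds[1], tau_decay = tds[2],
       residual = sqrt(mean(stats::resid(fit)^2)), ok = TRUE)
}

#' Single-spike postsynaptic potential
#'
#' Simulates one postsynaptic neuron of the given class (homogeneous
#' parameters), delivers a single presynaptic spike through the receptor
#' set implied by the polarity, records the voltage deflection and fits a
#' difference of exponentials. Excitatory PSPs are recorded from rest by
#' default; inhibitory ones at a holding potential of -55 mV (maintained by
#' a constant bias current), matching the protocol under which the
#' reference amplitudes were obtained.
#'
#' @param post postsynaptic class.
#' @param polarity `"exc"` or `"inh"`.
#' @param holding numeric holding potential (mV) or `"rest"`. Default:
#'   `"rest"` for excitatory, -55 for inhibitory.
#' @param weight synaptic weight (1 = the receptor-table reference PSP).
#' @param tau_w adaptation time constant (ms).
#' @param dt resolution (ms).
#' @param duration recording window after spike arrival (ms).
#' @return list with the fields of [fit_double_exp()] plus `t` (ms since
#'   arrival) and `deflection` (mV).
#' @export
psp_response <- function(post = c("E", "I1", "I2"),
                         polarity = c("exc", "inh"),
                         holding = NULL, weight = 1, tau_w = 90,
                         dt = 0.1, duration = 300) {
  post <- match.arg(post); polarity <- match.arg(polarity)
  if (is.null(holding)) holding <- if (polarity == "exc") "rest" else -55
  spec <- neuron_class_spec(post, tau_w = tau_w)
  params <- hom_params(spec)
  V0 <- if (identical(holding, "rest")) params$E_leak else holding
  bias <- (params$g_leak + params$a) * (V0 - params$E_leak)
  t_arr <- 10
  res <- simulate_single(params, I_const = bias,
                         duration = t_arr + duration, dt = dt,
                         V0 = V0, I_adapt0 = params$a * (V0 - params$E_leak),
                         ext_spikes = data.frame(time = t_arr,
                                                 weight = weight,
                                                 polarity = polarity),
                         record_every = 1, class_label = post)
  tt <- res$trace_times - t_arr
  defl <- res$V - V0
  sel <- tt >= 0
  fit <- if (abs(weight) > 0) fit_double_exp(tt[sel], defl[sel])
         else list(J_syn = 0, tau_rise = NA_real_, tau_decay = NA_real_,
                   residual = 0, ok = FALSE)
  c(fit, list(t = tt[sel], deflection = defl[sel], holding = V0))
}

#' Sample synaptic weights and delays for one connection type
#'
#' Homogeneous mode: all weights equal `mu_w` and all delays equal `mu_d`
#' rounded to the simulation grid. Heterogeneous mode: independent
#' lognormal draws with distribution mean/sd taken from the connection
#' table; weights are positive by construction, delays are left-truncated
#' at 0.1 ms and rounded to the nearest multiple of the resolution.
#'
#' @param spec a [synapse_type_spec()] (or any list with `mu_w`, `sigma_w`,
#'   `mu_d`, `sigma_d`).
#' @param n_connections number of draws.
#' @param heterogeneous lognormal draws?
#' @param seed optional integer seed.
#' @param resolution simulation resolution (ms).
#' @return list with numeric vectors `weights` and `delays`.
#' @export
sample_weights_delays <- function(spec, n_connections, heterogeneous = FALSE,
                                  seed = NULL, resolution = 0.1) {
  stopifnot(n_connections >= 0)
  if (spec$mu_d < resolution)
    stop("mean delay below simulation resolution")
  if (!is.null(seed)) set.seed(seed)
  n <- n_connections
  if (!heterogeneous) {
    return(list(weights = rep(spec$mu_w, n),
                delays = rep(round(spec$mu_d / resolution) * resolution, n)))
  }
  lw <- lnorm_params(spec$mu_w, spec$sigma_w)
  ld <- lnorm_params(spec$mu_d, spec$sigma_d)
  w <- rlnorm(n, lw$meanlog, lw$sdlog)
  d <- rlnorm(n, ld$meanlog, ld$sdlog)
  d <- pmax(d, 0.1)
  d <- pmax(round(d / resolution) * resolution, resolution)
  list(weights = w, delays = d)
}
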