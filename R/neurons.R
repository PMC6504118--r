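# Neuron populations: adaptive leaky integrate-and-fire parameter sampling
# and single-neuron dynamics.

draw_param <- function(desc, n) {
  switch(desc$family,
    normal = rnorm(n, desc$mean, desc$sd),
    lognormal = {
      lp <- lnorm_params(desc$mean, desc$sd)
      rlnorm(n, lp$meanlog, lp$sdlog)
    },
    stop("unknown distribution family: ", desc$family))
}

#' Sample a neuron population
#'
#' In the homogeneous mode every neuron carries the representative scalar
#' parameter set of its class. In the heterogeneous mode each parameter is
#' drawn independently per neuron from its class-specific distribution.
#' `C_m` and `tau_m` are the sampled quantities and the leak conductance is
#' derived as `g_leak = C_m / tau_m`, so that the listed membrane
#' time-constant distribution is honoured. Draws violating
#' `V_reset < V_thresh` or positivity of `g_leak`, `C_m`, `t_ref` are
#' rejection-resampled.
#'
#' @param spec a [neuron_class_spec()].
#' @param n number of neurons (`n >= 0`).
#' @param heterogeneous draw parameters from distributions?
#' @param seed optional integer seed (local RNG state).
#' @param primary which pair of redundant membrane parameters is sampled:
#'   `"Cm_gleak"` (default) draws `C_m` and `g_leak` from their listed
#'   distributions (the model's native parameters; `tau_m` follows as
#'   `C_m/g_leak`), `"Cm_taum"` draws `C_m` and `tau_m` and derives
#'   `g_leak = C_m/tau_m`.
#' @return a `neuron_population` list with per-neuron parameter vectors.
#' @export
sample_population <- function(spec, n, heterogeneous = FALSE, seed = NULL,
                              primary = c("Cm_gleak", "Cm_taum")) {
  primary <- match.arg(primary)
  stopifnot(inherits(spec, "neuron_class_spec"))
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n))
    stop("n must be a nonnegative integer")
  if (!is.null(seed)) set.seed(seed)
  fields <- c("E_leak", "V_thresh", "V_reset", "g_leak", "C_m", "t_ref")
  if (n == 0) {
    pars <- stats::setNames(rep(list(numeric(0)), length(fields)), fields)
  } else if (!heterogeneous) {
    pars <- lapply(stats::setNames(fields, fields),
                   function(f) rep(spec$hom[[f]], n))
  } else {
    second <- if (primary == "Cm_gleak") "g_leak" else "tau_m"
    pars <- list(
      E_leak   = draw_param(spec$het$E_leak, n),
      V_thresh = draw_param(spec$het$V_thresh, n),
      V_reset  = draw_param(spec$het$V_reset, n),
      C_m      = draw_param(spec$het$C_m, n),
      t_ref    = draw_param(spec$het$t_ref, n))
    pars[[second]] <- draw_param(spec$het[[second]], n)
    # rejection resampling of invalid draws (paper states no truncation rule)
    for (it in 1:1000) {
      bad <- pars$V_reset >= pars$V_thresh
      if (!any(bad)) break
      pars$V_reset[bad] <- draw_param(spec$het$V_reset, sum(bad))
      pars$V_thresh[bad] <- draw_param(spec$het$V_thresh, sum(bad))
    }
    for (f in c("C_m", second, "t_ref")) {
      for (it in 1:1000) {
        bad <- pars[[f]] <= 0
        if (!any(bad)) break
        pars[[f]][bad] <- draw_param(spec$het[[f]], sum(bad))
      }
    }
    if (primary == "Cm_gleak") pars$tau_m <- pars$C_m / pars$g_leak
    else pars$g_leak <- pars$C_m / pars$tau_m
    pars <- pars[c(fields, "tau_m")]
  }
  structure(list(label = spec$label, n = as.integer(n), pars = pars,
                 a = spec$a, b = spec$b, tau_w = spec$tau_w,
                 heterogeneous = heterogeneous, seed = seed),
            class = "neuron_population")
}

#' @export
print.neuron_population <- function(x, ...) {
  cat(sprintf("<neuron_population> class %s, n = %d (%s)\n", x$label, x$n,
              if (x$heterogeneous) "heterogeneous" else "homogeneous"))
  invisible(x)
}

#' Membrane and adaptation-current derivatives
#'
#' Right-hand side of the adaptive leaky integrate-and-fire subthreshold
#' dynamics:
#' \deqn{C_m \dot V = -g_{leak}(V - E_{leak}) - I_{adapt} - I_{syn} + I_{inj}}
#' \deqn{\tau_w \dot I_{adapt} = -I_{adapt} + a (V - E_{leak})}
#' The spike-triggered increment `b` is applied instantaneously at spike
#' times by the integrator, not inside this derivative.
#'
#' @param V membrane potential (mV).
#' @param I_adapt adaptation current (pA).
#' @param params named list/vector with `C_m`, `g_leak`, `E_leak`, `a`,
#'   `tau_w`.
#' @param I_syn_total total synaptic current (pA, outward positive).
#' @param I_inj injected current (pA).
#' @return numeric vector `c(dV, dI_adapt)` in mV/ms and pA/ms.
#' @export
membrane_derivatives <- function(V, I_adapt, params, I_syn_total = 0,
                                 I_inj = 0) {
  dV <- (-params$g_leak * (V - params$E_leak) - I_adapt - I_syn_total +
           I_inj) / params$C_m
  dW <- (-I_adapt + params$a * (V - params$E_leak)) / params$tau_w
  c(dV = dV, dI_adapt = dW)
}

#' Rheobase current of the adaptive LIF neuron
#'
#' Closed form: with sub-threshold adaptation the fixed point under
#' constant current `I` is `V = E_leak + I/(g_leak + a)`, so the minimal
#' current reaching threshold is `(g_leak + a)(V_thresh - E_leak)`.
#'
#' @param params named list with `g_leak`, `a`, `V_thresh`, `E_leak`.
#' @return rheobase current in pA.
#' @export
rheobase <- function(params) {
  (params$g_leak + params$a) * (params$V_thresh - params$E_leak)
}

hom_params <- function(spec) {
  c(as.list(spec$hom), list(a = spec$a, b = spec$b, tau_w = spec$tau_w))
}

#' fI curve of a single neuron
#'
#' Simulates one neuron under constant current steps (default 1 s each,
#' from rest) and summarizes the rate-vs-current relation: rheobase (first
#' grid current with sustained firing), rate just above rheobase, rate at
#' the maximum grid current, and the least-squares slope of the
#' supra-threshold segment. Spikes during the initial `settle` window are
#' discarded: with slow adaptation a step from rest transiently overshoots
#' the adapted fixed point and can fire a few onset spikes below the
#' stationary rheobase `(g_leak + a)(V_thresh - E_leak)`.
#'
#' @param params named list of single-neuron parameters (`E_leak`,
#'   `V_thresh`, `V_reset`, `g_leak`, `C_m`, `t_ref`, `a`, `b`, `tau_w`).
#' @param I_grid currents to test (pA), sorted ascending.
#' @param duration step duration (ms), at least 1000.
#' @param dt integration resolution (ms).
#' @param settle onset window discarded from the rate (ms).
#' @return list with `I_rh`, `nu_min`, `nu_max`, `slope` (spikes/s/pA) and
#'   the full `rates` vector. If no grid current elicits a spike, `I_rh` is
#'   `Inf` and slope is `NA`.
#' @export
fi_curve <- function(params, I_grid, duration = 1000, dt = 0.1,
                     settle = 500) {
  stopifnot(duration >= 1000, !is.unsorted(I_grid), settle < duration)
  rates <- vapply(I_grid, function(I) {
    res <- simulate_single(params, I_const = I, duration = duration, dt = dt)
    sum(res$spike_times > settle) / ((duration - settle) / 1000)
  }, numeric(1))
  act <- which(rates > 0)
  if (!length(act))
    return(list(I_rh = Inf, nu_min = 0, nu_max = 0, slope = NA_real_,
                I_grid = I_grid, rates = rates))
  i0 <- act[1]
  supra <- seq(i0, length(I_grid))
  slope <- if (length(supra) >= 2)
    unname(coef(lm(rates[supra] ~ I_grid[supra]))[2]) else NA_real_
  list(I_rh = I_grid[i0], nu_min = rates[i0], nu_max = rates[length(rates)],
       slope = slope, I_grid = I_grid, rates = rates)
}

# one neuron, constant current, no synapses: spike count via the engine
single_neuron_spikes <- function(params, I, duration, dt = 0.1) {
  res <- simulate_single(params, I_const = I, duration = duration, dt = dt)
  length(res$spike_times)
}
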