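# Built-in physiological parameter sets for the three neuron classes,
# the four receptor types per postsynaptic class, and the nine connection
# types of the layer 2/3 microcircuit.

#' Single-neuron parameter table
#'
#' Physiological parameters for the three neuron classes: excitatory
#' pyramidal cells (`E`), fast-spiking interneurons (`I1`) and
#' non-fast-spiking interneurons (`I2`). Each parameter carries a
#' homogeneous (representative) value and a distribution descriptor
#' (`normal` or `lognormal`, parameterized by distribution mean and sd)
#' used when neuronal heterogeneity is switched on. Lognormal descriptors
#' are given as the mean/sd of the distribution itself, not the underlying
#' shape parameters (see [lnorm_params()]).
#'
#' Units: potentials mV, conductances nS, capacitance pF, times ms.
#' `a` (nS) and `b` (pA) are the sub-threshold and spike-triggered
#' adaptation couplings; `tau_w` (ms) is the adaptation time constant.
#'
#' @param label one of `"E"`, `"I1"`, `"I2"`.
#' @param tau_w adaptation time constant in ms. The default, 90 ms, is
#'   calibrated so that the single-spike excitatory PSP on an E neuron
#'   reproduces the reference amplitude/rise/decay triple (0.82 mV,
#'   3.16 ms, 17.8 ms); see the methods vignette.
#' @return a `neuron_class_spec` list with elements `label`, `hom` (named
#'   numeric vector), `het` (list of distribution descriptors), `a`, `b`,
#'   `tau_w`.
#' @export
neuron_class_spec <- function(label = c("E", "I1", "I2"), tau_w = 90) {
  label <- match.arg(label)
  hom <- switch(label,
    E  = c(E_leak = -76.43, V_thresh = -44.45, V_reset = -54.18,
           g_leak = 4.64, C_m = 116.52, t_ref = 2.05,
           tau_m = 25.11, R_m = 215.54),
    I1 = c(E_leak = -64.33, V_thresh = -38.97, V_reset = -57.47,
           g_leak = 9.75, C_m = 104.52, t_ref = 0.52,
           tau_m = 10.72, R_m = 102.53),
    I2 = c(E_leak = -61.00, V_thresh = -34.44, V_reset = -47.11,
           g_leak = 4.61, C_m = 102.87, t_ref = 1.34,
           tau_m = 22.33, R_m = 217.10))
  het <- switch(label,
    E = list(
      E_leak   = list(family = "normal",    mean = -73,    sd = 4),
      V_thresh = list(family = "normal",    mean = -42,    sd = 4),
      V_reset  = list(family = "normal",    mean = -52,    sd = 5),
      g_leak   = list(family = "normal",    mean = 4.73,   sd = 0.38),
      C_m      = list(family = "normal",    mean = 114,    sd = 8.7),
      t_ref    = list(family = "lognormal", mean = 1.8,    sd = 0.25),
      tau_m    = list(family = "lognormal", mean = 22,     sd = 2),
      R_m      = list(family = "lognormal", mean = 160,    sd = 50)),
    I1 = list(
      E_leak   = list(family = "normal",    mean = -67.5,  sd = 2),
      V_thresh = list(family = "normal",    mean = -40,    sd = 4),
      V_reset  = list(family = "normal",    mean = -58,    sd = 6.4),
      g_leak   = list(family = "normal",    mean = 9.09,   sd = 0.75),
      C_m      = list(family = "lognormal", mean = 68.9,   sd = 35.6),
      t_ref    = list(family = "lognormal", mean = 0.5,    sd = 0.01),
      tau_m    = list(family = "lognormal", mean = 9.5,    sd = 2),
      R_m      = list(family = "lognormal", mean = 100,    sd = 10)),
    I2 = list(
      E_leak   = list(family = "normal",    mean = -62.6,  sd = 2),
      V_thresh = list(family = "normal",    mean = -36,    sd = 2),
      V_reset  = list(family = "normal",    mean = -54,    sd = 5.4),
      g_leak   = list(family = "normal",    mean = 4.5,    sd = 0.2),
      C_m      = list(family = "lognormal", mean = 82.24,  sd = 17.7),
      t_ref    = list(family = "lognormal", mean = 1.3,    sd = 0.05),
      tau_m    = list(family = "lognormal", mean = 20,     sd = 2),
      R_m      = list(family = "lognormal", mean = 210,    sd = 10)))
  ab <- switch(label, E = c(4, 30), I1 = c(0, 0), I2 = c(2, 10))
  structure(list(label = label, hom = hom, het = het,
                 a = ab[1], b = ab[2], tau_w = tau_w),
            class = "neuron_class_spec")
}

#' Receptor kinetics table
#'
#' Conductance parameters of the four receptor types expressed by each
#' postsynaptic neuron class. An excitatory synapse onto a neuron activates
#' its AMPA and NMDA receptors; an inhibitory synapse activates GABA-A and
#' GABA-B. The single-spike conductance transient is
#' \deqn{g(t) = \bar g \, n(V)\, [1-e^{-t/\tau_{rise}}]
#'       [r e^{-t/\tau_f} + (1-r) e^{-t/\tau_s}]\,\Theta(t)}
#' where \eqn{n(V)} is 1 for all receptors except NMDA (magnesium block,
#' see [nmda_gating()]).
#'
#' @param post postsynaptic class, one of `"E"`, `"I1"`, `"I2"`.
#' @return data.frame with one row per receptor: `receptor`, `g_bar` (nS),
#'   `E_rev` (mV), `tau_rise`, `r`, `tau_decay_fast`, `tau_decay_slow` (ms),
#'   `voltage_gated`.
#' @export
receptor_params <- function(post = c("E", "I1", "I2")) {
  post <- match.arg(post)
  tab <- switch(post,
    E = data.frame(
      receptor = c("AMPA", "NMDA", "GABA_A", "GABA_B"),
      g_bar = c(0.9, 0.14, 0.15, 0.009),
      E_rev = c(0, 0, -75, -90),
      tau_rise = c(0.3, 1, 0.25, 30),
      r = c(1, 0, 1, 0.8),
      tau_decay_fast = c(2, NA, 6, 200),
      tau_decay_slow = c(NA, 100, NA, 600)),
    I1 = data.frame(
      receptor = c("AMPA", "NMDA", "GABA_A", "GABA_B"),
      g_bar = c(1.6, 0.003, 1, 0.022),
      E_rev = c(0, 0, -75, -90),
      tau_rise = c(0.1, 1, 0.1, 25),
      r = c(1, 0, 1, 0.8),
      tau_decay_fast = c(0.7, NA, 2.5, 50),
      tau_decay_slow = c(NA, 100, NA, 400)),
    I2 = data.frame(
      receptor = c("AMPA", "NMDA", "GABA_A", "GABA_B"),
      g_bar = c(0.8, 0.012, 0.7, 0.025),
      E_rev = c(0, 0, -75, -90),
      tau_rise = c(0.2, 1, 0.2, 25),
      r = c(1, 0, 1, 0.8),
      tau_decay_fast = c(1.8, NA, 5, 150),
      tau_decay_slow = c(NA, 100, NA, 500)))
  tab$voltage_gated <- tab$receptor == "NMDA"
  tab
}

#' Connection-type parameter table
#'
#' Connection density, weight/delay distribution parameters and structural
#' bias parameters for the nine synapse types. `p` is the connection
#' density; `mu_w`/`sigma_w` the (dimensionless) weight distribution
#' mean/sd; `mu_d`/`sigma_d` the delay distribution mean/sd in ms;
#' `k_in`/`k_out` the in/out-degree skewness parameters and
#' `c_in`/`c_out` the weight-correlation strengths (entries reported as
#' untested or without effect are 0).
#'
#' @return data.frame with one row per connection type (`pre`, `post`
#'   columns give the classes).
#' @export
connection_params <- function() {
  data.frame(
    pre   = c("E", "E", "E", "I1", "I2", "I1", "I1", "I2", "I2"),
    post  = c("E", "I1", "I2", "E", "E", "I1", "I2", "I1", "I2"),
    p     = c(0.168, 0.575, 0.244, 0.60, 0.465, 0.55, 0.241, 0.379, 0.381),
    mu_w  = c(0.45, 1.65, 0.638, 5.148, 4.85, 2.22, 1.4, 1.47, 0.83),
    sigma_w = c(0.10, 0.10, 0.11, 0.11, 0.11, 0.14, 0.25, 0.10, 0.2),
    mu_d  = c(1.8, 1.2, 1.5, 0.8, 1.5, 1, 1.2, 1.5, 1.5),
    sigma_d = c(0.25, 0.2, 0.2, 0.1, 0.2, 0.1, 0.3, 0.5, 0.3),
    k_in  = c(5, 5, 0, 0, 0, 0, 0, 0, 0),
    k_out = c(5, 0, 0, 0, 0, 0, 0, 0, 0),
    c_in  = c(1, 1, 1, 0, 0, 0, 0, 0, 0),
    c_out = c(0, 1, 0, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
}

#' Convert lognormal distribution mean/sd to shape parameters
#'
#' The parameter tables describe lognormal distributions by their mean `m`
#' and standard deviation `s` (on the natural scale). The underlying
#' parameters are \eqn{\mu = \ln(m^2/\sqrt{m^2+s^2})} and
#' \eqn{\sigma^2 = \ln(1+s^2/m^2)}.
#'
#' @param m,s distribution mean and sd (natural scale), `m > 0`, `s >= 0`.
#' @return list with `meanlog` and `sdlog`.
#' @export
lnorm_params <- function(m, s) {
  stopifnot(all(m > 0), all(s >= 0))
  list(meanlog = log(m^2 / sqrt(m^2 + s^2)),
       sdlog = sqrt(log(1 + (s / m)^2)))
}

#' Default synapse-type specification
#'
#' Bundles the connection-type row (density, weight/delay distributions,
#' structural bias) with the receptor set implied by the presynaptic class
#' (excitatory: AMPA+NMDA of the postsynaptic class; inhibitory:
#' GABA-A+GABA-B).
#'
#' @param pre,post pre- and postsynaptic classes.
#' @return a `synapse_type_spec` list.
#' @export
synapse_type_spec <- function(pre = c("E", "I1", "I2"),
                              post = c("E", "I1", "I2")) {
  pre <- match.arg(pre); post <- match.arg(post)
  tab <- connection_params()
  row <- tab[tab$pre == pre & tab$post == post, ]
  stopifnot(nrow(row) == 1)
  polarity <- if (pre == "E") "exc" else "inh"
  rec <- receptor_params(post)
  rec <- rec[rec$receptor %in%
               (if (polarity == "exc") c("AMPA", "NMDA")
                else c("GABA_A", "GABA_B")), ]
  structure(c(as.list(row), list(polarity = polarity, receptors = rec)),
            class = "synapse_type_spec")
}
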