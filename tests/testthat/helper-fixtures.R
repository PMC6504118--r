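# Shared fixtures: homogeneous parameter lists and tiny circuits.

class_hom_params <- function(label, tau_w = 90) {
  spec <- neuron_class_spec(label, tau_w = tau_w)
  c(as.list(spec$hom), list(a = spec$a, b = spec$b, tau_w = spec$tau_w))
}

tiny_circuit <- function(condition = "Hom", N = 100, seed = 1) {
  build_microcircuit(N, condition, seed = seed)
}

# analytic inter-spike interval of a plain LIF neuron under constant I
lif_isi <- function(p, I) {
  vinf <- p$E_leak + I / p$g_leak
  tau <- p$C_m / p$g_leak
  if (vinf <= p$V_thresh) return(Inf)
  p$t_ref + tau * log((vinf - p$V_reset) / (vinf - p$V_thresh))
}
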