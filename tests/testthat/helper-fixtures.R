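# shared fixtures: parameter sets used across the suite

# membrane/synaptic time constants of the neuron-level examples (ms)
p_neuron <- function(t_ref = 0)
  lif_params(tau_m = 10, tau_s = 4, sigma_V = 0.25, t_ref = t_ref)

# boundary-view process of the periodic-boundary examples:
# sigma_x(inf) = 0.5, tau_x = 1, tau_y = 0.2
p_boundary <- function() lif_params(tau_m = 1, tau_s = 0.2, sigma_V = 0.5)

# parameter set with gamma * tau_y = u at unit stationary sigma_x
p_ratio <- function(u) lif_params(tau_m = 1, tau_s = u, sigma_V = 1)
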