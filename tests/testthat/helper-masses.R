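# Shared fitted masses, computed once per test run (the full pipeline takes a
# few seconds per mass); unit tests that only need structure use the cheap
# synthetic fixtures from make_fixture_mass() instead.

.mass_cache <- new.env(parent = emptyenv())

get_wbm <- function() {
  if (is.null(.mass_cache$wbm))
    .mass_cache$wbm <- mnm_fit(wb_neuron(), dnuK_grid = seq(0, 20, by = 2))
  .mass_cache$wbm
}

get_sem <- function() {
  if (is.null(.mass_cache$sem))
    .mass_cache$sem <- mnm_fit(sean_neuron(), dnuK_grid = seq(0, 20, by = 2))
  .mass_cache$sem
}

# a made-up voltage trace with k rectangular spikes in the averaging window
synthetic_spike_trace <- function(n_spikes, duration = 1500, transient = 500,
                                  dt = 0.1) {
  t <- seq(0, duration, by = dt)
  V <- rep(-60, length(t))
  window <- duration - transient
  at <- transient + (seq_len(n_spikes) - 0.5) / n_spikes * window
  for (a in at) V[t >= a & t < a + 1] <- 20
  tr <- data.frame(time = t, V = V, n = 0.1, h = 0.5, kflux = -0.5)
  attr(tr, "I_inj") <- 0; attr(tr, "dnuK") <- 0
  tr
}
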