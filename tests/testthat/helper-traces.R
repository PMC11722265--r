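# Crafted waveforms with analytically known feature values.

# Triangular spikes rising/falling 2 mV per 0.025 ms sample (80 mV/ms) from a
# flat baseline. `thresh_times` gives the time of the last baseline sample of
# each spike (the detected AP threshold); `peaks` the apex voltages.
make_triangle_trace <- function(thresh_times, peaks, base = -70,
                                protocol = step_protocol(noise = FALSE)) {
  dt <- protocol$dt
  n <- round(protocol$duration / dt) + 1
  vm <- rep(base, n)
  for (s in seq_along(thresh_times)) {
    i0 <- round(thresh_times[s] / dt) + 1          # threshold sample
    k <- (peaks[s] - base) / 2                      # rise steps
    stopifnot(k == round(k))
    vm[i0 + seq_len(k)] <- base + 2 * seq_len(k)        # rise
    vm[i0 + k + seq_len(k)] <- peaks[s] - 2 * seq_len(k) # fall back to base
  }
  voltage_trace(seq(0, by = dt, length.out = n), vm, protocol)
}

# reference passive parameter set (all active conductances zero)
passive_params <- function(C = 1, Rinput = 100, tau = 10, Eleak = -70) {
  c(C = C, Rinput = Rinput, tau = tau, gNat = 0, gNa = 0, gKd = 0, gM = 0,
    gKv31 = 0, gL = 0, Eleak = Eleak, tau_max = 1000, VT = -60, rSS = 1)
}

# fast-spiking-like parameter set (high delayed-rectifier and Kv3.1)
fs_params <- function() {
  c(C = 1, Rinput = 180, tau = 10, gNat = 80, gNa = 40, gKd = 15, gM = 0.1,
    gKv31 = 100, gL = 0.1, Eleak = -75, tau_max = 1000, VT = -60, rSS = 1.5)
}
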