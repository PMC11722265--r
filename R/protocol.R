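#' Step-current stimulation protocol
#'
#' The experimental paradigm emulated throughout the package: a constant
#' current step injected into the soma, with small Gaussian current noise at
#' every time point modeling membrane voltage fluctuations.
#'
#' @param amplitude Step amplitude in pA (default 300).
#' @param onset,offset Stimulation onset/offset in ms (defaults 100 and 700).
#' @param duration Total simulated time in ms (default 800).
#' @param dt Integration/sampling step in ms (default 0.025).
#' @param temperature Bath temperature in degrees C (default 25).
#' @param t_ref Reference temperature of the gate kinetics (default 36).
#' @param q10 Temperature coefficient scaling gate kinetics by
#'   `q10^((temperature - t_ref)/10)` (default 2.3).
#' @param noise_mean,noise_sd Mean and SD (pA) of the per-step Gaussian noise
#'   current (defaults 10 and 1).
#' @param noise Logical; disable to obtain deterministic noise-free traces.
#' @param e_na,e_k,e_ca Fixed reversal potentials in mV.
#' @param v_guard Absolute voltage bound (mV) beyond which a simulation is
#'   flagged failed.
#' @return An object of class `stim_protocol`.
#' @export
step_protocol <- function(amplitude = 300, onset = 100, offset = 700,
                          duration = 800, dt = 0.025, temperature = 25,
                          t_ref = 36, q10 = 2.3, noise_mean = 10,
                          noise_sd = 1, noise = TRUE,
                          e_na = 50, e_k = -90, e_ca = 120,
                          v_guard = 1000) {
  if (!(0 <= onset && onset < offset && offset <= duration))
    stop("protocol requires 0 <= onset < offset <= duration")
  if (dt <= 0) stop("protocol requires dt > 0")
  structure(list(amplitude = amplitude, onset = onset, offset = offset,
                 duration = duration, dt = dt, temperature = temperature,
                 t_ref = t_ref, q10 = q10, noise_mean = noise_mean,
                 noise_sd = noise_sd, noise = noise, e_na = e_na, e_k = e_k,
                 e_ca = e_ca, v_guard = v_guard),
            class = "stim_protocol")
}

#' Temperature scaling factor of the gate kinetics
#' @param protocol A `stim_protocol`.
#' @return `q10^((temperature - t_ref)/10)`.
#' @export
q10_factor <- function(protocol) {
  protocol$q10^((protocol$temperature - protocol$t_ref) / 10)
}
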