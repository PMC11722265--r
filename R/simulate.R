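#' Membrane area reconciling the passive parameter triple
#'
#' Per-area conductances and capacitance are converted to absolute values
#' through the area `A = tau / (C * Rinput)` (in consistent units), which
#' makes the passive membrane time constant of the simulated compartment
#' equal `tau` while the total leak conductance equals `1/Rinput` exactly.
#'
#' @param params Named parameter vector (uses `C`, `Rinput`, `tau`).
#' @return Membrane area in cm2.
#' @examples
#' membrane_area(c(C = 1, Rinput = 100, tau = 10,
#'                 gNat = 0, gNa = 0, gKd = 0, gM = 0, gKv31 = 0, gL = 0,
#'                 Eleak = -70, tau_max = 1000, VT = -60, rSS = 1)) # 1e-4 cm2
#' @export
membrane_area <- function(params) {
  params <- as_param_vector(params)
  unname(params["tau"] / (params["C"] * params["Rinput"] * 1e3))
}

#' Voltage-dependent kinetics of the nine ion-channel gates
#'
#' Returns the steady state and effective time constant of every gate at a
#' fixed voltage, after temperature (Q10), rate-to-steady-state (rSS, for the
#' m/h gates of gNa and the n gate of gKd) and tau_max (p gate) scaling.
#' Scaling both opening and closing rates by a common factor divides the time
#' constant by that factor and leaves the steady state unchanged.
#'
#' @param V Membrane voltage in mV (finite scalar).
#' @param params Named parameter vector (uses `VT`, `tau_max`, `rSS`).
#' @param protocol A `stim_protocol` (temperature scaling).
#' @return Data frame with columns `gate`, `x_inf`, `tau_ms`.
#' @export
gate_rates <- function(V, params, protocol = step_protocol()) {
  stopifnot(is.finite(V))
  params <- as_param_vector(params)
  kk <- hh_gate_kinetics(V, params[["VT"]], params[["tau_max"]],
                         params[["rSS"]], q10_factor(protocol))
  data.frame(gate = c("m", "h", "m_hat", "h_hat", "n", "p", "v", "q", "r"),
             x_inf = kk[, 1], tau_ms = kk[, 2])
}

#' Simulate a batch of parameter vectors under a step protocol
#'
#' Integrates the single-compartment conductance-based model with fixed-step
#' exponential-Euler updates for all state variables. A simulation whose
#' voltage leaves the guard band (or turns non-finite) is flagged failed and
#' returned as an all-NA trace, not an error.
#'
#' @param theta Parameter matrix `n x 13` (columns [param_names()]) or a
#'   single named vector.
#' @param protocol A `stim_protocol`.
#' @param seed Optional integer seed for the noise current.
#' @return List with `time` (ms), `vm` (`n x n_time` matrix, mV) and logical
#'   `failed` (length n).
#' @export
simulate_batch <- function(theta, protocol = step_protocol(), seed = NULL) {
  theta <- as_param_matrix(theta)
  if (!is.null(seed)) set.seed(seed)
  res <- hh_integrate_batch(theta, protocol$dt, protocol$duration,
                            protocol$onset, protocol$offset,
                            protocol$amplitude, protocol$noise_mean,
                            protocol$noise_sd, isTRUE(protocol$noise),
                            protocol$temperature, protocol$t_ref,
                            protocol$q10, protocol$e_na, protocol$e_k,
                            protocol$e_ca, protocol$v_guard)
  n_steps <- round(protocol$duration / protocol$dt)
  list(time = seq(0, by = protocol$dt, length.out = n_steps + 1),
       vm = res$vm, failed = as.logical(res$failed))
}

#' Simulate a single neuron model
#'
#' @inheritParams simulate_batch
#' @param params Named parameter vector of length 13.
#' @return A `voltage_trace`: list with `time` (ms), `vm` (mV), `protocol`,
#'   `params` and logical `failed`.
#' @export
simulate_neuron <- function(params, protocol = step_protocol(), seed = NULL) {
  params <- validate_params(params)
  res <- simulate_batch(matrix(params, nrow = 1,
                               dimnames = list(NULL, param_names())),
                        protocol, seed)
  structure(list(time = res$time, vm = res$vm[1, ], protocol = protocol,
                 params = params, failed = res$failed[1]),
            class = "voltage_trace")
}

#' Coerce a (time, vm) pair into a voltage trace object
#'
#' For feature extraction of traces that did not come out of the simulator
#' (experimental recordings, crafted test waveforms). The grid must be
#' uniform.
#'
#' @param time Time grid in ms (uniform spacing).
#' @param vm Membrane voltage samples in mV.
#' @param protocol The `stim_protocol` the trace was recorded under.
#' @return A `voltage_trace`.
#' @export
voltage_trace <- function(time, vm, protocol = step_protocol()) {
  stopifnot(length(time) == length(vm), length(time) >= 2)
  dts <- diff(time)
  if (max(abs(dts - dts[1])) > 1e-9)
    stop("voltage_trace requires a uniform time grid")
  structure(list(time = time, vm = vm, protocol = protocol, params = NULL,
                 failed = any(!is.finite(vm))),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples, dt = %g ms, duration = %g ms%s\n",
              length(x$vm), x$time[2] - x$time[1], max(x$time),
              if (isTRUE(x$failed)) " [FAILED]" else ""))
  invisible(x)
}

#' Read/write a voltage trace as two-column CSV
#'
#' Columns `time_ms`, `vm_mV`.
#' @param trace A `voltage_trace`.
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  data.table::fwrite(data.table::data.table(time_ms = trace$time,
                                            vm_mV = trace$vm), path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param protocol Protocol to attach on read.
#' @export
read_trace_csv <- function(path, protocol = step_protocol()) {
  d <- data.table::fread(path)
  voltage_trace(d$time_ms, d$vm_mV, protocol)
}
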