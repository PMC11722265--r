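#' Names of the 23 electrophysiological summary features
#'
#' Spike-shape features (threshold, amplitude, width, afterhyperpolarization
#' for the 1st and 3rd action potential), spike-count features over the
#' injection window and its sub-windows, adaptation and variability indices,
#' latency, and membrane-voltage moments.
#'
#' @return Character vector of length 23.
#' @export
feature_names <- function() {
  c("ap_threshold", "ap_amplitude", "ap_width", "ahp",
    "ap_threshold_3rd", "ap_amplitude_3rd", "ap_width_3rd", "ahp_3rd",
    "ap_count", "ap_count_1st_8th", "ap_count_1st_quarter",
    "ap_count_1st_half", "ap_count_2nd_half",
    "ap_amp_adapt", "ap_average_amp_adapt", "ap_cv",
    "isi_adapt", "isi_cv", "latency",
    "rest_vm_mean", "vm_mean", "vm_std", "vm_skewness")
}

# the 11 features brought closer to Gaussian before standardization:
# counts via log(x+1), strictly positive ratios/latency via log(x), and the
# average amplitude-adaptation ratio via the logistic sigmoid
log1p_features <- function() {
  c("ap_count", "ap_count_1st_8th", "ap_count_1st_quarter",
    "ap_count_1st_half", "ap_count_2nd_half")
}
log_features <- function() {
  c("ap_amp_adapt", "ap_cv", "isi_adapt", "isi_cv", "latency")
}
sigmoid_features <- function() "ap_average_amp_adapt"

#' Detect action potentials in a voltage trace
#'
#' An AP begins at the first grid point of an upstroke where the forward
#' finite-difference dV/dt reaches `dvdt_threshold`; its peak is the voltage
#' maximum before the trace first returns to the threshold voltage; its width
#' is measured at half height between threshold and peak (linear
#' interpolation between grid points); the afterhyperpolarization (AHP) is
#' the depth of the post-peak voltage minimum before the next AP threshold
#' (or the end of the protocol), measured downward from the AP threshold
#' voltage (positive = dips below threshold).
#'
#' @param trace A `voltage_trace` (uniform dt).
#' @param dvdt_threshold Upstroke detection threshold in mV/ms (default 20).
#' @param t_max Ignore samples beyond this time (defaults to the protocol
#'   duration, making detection invariant to trailing padding).
#' @return Data frame (possibly 0-row) with columns `t_threshold`,
#'   `v_threshold`, `t_peak`, `v_peak`, `amplitude`, `width`, `ahp`.
#' @export
detect_spikes <- function(trace, dvdt_threshold = 20, t_max = NULL) {
  empty <- data.frame(t_threshold = numeric(0), v_threshold = numeric(0),
                      t_peak = numeric(0), v_peak = numeric(0),
                      amplitude = numeric(0), width = numeric(0),
                      ahp = numeric(0))
  time <- trace$time; vm <- trace$vm
  if (is.null(t_max)) t_max <- trace$protocol$duration
  keep <- time <= t_max + 1e-9
  time <- time[keep]; vm <- vm[keep]
  n <- length(vm)
  if (n < 3 || any(!is.finite(vm))) return(empty)
  dt <- time[2] - time[1]
  dvdt <- diff(vm) / dt                      # dvdt[i] at sample i (forward)
  up <- which(dvdt >= dvdt_threshold & c(-Inf, dvdt[-(n - 1)]) < dvdt_threshold)

  rows <- list(); last_end <- 0L
  for (ti in up) {
    if (ti <= last_end) next                 # still inside the previous AP
    vt <- vm[ti]
    # spike ends when voltage first returns to/below its threshold voltage
    after <- ti + which(vm[(ti + 1):n] <= vt)
    end_i <- if (length(after)) after[1] else n
    pk_rel <- which.max(vm[ti:end_i])
    pk <- ti + pk_rel - 1L
    rows[[length(rows) + 1L]] <- c(ti = ti, pk = pk, end_i = end_i)
    last_end <- end_i
  }
  if (!length(rows)) return(empty)
  sp <- do.call(rbind, rows)

  k <- nrow(sp)
  out <- empty[rep(1L, 0L), ]
  width <- ahp <- numeric(k)
  for (s in seq_len(k)) {
    ti <- sp[s, "ti"]; pk <- sp[s, "pk"]; end_i <- sp[s, "end_i"]
    vt <- vm[ti]; vp <- vm[pk]
    level <- vt + 0.5 * (vp - vt)
    # rising half-height crossing in [ti, pk]
    ir <- ti + which(vm[(ti + 1):pk] >= level)[1] - 1L
    t_rise <- if (is.na(ir) || vp <= vt) NA_real_ else
      time[ir] + dt * (level - vm[ir]) / (vm[ir + 1] - vm[ir])
    # falling crossing in [pk, end of AHP window]
    nxt <- if (s < k) sp[s + 1L, "ti"] else n
    fall_seg <- vm[pk:nxt]
    jf <- which(fall_seg <= level)[1]
    t_fall <- if (is.na(jf) || jf == 1L) NA_real_ else {
      jj <- pk + jf - 2L
      time[jj] + dt * (vm[jj] - level) / (vm[jj] - vm[jj + 1])
    }
    width[s] <- t_fall - t_rise
    ahp[s] <- vt - min(vm[pk:nxt])
  }
  data.frame(t_threshold = time[sp[, "ti"]], v_threshold = vm[sp[, "ti"]],
             t_peak = time[sp[, "pk"]], v_peak = vm[sp[, "pk"]],
             amplitude = vm[sp[, "pk"]] - vm[sp[, "ti"]],
             width = width, ahp = ahp)
}

moment_skewness <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)                    # constant window: limit convention
  mean((x - m)^3) / s2^1.5
}

#' Extract the 23 electrophysiological summary features
#'
#' Windows are half-open `[start, end)` intervals on the simulation grid,
#' scaled from the protocol: the resting window is `[0, onset)`, the
#' injection window `[onset, offset)`, and the count sub-windows its first
#' eighth, quarter and half, and second half. Only APs whose threshold falls
#' inside the injection window count. Undefined features (e.g. 3rd-AP shape
#' with fewer than three APs) are returned as `NA`.
#'
#' @param trace A `voltage_trace`.
#' @param protocol Protocol defining the windows (defaults to the trace's).
#' @param dvdt_threshold Spike-detection threshold in mV/ms.
#' @return Named numeric vector of length 23 (`NA` = undefined), with the
#'   spike table attached as attribute `spikes`.
#' @export
extract_features <- function(trace, protocol = NULL, dvdt_threshold = 20) {
  if (is.null(protocol)) protocol <- trace$protocol
  fv <- stats::setNames(rep(NA_real_, 23L), feature_names())
  if (isTRUE(trace$failed)) return(fv)
  on <- protocol$onset; off <- protocol$offset
  time <- trace$time; vm <- trace$vm

  sp <- detect_spikes(trace, dvdt_threshold, t_max = protocol$duration)
  sp <- sp[sp$t_threshold >= on & sp$t_threshold < off, , drop = FALSE]
  nap <- nrow(sp)

  win <- function(a, b) vm[time >= a - 1e-9 & time < b - 1e-9]
  rest <- win(0, on); stimw <- win(on, off)
  fv["rest_vm_mean"] <- mean(rest)
  fv["vm_mean"] <- mean(stimw)
  fv["vm_std"] <- sqrt(mean((stimw - mean(stimw))^2))
  fv["vm_skewness"] <- moment_skewness(stimw)

  span <- off - on
  cnt <- function(a, b) sum(sp$t_threshold >= a & sp$t_threshold < b)
  fv["ap_count"] <- nap
  fv["ap_count_1st_8th"] <- cnt(on, on + span / 8)
  fv["ap_count_1st_quarter"] <- cnt(on, on + span / 4)
  fv["ap_count_1st_half"] <- cnt(on, on + span / 2)
  fv["ap_count_2nd_half"] <- cnt(on + span / 2, off)

  if (nap >= 1) {
    fv["ap_threshold"] <- sp$v_threshold[1]
    fv["ap_amplitude"] <- sp$amplitude[1]
    fv["ap_width"] <- sp$width[1]
    fv["ahp"] <- sp$ahp[1]
    fv["latency"] <- sp$t_threshold[1] - on
  }
  if (nap >= 3) {
    fv["ap_threshold_3rd"] <- sp$v_threshold[3]
    fv["ap_amplitude_3rd"] <- sp$amplitude[3]
    fv["ap_width_3rd"] <- sp$width[3]
    fv["ahp_3rd"] <- sp$ahp[3]
  }
  if (nap >= 2) {
    amps <- sp$amplitude
    fv["ap_amp_adapt"] <- amps[1] / amps[2]
    fv["ap_average_amp_adapt"] <- mean(amps[-length(amps)] / amps[-1])
    fv["ap_cv"] <- sd(amps) / mean(amps)
    isi <- diff(sp$t_threshold)
    if (length(isi) >= 2) {
      fv["isi_adapt"] <- isi[2] / isi[1]
      fv["isi_cv"] <- sd(isi) / mean(isi)
    }
  }
  fv[!is.finite(fv)] <- NA_real_
  attr(fv, "spikes") <- sp
  fv
}

#' Transform features towards Gaussianity
#'
#' Count features map through `log(x + 1)` (zero sub-window counts stay
#' defined), strictly positive ratio/latency features through `log(x)`, the
#' average amplitude-adaptation ratio through the logistic sigmoid
#' `1/(1 + exp(-x))`; the remaining features pass through unchanged. Any
#' non-finite result (e.g. `log` of a zero latency) becomes undefined (`NA`).
#'
#' @param fv Named feature vector from [extract_features()], or a matrix
#'   with 23 named columns.
#' @return Transformed vector/matrix of the same shape.
#' @export
transform_features <- function(fv) {
  if (is.matrix(fv)) {
    out <- t(apply(fv, 1, transform_features))
    colnames(out) <- colnames(fv)
    return(out)
  }
  out <- fv[feature_names()]
  out[log1p_features()] <- log1p(out[log1p_features()])
  out[log_features()] <- log(out[log_features()])
  s <- out[sigmoid_features()]
  out[sigmoid_features()] <- 1 / (1 + exp(-s))
  out[!is.finite(out)] <- NA_real_
  attributes(out) <- list(names = feature_names())
  out
}

#' Is a feature vector fully well-defined?
#'
#' TRUE iff all 23 transformed features are finite. This is the inclusion
#' criterion for simulations (and cells) throughout the pipeline.
#'
#' @param fv Raw (untransformed) feature vector or matrix.
#' @return Logical scalar (or vector for a matrix input).
#' @export
is_well_defined <- function(fv) {
  tf <- transform_features(fv)
  if (is.matrix(tf)) rowSums(!is.finite(tf)) == 0 else all(is.finite(tf))
}
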