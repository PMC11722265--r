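#' Names of the 13 biophysical model parameters
#'
#' Canonical ordering used throughout the package: membrane capacitance `C`
#' (uF/cm2), input resistance `Rinput` (MOhm), membrane time constant `tau`
#' (ms), maximal conductances `gNat`, `gNa`, `gKd`, `gM`, `gKv31`, `gL`
#' (mS/cm2), leak reversal `Eleak` (mV), muscarinic time-constant scale
#' `tau_max` (ms), spike-threshold adjustment `VT` (mV), and the dimensionless
#' rate-to-steady-state scale `rSS`.
#'
#' @return Character vector of length 13.
#' @export
param_names <- function() {
  c("C", "Rinput", "tau", "gNat", "gNa", "gKd", "gM", "gKv31", "gL",
    "Eleak", "tau_max", "VT", "rSS")
}

#' Construct a box-uniform prior over the biophysical parameters
#'
#' @param lower,upper Named numeric vectors of per-parameter bounds, in the
#'   order of [param_names()]. Defaults are the standard biologically
#'   plausible ranges used for cortical neurons (see [default_prior()]).
#' @return An object of class `prior_box` with elements `lower` and `upper`.
#' @export
prior_box <- function(lower, upper) {
  nm <- param_names()
  lower <- as.numeric(lower[nm]); upper <- as.numeric(upper[nm])
  names(lower) <- nm; names(upper) <- nm
  if (anyNA(lower) || anyNA(upper))
    stop("prior_box: bounds must be named numeric vectors covering all 13 parameters")
  if (any(lower >= upper))
    stop("prior_box: lower bound must be strictly below upper bound for every parameter")
  structure(list(lower = lower, upper = upper), class = "prior_box")
}

#' Default prior box for cortical neurons
#'
#' Ranges: C in \[0.1, 15\] uF/cm2, Rinput in \[20, 1000\] MOhm, tau in
#' \[0.1, 70\] ms, gNat in \[0, 250\], gNa in \[0, 100\], gKd in \[0, 30\],
#' gM in \[0, 3\], gKv31 in \[0, 250\], gL in \[0, 3\] mS/cm2, Eleak in
#' \[-130, -50\] mV, tau_max in \[50, 4000\] ms, VT in \[-90, -35\] mV and
#' rSS in \[0.1, 3\].
#'
#' @return A `prior_box`.
#' @export
default_prior <- function() {
  lower <- c(C = 0.1, Rinput = 20, tau = 0.1, gNat = 0, gNa = 0, gKd = 0,
             gM = 0, gKv31 = 0, gL = 0, Eleak = -130, tau_max = 50,
             VT = -90, rSS = 0.1)
  upper <- c(C = 15, Rinput = 1000, tau = 70, gNat = 250, gNa = 100,
             gKd = 30, gM = 3, gKv31 = 250, gL = 3, Eleak = -50,
             tau_max = 4000, VT = -35, rSS = 3)
  prior_box(lower, upper)
}

#' Draw independent uniform parameter samples from a prior box
#'
#' @param prior A `prior_box`.
#' @param n Number of draws (`n = 0` gives a 0-row matrix).
#' @param seed Optional integer seed; when given, draws are reproducible.
#' @return Numeric matrix `n x 13` with columns [param_names()].
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "prior_box"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  p <- length(prior$lower)
  u <- matrix(runif(n * p), nrow = n, ncol = p)
  theta <- sweep(sweep(u, 2, prior$upper - prior$lower, "*"), 2, prior$lower, "+")
  colnames(theta) <- param_names()
  theta
}

#' Validate a single parameter vector against its invariants
#'
#' Checks non-negative conductances and strictly positive C, Rinput, tau,
#' tau_max and rSS.
#'
#' @param theta Named numeric vector (or 1-row matrix) of 13 parameters.
#' @return The parameter vector, invisibly; errors if invalid.
#' @export
validate_params <- function(theta) {
  theta <- as_param_vector(theta)
  pos <- c("C", "Rinput", "tau", "tau_max", "rSS")
  if (any(theta[pos] <= 0))
    stop("invalid parameters: ", paste(pos[theta[pos] <= 0], collapse = ", "),
         " must be > 0")
  gg <- c("gNat", "gNa", "gKd", "gM", "gKv31", "gL")
  if (any(theta[gg] < 0))
    stop("invalid parameters: conductances must be >= 0")
  invisible(theta)
}

as_param_vector <- function(theta) {
  if (is.matrix(theta)) theta <- theta[1, ]
  theta <- theta[param_names()]
  if (anyNA(theta)) stop("parameter vector must be named with all 13 parameters")
  theta
}

as_param_matrix <- function(theta) {
  if (!is.matrix(theta)) theta <- matrix(theta, nrow = 1,
                                         dimnames = list(NULL, names(theta)))
  if (!is.null(colnames(theta))) theta <- theta[, param_names(), drop = FALSE]
  if (ncol(theta) != 13L) stop("expected 13 parameter columns")
  colnames(theta) <- param_names()
  theta
}
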