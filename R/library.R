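#' Fit a per-feature standardizer (Z-scoring) on transformed features
#'
#' Means and standard deviations (population convention, divisor n) are
#' computed over a reference set of fully defined transformed feature
#' vectors, exactly as features of simulations and observations are Z-scored
#' against a reference simulation library.
#'
#' @param x Matrix of transformed feature vectors (rows = simulations/cells).
#'   Rows with any undefined entry are dropped.
#' @return Object of class `feature_standardizer` with `mean` and `sd`.
#' @export
fit_standardizer <- function(x) {
  x <- as_feature_matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) == 0) stop("fit_standardizer: no fully defined vectors")
  m <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, m)^2))
  if (any(s <= 0))
    stop("fit_standardizer: zero standard deviation for feature(s): ",
         paste(colnames(x)[s <= 0], collapse = ", "))
  structure(list(mean = m, sd = s), class = "feature_standardizer")
}

#' @rdname fit_standardizer
#' @param std A `feature_standardizer`.
#' @return `apply_standardizer`: Z-scored vector or matrix.
#' @export
apply_standardizer <- function(x, std) {
  stopifnot(inherits(std, "feature_standardizer"))
  if (is.matrix(x)) {
    x <- as_feature_matrix(x)
    sweep(sweep(x, 2, std$mean), 2, std$sd, "/")
  } else {
    (x[feature_names()] - std$mean) / std$sd
  }
}

as_feature_matrix <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (!is.null(colnames(x))) x <- x[, feature_names(), drop = FALSE]
  if (ncol(x) != 23L) stop("expected 23 feature columns")
  colnames(x) <- feature_names()
  x
}

#' Build a library of (parameters, features) pairs simulated from the prior
#'
#' Draws `n` parameter vectors, simulates each under the protocol in batches,
#' extracts and transforms the 23 features, records which rows are fully
#' well-defined, and fits the library's own standardizer on its defined rows.
#' Failed simulations are stored as undefined rows. Deterministic given
#' `(seed, batch)`.
#'
#' @param prior A `prior_box`.
#' @param protocol A `stim_protocol`.
#' @param n Number of simulations (>= 1).
#' @param seed Integer seed.
#' @param batch Simulations per integrator call (memory control).
#' @param theta Optional pre-drawn parameter matrix (overrides `prior`/`n`).
#' @param verbose Print progress.
#' @return Object of class `sim_library` with elements `theta` (n x 13),
#'   `x_raw`, `x_trans` (n x 23), `defined` (logical), `std`
#'   (`feature_standardizer` or NULL if < 2 defined rows), `prior`,
#'   `protocol`, `seed`.
#' @export
build_library <- function(prior = default_prior(), protocol = step_protocol(),
                          n = 1000, seed = 1, batch = 100, theta = NULL,
                          verbose = FALSE) {
  set.seed(seed)
  if (is.null(theta)) {
    stopifnot(n >= 1)
    theta <- sample_prior(prior, n)
  } else {
    theta <- as_param_matrix(theta)
    n <- nrow(theta)
  }
  x_raw <- matrix(NA_real_, n, 23, dimnames = list(NULL, feature_names()))
  failed <- logical(n)
  starts <- seq(1, n, by = batch)
  for (b in starts) {
    idx <- b:min(b + batch - 1, n)
    res <- simulate_batch(theta[idx, , drop = FALSE], protocol)
    for (j in seq_along(idx)) {
      tr <- structure(list(time = res$time, vm = res$vm[j, ],
                           protocol = protocol, failed = res$failed[j]),
                      class = "voltage_trace")
      x_raw[idx[j], ] <- extract_features(tr, protocol)
    }
    failed[idx] <- res$failed
    if (verbose) message(sprintf("simulated %d / %d", max(idx), n))
  }
  x_trans <- transform_features(x_raw)
  defined <- rowSums(!is.finite(x_trans)) == 0
  std <- if (sum(defined) >= 2) fit_standardizer(x_trans[defined, , drop = FALSE]) else NULL
  structure(list(theta = theta, x_raw = x_raw, x_trans = x_trans,
                 defined = defined, failed = failed, std = std,
                 prior = prior, protocol = protocol, seed = seed),
            class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("<sim_library> %d simulations, %d (%.1f%%) well-defined\n",
              nrow(x$theta), sum(x$defined), 100 * mean(x$defined)))
  invisible(x)
}

#' Z-scored features of the library's defined rows
#' @param lib A `sim_library`.
#' @return Matrix of Z-scored transformed features (defined rows only), with
#'   attribute `rows` giving the original row indices.
#' @export
library_zscores <- function(lib) {
  z <- apply_standardizer(lib$x_trans[lib$defined, , drop = FALSE], lib$std)
  attr(z, "rows") <- which(lib$defined)
  z
}

#' Nearest simulations to an observation in Z-scored feature space
#'
#' Euclidean distance over all 23 Z-scored transformed features, restricted
#' to well-defined library rows; ties broken by row index.
#'
#' @param obs A single Z-scored feature vector, or a matrix of them (rows =
#'   observations), already in the library's Z space.
#' @param lib A `sim_library`.
#' @param k Number of neighbours (<= number of defined rows).
#' @return For a single observation, a list with `rows` (library row ids,
#'   ascending distance) and `dist`; for a matrix, a list of such lists.
#' @export
nearest_simulations <- function(obs, lib, k = 1) {
  z <- library_zscores(lib)
  rows <- attr(z, "rows")
  if (k > nrow(z)) stop("k exceeds the number of well-defined library rows")
  one <- function(o) {
    if (any(!is.finite(o))) stop("observation must be fully defined")
    d2 <- rowSums(sweep(z, 2, o)^2)
    ord <- order(d2, seq_along(d2))[seq_len(k)]
    list(rows = rows[ord], dist = sqrt(d2[ord]))
  }
  if (is.matrix(obs)) apply(obs, 1, one) else one(obs[feature_names()])
}

#' Distance distributions diagnosing model-data mismatch
#'
#' For each observation, its Euclidean distance (Z space) to the nearest
#' library simulation; and for a sample of library simulations, the distance
#' to their nearest *other* simulation. Observations systematically shifted
#' away from the simulator's reachable feature region show a right-shifted
#' observation distribution.
#'
#' @param observations Matrix of Z-scored observation features (0-row allowed).
#' @param lib A `sim_library`.
#' @param n_sim_ref Number of library rows sampled for the within-library
#'   distribution (default all, capped at 1000).
#' @param seed Seed for the reference subsample.
#' @return List with numeric vectors `obs_to_sim` and `sim_to_sim`.
#' @export
mismatch_profile <- function(observations, lib, n_sim_ref = 1000, seed = 1) {
  z <- library_zscores(lib)
  obs_to_sim <- numeric(0)
  if (!is.null(observations) && nrow(observations) > 0) {
    obs_to_sim <- apply(observations, 1, function(o)
      sqrt(min(rowSums(sweep(z, 2, o)^2))))
  }
  set.seed(seed)
  ref <- sample(nrow(z), min(n_sim_ref, nrow(z)))
  sim_to_sim <- vapply(ref, function(i) {
    d2 <- rowSums(sweep(z, 2, z[i, ])^2)
    sqrt(min(d2[-i]))
  }, numeric(1))
  list(obs_to_sim = unname(obs_to_sim), sim_to_sim = unname(sim_to_sim))
}

#' Persist a simulation library as plain-text files
#'
#' Writes `theta.csv`, `features_raw.csv`, `features_transformed.csv` (with a
#' `defined` column) and `meta.yaml` (prior box, protocol, seed) into a
#' directory.
#'
#' @param lib A `sim_library`.
#' @param dir Output directory (created if needed).
#' @export
write_library <- function(lib, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(lib$theta),
                     file.path(dir, "theta.csv"))
  data.table::fwrite(data.table::as.data.table(lib$x_raw),
                     file.path(dir, "features_raw.csv"))
  xt <- data.table::as.data.table(lib$x_trans)
  xt$defined <- lib$defined
  data.table::fwrite(xt, file.path(dir, "features_transformed.csv"))
  yaml::write_yaml(list(seed = lib$seed,
                        prior = list(lower = as.list(lib$prior$lower),
                                     upper = as.list(lib$prior$upper)),
                        protocol = unclass(lib$protocol)),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_library
#' @return `read_library`: the reconstructed `sim_library`.
#' @export
read_library <- function(dir) {
  theta <- as.matrix(data.table::fread(file.path(dir, "theta.csv")))
  x_raw <- as.matrix(data.table::fread(file.path(dir, "features_raw.csv")))
  xt <- as.data.frame(data.table::fread(file.path(dir, "features_transformed.csv")))
  defined <- xt$defined
  x_trans <- as.matrix(xt[, setdiff(names(xt), "defined")])
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  prior <- prior_box(unlist(meta$prior$lower), unlist(meta$prior$upper))
  protocol <- do.call(step_protocol,
                      meta$protocol[setdiff(names(meta$protocol), character(0))])
  std <- if (sum(defined) >= 2)
    fit_standardizer(x_trans[defined, , drop = FALSE]) else NULL
  structure(list(theta = theta, x_raw = x_raw, x_trans = x_trans,
                 defined = defined, failed = rep(NA, nrow(theta)), std = std,
                 prior = prior, protocol = protocol, seed = meta$seed),
            class = "sim_library")
}
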