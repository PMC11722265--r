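#' Default family-level parameter boxes for synthetic cohorts
#'
#' Three caricature families spanning the firing-pattern diversity of
#' cortical neurons: a fast-spiking interneuron-like family (high
#' delayed-rectifier and Kv3.1 conductances, fast membrane), an adapting
#' interneuron-like family, and a pyramidal-like family (wider APs via small
#' rSS, slower membrane, more muscarinic adaptation). Each entry is a
#' sub-box of the default prior from which that family's parameters are
#' drawn uniformly.
#'
#' @return Named list of `list(lower, upper)` named vectors.
#' @export
default_families <- function() {
  box <- function(...) {
    m <- rbind(...)
    list(lower = stats::setNames(m[, 1], param_names()),
         upper = stats::setNames(m[, 2], param_names()))
  }
  list(
    fast_spiking = box(
      C = c(0.5, 2), Rinput = c(100, 250), tau = c(5, 15),
      gNat = c(40, 120), gNa = c(20, 60), gKd = c(8, 20), gM = c(0, 0.3),
      gKv31 = c(60, 180), gL = c(0, 0.3), Eleak = c(-85, -70),
      tau_max = c(500, 1500), VT = c(-67, -57), rSS = c(1.2, 2.2)),
    adapting = box(
      C = c(1, 3), Rinput = c(200, 400), tau = c(10, 25),
      gNat = c(30, 90), gNa = c(10, 40), gKd = c(4, 12), gM = c(0.3, 1.2),
      gKv31 = c(20, 80), gL = c(0.2, 1), Eleak = c(-80, -65),
      tau_max = c(800, 2500), VT = c(-65, -55), rSS = c(0.8, 1.6)),
    pyramidal = box(
      C = c(1, 3), Rinput = c(80, 200), tau = c(15, 35),
      gNat = c(30, 100), gNa = c(10, 40), gKd = c(3, 10), gM = c(0.5, 2),
      gKv31 = c(5, 40), gL = c(0.3, 1.5), Eleak = c(-85, -70),
      tau_max = c(1000, 3000), VT = c(-60, -48), rSS = c(0.3, 0.8))
  )
}

# fixed 13 -> 2 latent map coupling biophysics to gene expression:
# axis 1 ~ fast-spiking vs pyramidal (K conductances, rSS, membrane speed),
# axis 2 ~ adaptation/calcium axis
default_latent_map <- function() {
  M <- matrix(0, 13, 2, dimnames = list(param_names(), NULL))
  M[c("gKd", "gKv31", "rSS"), 1] <- c(0.5, 0.5, 0.4)
  M[c("tau", "C"), 1] <- c(-0.4, -0.2)
  M[c("gM", "gL", "tau_max"), 2] <- c(0.6, 0.5, 0.3)
  M[c("Eleak", "VT"), 2] <- c(-0.3, 0.3)
  sweep(M, 2, sqrt(colSums(M^2)), "/")
}

#' Generate a synthetic Patch-seq-like cohort
#'
#' Draws ground-truth biophysical parameters from a mixture of per-family
#' sub-boxes of the prior, simulates and featurizes every cell (resampling
#' parameters until the feature vector is fully well-defined), and couples a
#' negative-binomial gene-count matrix to the biophysics through a rank-2
#' latent bottleneck: `T = standardize(theta) %*% M`, counts with mean
#' `s_c * exp(a_g + (T B')_cg)` and dispersion `phi`, where exactly
#' `n_active_genes` rows of the loading matrix `B` are nonzero.
#'
#' @param n_cells Number of cells (default 200).
#' @param n_genes Number of genes (default 300).
#' @param n_active_genes Genes truly coupled to the biophysics (default 25).
#' @param families Named list of family boxes (default [default_families()]).
#' @param protocol Stimulation protocol.
#' @param phi Negative-binomial dispersion (size) parameter (default 2).
#' @param b_scale Scale of the nonzero gene loadings (default 0.5).
#' @param libsize_sd SD of the log-normal cell size factors (default 0.3).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param max_attempts Resampling cap per cell before erroring.
#' @param keep_traces Keep the simulated voltage matrix (memory-heavy).
#' @return Object of class `synthetic_cohort`: `theta`, `features_raw`,
#'   `features_trans`, `family`, `counts`, `B`, `M`, `active_genes`,
#'   `latent`, `protocol`, `seed`.
#' @export
make_cohort <- function(n_cells = 200, n_genes = 300, n_active_genes = 25,
                        families = default_families(),
                        protocol = step_protocol(), phi = 2, b_scale = 0.5,
                        libsize_sd = 0.3, seed = 1, max_attempts = 200,
                        keep_traces = FALSE) {
  if (n_active_genes > n_genes) stop("n_active_genes exceeds n_genes")
  set.seed(seed)
  fam_names <- names(families)
  family <- sample(fam_names, n_cells, replace = TRUE)
  theta <- matrix(NA_real_, n_cells, 13, dimnames = list(NULL, param_names()))
  x_raw <- matrix(NA_real_, n_cells, 23, dimnames = list(NULL, feature_names()))
  traces <- if (keep_traces) vector("list", n_cells) else NULL

  draw_in_box <- function(b) b$lower + runif(13) * (b$upper - b$lower)
  for (i in seq_len(n_cells)) {
    fb <- families[[family[i]]]
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      th <- draw_in_box(fb)
      tr <- simulate_neuron(th, protocol)
      fv <- extract_features(tr, protocol)
      if (is_well_defined(fv)) {
        theta[i, ] <- th; x_raw[i, ] <- fv
        if (keep_traces) traces[[i]] <- tr
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not draw a well-defined cell for family ",
                  family[i], " in ", max_attempts, " attempts")
  }

  tz <- scale(theta)
  M <- default_latent_map()
  latent <- tz %*% M
  active <- sort(sample(n_genes, n_active_genes))
  B <- matrix(0, n_genes, 2)
  B[active, ] <- matrix(rnorm(n_active_genes * 2, sd = b_scale),
                        n_active_genes)
  a_g <- rnorm(n_genes, mean = log(3), sd = 0.7)
  s_c <- exp(rnorm(n_cells, 0, libsize_sd))
  mu <- s_c * exp(sweep(latent %*% t(B), 2, a_g, "+"))
  counts <- matrix(rnbinom(n_cells * n_genes, mu = mu, size = phi),
                   n_cells, n_genes,
                   dimnames = list(NULL, paste0("gene", seq_len(n_genes))))

  structure(list(theta = theta, features_raw = x_raw,
                 features_trans = transform_features(x_raw),
                 family = family, counts = counts, B = B, M = M,
                 active_genes = active, latent = latent,
                 protocol = protocol, phi = phi, seed = seed,
                 traces = traces),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cells (%s), %d genes (%d active)\n",
              nrow(x$theta),
              paste(names(table(x$family)), table(x$family), sep = ":",
                    collapse = ", "),
              ncol(x$counts), length(x$active_genes)))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `truth_theta.csv`, `features.csv` (raw features plus a
#' `well_defined` column), `expression.csv` (counts),
#' `truth_loadings.csv` (gene loading matrix with an `active` flag) and
#' `cohort.yaml` (generator configuration and seed).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(cohort$theta),
                     file.path(dir, "truth_theta.csv"))
  fx <- data.table::as.data.table(cohort$features_raw)
  fx$well_defined <- is_well_defined(cohort$features_raw)
  fx$family <- cohort$family
  data.table::fwrite(fx, file.path(dir, "features.csv"))
  data.table::fwrite(data.table::as.data.table(cohort$counts),
                     file.path(dir, "expression.csv"))
  bl <- data.table::data.table(gene = colnames(cohort$counts),
                               loading_1 = cohort$B[, 1],
                               loading_2 = cohort$B[, 2],
                               active = seq_len(nrow(cohort$B)) %in%
                                 cohort$active_genes)
  data.table::fwrite(bl, file.path(dir, "truth_loadings.csv"))
  yaml::write_yaml(list(n_cells = nrow(cohort$theta),
                        n_genes = ncol(cohort$counts),
                        n_active_genes = length(cohort$active_genes),
                        families = unique(cohort$family),
                        phi = cohort$phi, seed = cohort$seed),
                   file.path(dir, "cohort.yaml"))
  invisible(dir)
}

#' Misspecification offset applied to observed features
#'
#' Emulates systematic model-data mismatch: observations are shifted in
#' Z-scored feature space by a fixed, recorded, invertible offset (and
#' optional per-feature scale). The default targets the AP-width axis, the
#' feature along which real recordings most visibly depart from the
#' simulator's reachable region.
#'
#' @param offset Named numeric vector of Z-space shifts (names from
#'   [feature_names()]); unnamed scalar plus `feature` also accepted.
#' @param feature Feature receiving a scalar `offset`.
#' @param scale Optional named per-feature multiplicative factors.
#' @return Object of class `misspec_spec`.
#' @export
misspec_spec <- function(offset = 0.5, feature = "ap_width", scale = NULL) {
  off <- stats::setNames(rep(0, 23), feature_names())
  if (!is.null(names(offset))) {
    off[names(offset)] <- offset
  } else {
    off[feature] <- offset
  }
  sc <- stats::setNames(rep(1, 23), feature_names())
  if (!is.null(scale)) sc[names(scale)] <- scale
  structure(list(offset = off, scale = sc), class = "misspec_spec")
}

#' Apply (or invert) a misspecification spec in Z space
#'
#' @param z Matrix or vector of Z-scored features.
#' @param spec A [misspec_spec()] (`NULL` = identity).
#' @param invert Undo the transformation.
#' @return Shifted features, same shape.
#' @export
misspecify <- function(z, spec = misspec_spec(), invert = FALSE) {
  if (is.null(spec)) return(z)
  stopifnot(inherits(spec, "misspec_spec"))
  apply_vec <- function(v) {
    if (invert) (v - spec$offset) / spec$scale else v * spec$scale + spec$offset
  }
  if (is.matrix(z)) {
    out <- t(apply(z, 1, apply_vec)); colnames(out) <- colnames(z); out
  } else apply_vec(z)
}

#' Join ground truth with inference results for a cohort
#'
#' For each cell: the true parameters, the MAP estimate, the Z-space
#' parameter error, and per-marginal 95% credible-interval coverage flags
#' from posterior samples.
#'
#' @param cohort A `synthetic_cohort`.
#' @param model An `npe_posterior`.
#' @param lib The `sim_library` whose standardizer defines the observation
#'   Z space the model was trained in.
#' @param observations Optional pre-computed Z-scored observations
#'   (e.g. misspecified ones); default: the cohort's features Z-scored with
#'   the library standardizer.
#' @param n_samples Posterior draws per cell for the credible intervals.
#' @param n_map_samples Draws for the MAP argmax.
#' @param seed Integer seed.
#' @return List with `per_cell` data frame (`cell`, `family`,
#'   `map_z_error`, `coverage` = fraction of the 13 marginals covering
#'   truth), `coverage_by_param` (named vector), `map_theta`, and overall
#'   `coverage`.
#' @export
recovery_report <- function(cohort, model, lib, observations = NULL,
                            n_samples = 1000, n_map_samples = 10000,
                            seed = 1) {
  if (is.null(observations))
    observations <- apply_standardizer(cohort$features_trans, lib$std)
  n <- nrow(cohort$theta)
  set.seed(seed)
  tc <- colMeans(lib$theta[lib$defined, , drop = FALSE])
  ts <- apply(lib$theta[lib$defined, , drop = FALSE], 2, sd)
  map_theta <- matrix(NA_real_, n, 13, dimnames = list(NULL, param_names()))
  cover <- matrix(NA, n, 13, dimnames = list(NULL, param_names()))
  err <- numeric(n)
  for (i in seq_len(n)) {
    x0 <- observations[i, ]
    s <- posterior_sample(model, x0, n_samples)
    lo <- apply(s, 2, quantile, 0.025); hi <- apply(s, 2, quantile, 0.975)
    cover[i, ] <- cohort$theta[i, ] >= lo & cohort$theta[i, ] <= hi
    map_theta[i, ] <- map_estimate(model, x0, n_samples = n_map_samples)
    err[i] <- sqrt(sum(((map_theta[i, ] - cohort$theta[i, ]) / ts)^2))
  }
  list(per_cell = data.frame(cell = seq_len(n), family = cohort$family,
                             map_z_error = err,
                             coverage = rowMeans(cover)),
       coverage_by_param = colMeans(cover),
       coverage = mean(cover),
       map_theta = map_theta)
}
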