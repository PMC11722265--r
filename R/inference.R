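#' Training configuration for neural posterior estimation
#'
#' @param scheme Training schedule: `"standard"` (all defined library pairs),
#'   `"best_euclidean"` (union of the `n_close` nearest library pairs per
#'   observation), `"noise_ephys"` (same subset with isotropic Gaussian noise
#'   of amplitude `sigma` added to every Z-scored feature; the
#'   misspecification-robust NPE-N schedule at the default `sigma = 0.1`),
#'   `"noise_ephys_params"` (noise on features and on standardized
#'   parameters, clipped back to the prior box) or `"augmentation"`
#'   (clean + feature-noised subsets concatenated).
#' @param sigma Noise amplitude in Z units (default 0.1).
#' @param n_close Nearest simulations kept per observation (default 1000).
#' @param n_hidden,n_components Network width and mixture size.
#' @param max_epochs,batch_size,lr,val_frac,patience,min_pairs Optimizer
#'   controls: epoch cap, minibatch size, Adam learning rate, validation
#'   fraction for early stopping, early-stopping patience, minimum number of
#'   training pairs.
#' @param seed Integer seed controlling initialization, shuffling and noise.
#' @return A list of class `npe_config`.
#' @export
npe_config <- function(scheme = c("standard", "best_euclidean", "noise_ephys",
                                  "noise_ephys_params", "augmentation"),
                       sigma = 0.1, n_close = 1000, n_hidden = 50,
                       n_components = 4, max_epochs = 200, batch_size = 256,
                       lr = 1e-3, val_frac = 0.1, patience = 20,
                       min_pairs = 50, seed = 1) {
  scheme <- match.arg(scheme)
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(scheme = scheme, sigma = sigma, n_close = n_close,
                 n_hidden = n_hidden, n_components = n_components,
                 max_epochs = max_epochs, batch_size = batch_size, lr = lr,
                 val_frac = val_frac, patience = patience,
                 min_pairs = min_pairs, seed = seed),
            class = "npe_config")
}

#' Assemble (theta, x) training pairs under a training schedule
#'
#' @param lib A `sim_library`.
#' @param observations Matrix of Z-scored observed feature vectors (in the
#'   library's Z space); may be `NULL`/empty only for `scheme = "standard"`.
#' @param config An [npe_config()].
#' @return List with `theta` (n x 13) and `x` (n x 23, Z space).
#' @export
build_training_set <- function(lib, observations = NULL,
                               config = npe_config()) {
  z <- library_zscores(lib)
  rows <- attr(z, "rows")
  if (config$scheme == "standard") {
    attr(z, "rows") <- NULL
    return(list(theta = lib$theta[rows, , drop = FALSE], x = z))
  }
  if (is.null(observations) || nrow(observations) == 0)
    stop("scheme '", config$scheme, "' requires observations")
  k <- min(config$n_close, nrow(z))
  nn <- nearest_simulations(observations, lib, k = k)
  sel_rows <- sort(unique(unlist(lapply(nn, `[[`, "rows"))))
  idx <- match(sel_rows, rows)
  theta <- lib$theta[sel_rows, , drop = FALSE]
  x <- z[idx, , drop = FALSE]
  if (config$scheme == "best_euclidean")
    return(list(theta = theta, x = x))

  set.seed(config$seed + 1L)
  noisy_x <- x + matrix(rnorm(length(x), 0, config$sigma), nrow(x))
  if (config$scheme == "noise_ephys")
    return(list(theta = theta, x = noisy_x))
  if (config$scheme == "noise_ephys_params") {
    tc <- colMeans(lib$theta[rows, , drop = FALSE])
    ts <- apply(lib$theta[rows, , drop = FALSE], 2, sd)
    tz <- sweep(sweep(theta, 2, tc), 2, ts, "/")
    tz <- tz + matrix(rnorm(length(tz), 0, config$sigma), nrow(tz))
    th <- sweep(sweep(tz, 2, ts, "*"), 2, tc, "+")
    th <- pmin(pmax(th, matrix(lib$prior$lower, nrow(th), 13, byrow = TRUE)),
               matrix(lib$prior$upper, nrow(th), 13, byrow = TRUE))
    colnames(th) <- param_names()
    return(list(theta = th, x = noisy_x))
  }
  # augmentation: clean and noised copies concatenated
  list(theta = rbind(theta, theta), x = rbind(x, noisy_x))
}

#' Train a conditional density estimator q(theta | x)
#'
#' Maximizes the conditional log-likelihood of the parameters given the
#' summary statistics over the training pairs, with Adam, minibatches and
#' early stopping on a held-out validation split. Parameters are
#' standardized internally; reported densities include the (constant)
#' change-of-variables term, so they refer to original parameter units.
#'
#' @param pairs List with `theta` (n x D) and `x` (n x Dx) as produced by
#'   [build_training_set()].
#' @param config An [npe_config()].
#' @param prior Optional `prior_box`; posterior samples are clipped to it.
#' @param verbose Print per-epoch losses.
#' @return An object of class `npe_posterior`.
#' @export
train_npe <- function(pairs, config = npe_config(), prior = NULL,
                      verbose = FALSE) {
  theta <- as.matrix(pairs$theta); x <- as.matrix(pairs$x)
  stopifnot(nrow(theta) == nrow(x))
  if (nrow(theta) < config$min_pairs)
    stop("too few training pairs (", nrow(theta), " < ", config$min_pairs, ")")
  set.seed(config$seed)
  n <- nrow(theta)
  tc <- colMeans(theta); ts <- apply(theta, 2, sd)
  if (any(ts <= 0)) stop("degenerate parameter column (zero variance)")
  theta_z <- sweep(sweep(theta, 2, tc), 2, ts, "/")

  layout <- mdn_layout(D = ncol(theta), Dx = ncol(x), H = config$n_hidden,
                       K = config$n_components)
  par <- mdn_init(layout, theta_z, seed = config$seed)
  st <- adam_state(par)

  n_val <- max(1L, floor(config$val_frac * n))
  perm <- sample(n)
  val_i <- perm[seq_len(n_val)]; tr_i <- perm[-seq_len(n_val)]
  Xtr <- x[tr_i, , drop = FALSE]; Ttr <- theta_z[tr_i, , drop = FALSE]
  Xva <- x[val_i, , drop = FALSE]; Tva <- theta_z[val_i, , drop = FALSE]

  best <- list(loss = Inf, par = par)
  bad <- 0L; history <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(nrow(Xtr))
    bs <- config$batch_size
    for (b in seq(1, nrow(Xtr), by = bs)) {
      ii <- ord[b:min(b + bs - 1, nrow(Xtr))]
      g <- mdn_loss_grad(par, Xtr[ii, , drop = FALSE],
                         Ttr[ii, , drop = FALSE], layout)
      if (!is.finite(g$loss))
        stop("training diverged (non-finite loss at epoch ", epoch, ")")
      upd <- adam_step(par, g$grad, st, lr = config$lr)
      par <- upd$par; st <- upd$st
    }
    vl <- mdn_loss_grad(par, Xva, Tva, layout, want_grad = FALSE)$loss
    history <- c(history, vl)
    if (verbose) message(sprintf("epoch %3d  val loss %.4f", epoch, vl))
    if (is.finite(vl) && vl < best$loss - 1e-5) {
      best <- list(loss = vl, par = par); bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$patience) break
    }
  }
  structure(list(par = best$par, layout = layout, theta_center = tc,
                 theta_scale = ts, theta_names = colnames(theta),
                 prior = prior, config = config, val_loss = best$loss,
                 history = history, n_train = n),
            class = "npe_posterior")
}

#' @export
print.npe_posterior <- function(x, ...) {
  cat(sprintf(
    "<npe_posterior> scheme=%s sigma=%g | D=%d K=%d H=%d | %d pairs, val loss %.3f\n",
    x$config$scheme, x$config$sigma, x$layout$D, x$layout$K, x$layout$H,
    x$n_train, x$val_loss))
  invisible(x)
}

theta_to_z <- function(model, theta) {
  sweep(sweep(as.matrix(theta), 2, model$theta_center), 2, model$theta_scale, "/")
}
theta_from_z <- function(model, tz) {
  th <- sweep(sweep(tz, 2, model$theta_scale, "*"), 2, model$theta_center, "+")
  colnames(th) <- model$theta_names
  th
}

#' Posterior log-density log q(theta | x)
#'
#' @param model An `npe_posterior`.
#' @param theta Parameter matrix (rows) or single vector, original units.
#' @param x A single conditioning feature vector (Z space).
#' @return Numeric vector of log-densities (original parameter units).
#' @export
posterior_log_density <- function(model, theta, x) {
  theta <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1)
  if (!is.null(colnames(theta)) && !is.null(model$theta_names))
    theta <- theta[, model$theta_names, drop = FALSE]
  tz <- theta_to_z(model, theta)
  mp <- mdn_params_at(model, x)
  K <- model$layout$K; D <- model$layout$D
  lp <- matrix(0, nrow(tz), K)
  for (k in seq_len(K)) {
    ck <- mp$comps[[k]]
    E <- sweep(tz, 2, ck$mu)
    U <- E %*% ck$L
    lp[, k] <- log(mp$pi[k]) + sum(ck$dg) - 0.5 * D * log(2 * pi) -
      0.5 * rowSums(U^2)
  }
  logsumexp_rows(lp) - sum(log(model$theta_scale))
}

#' Draw posterior samples theta ~ q(theta | x)
#'
#' When the model carries a prior box, mass leaking outside the box is
#' handled by rejection (the draw is from the density truncated to the prior
#' support); if the acceptance rate is pathologically low the few remaining
#' draws are clipped to the box.
#'
#' @inheritParams posterior_log_density
#' @param n Number of draws.
#' @param seed Optional seed (sampling is deterministic given it).
#' @return Matrix `n x D` in original parameter units.
#' @export
posterior_sample <- function(model, x, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mp <- mdn_params_at(model, x)
  D <- model$layout$D
  draw <- function(m) {
    counts <- as.vector(stats::rmultinom(1, m, mp$pi))
    out <- matrix(0, m, D)
    pos <- 0L
    for (k in seq_along(counts)) {
      nk <- counts[k]
      if (nk == 0) next
      ck <- mp$comps[[k]]
      Z <- matrix(rnorm(nk * D), nk, D)
      Linv <- forwardsolve(ck$L, diag(D))
      out[pos + seq_len(nk), ] <- Z %*% Linv +
        matrix(ck$mu, nk, D, byrow = TRUE)
      pos <- pos + nk
    }
    theta_from_z(model, out[sample(m), , drop = FALSE])
  }
  if (is.null(model$prior)) return(draw(n))
  lo <- model$prior$lower; hi <- model$prior$upper
  acc <- matrix(NA_real_, 0, D)
  for (round in 1:20) {
    th <- draw(max(n - nrow(acc), 64L))
    ok <- rowSums(sweep(th, 2, lo, "<") | sweep(th, 2, hi, ">")) == 0
    acc <- rbind(acc, th[ok, , drop = FALSE])
    if (nrow(acc) >= n) break
  }
  if (nrow(acc) < n) {
    extra <- draw(n - nrow(acc))
    extra <- pmin(pmax(extra, matrix(lo, nrow(extra), D, byrow = TRUE)),
                  matrix(hi, nrow(extra), D, byrow = TRUE))
    acc <- rbind(acc, extra)
  }
  th <- acc[seq_len(n), , drop = FALSE]
  colnames(th) <- model$theta_names
  th
}

#' Maximum-a-posteriori estimate by sample argmax
#'
#' Draws `n_samples` from the posterior and returns the draw with the
#' highest estimated posterior density.
#'
#' @inheritParams posterior_sample
#' @param n_samples Number of posterior draws scanned (default 10000).
#' @return Named parameter vector.
#' @export
map_estimate <- function(model, x, n_samples = 10000, seed = NULL) {
  th <- posterior_sample(model, x, n_samples, seed = seed)
  ld <- posterior_log_density(model, th, x)
  th[which.max(ld), ]
}

#' Monte-Carlo posterior entropy score
#'
#' The negative mean posterior log-density over `n_draws` posterior samples,
#' a per-cell uncertainty score: broader posteriors score higher.
#'
#' @inheritParams posterior_sample
#' @param n_draws Number of draws (default 1000).
#' @return Numeric scalar.
#' @export
posterior_entropy <- function(model, x, n_draws = 1000, seed = NULL) {
  th <- posterior_sample(model, x, n_draws, seed = seed)
  -mean(posterior_log_density(model, th, x))
}

#' Evaluate posterior fits by re-simulation
#'
#' For each observation: simulate the MAP parameters and `n_post` random
#' posterior draws, extract features, and measure the Euclidean distance to
#' the observation in the library's Z space. Simulations with any undefined
#' feature count as fails and are excluded from distance means.
#'
#' @param model An `npe_posterior` (or the string `"prior"` for the
#'   prior-baseline row, sampling parameters from `lib$prior`).
#' @param observations Matrix of fully defined Z-scored observation features.
#' @param lib The `sim_library` providing standardizer, protocol and prior.
#' @param n_post Posterior draws per observation (0 omits those columns).
#' @param n_map_samples Draws used for the MAP argmax.
#' @param seed Integer seed.
#' @return List with `per_cell` (data frame) and `aggregate` (one-row data
#'   frame with `map_fail_pct`, `map_dist_mean`, `map_dist_sd`,
#'   `post_fail_pct`, `post_dist_mean`, `post_dist_sd`), plus `map_theta`.
#' @export
evaluate_fit <- function(model, observations, lib, n_post = 10,
                         n_map_samples = 10000, seed = 1) {
  stopifnot(is.matrix(observations))
  if (any(!is.finite(observations))) stop("observations must be fully defined")
  n_obs <- nrow(observations)
  set.seed(seed)
  prior_model <- identical(model, "prior")
  map_theta <- matrix(NA_real_, n_obs, 13,
                      dimnames = list(NULL, param_names()))
  rows <- vector("list", n_obs)
  for (i in seq_len(n_obs)) {
    x0 <- observations[i, ]
    if (prior_model) {
      nn <- nearest_simulations(x0, lib, k = 1)
      mtheta <- lib$theta[nn$rows[1], ]
      post <- if (n_post > 0) sample_prior(lib$prior, n_post) else NULL
    } else {
      mtheta <- map_estimate(model, x0, n_samples = n_map_samples)
      post <- if (n_post > 0) posterior_sample(model, x0, n_post) else NULL
    }
    map_theta[i, ] <- mtheta
    sims <- rbind(mtheta, post)
    res <- simulate_batch(sims, lib$protocol)
    dists <- rep(NA_real_, nrow(sims)); def <- logical(nrow(sims))
    for (j in seq_len(nrow(sims))) {
      tr <- structure(list(time = res$time, vm = res$vm[j, ],
                           protocol = lib$protocol, failed = res$failed[j]),
                      class = "voltage_trace")
      fv <- extract_features(tr, lib$protocol)
      tf <- transform_features(fv)
      if (all(is.finite(tf))) {
        def[j] <- TRUE
        zz <- apply_standardizer(tf, lib$std)
        dists[j] <- sqrt(sum((zz - x0)^2))
      }
    }
    rows[[i]] <- data.frame(
      cell = i,
      map_defined = def[1],
      map_distance = dists[1],
      post_fail_rate = if (n_post > 0) mean(!def[-1]) else NA_real_,
      post_distance = if (n_post > 0 && any(def[-1]))
        mean(dists[-1][def[-1]]) else NA_real_)
  }
  per_cell <- do.call(rbind, rows)
  aggregate <- data.frame(
    map_fail_pct = 100 * mean(!per_cell$map_defined),
    map_dist_mean = mean(per_cell$map_distance, na.rm = TRUE),
    map_dist_sd = sd(per_cell$map_distance, na.rm = TRUE),
    post_fail_pct = if (n_post > 0) 100 * mean(per_cell$post_fail_rate) else NA_real_,
    post_dist_mean = if (n_post > 0) mean(per_cell$post_distance, na.rm = TRUE) else NA_real_,
    post_dist_sd = if (n_post > 0) sd(per_cell$post_distance, na.rm = TRUE) else NA_real_)
  list(per_cell = per_cell, aggregate = aggregate, map_theta = map_theta)
}
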