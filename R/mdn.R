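# Conditional density estimator used for neural posterior estimation.
#
# A mixture-density network: a single-hidden-layer tanh network maps the
# summary-statistic vector x to the parameters of a full-covariance Gaussian
# mixture over (standardized) model parameters theta. Covariances are
# parameterized through the Cholesky factor L of the precision matrix
# (diagonal via exp), so log-densities are available in closed form:
#   log N(theta | mu, (L L^T)^-1) = sum(log diag L) - D/2 log(2 pi)
#                                   - 0.5 || L^T (theta - mu) ||^2.
# Training maximizes the conditional log-likelihood with Adam and early
# stopping on a validation split; gradients are hand-derived and verified
# against numerical differentiation in the test suite.

mdn_layout <- function(D, Dx, H, K) {
  npair <- D * (D - 1) / 2
  pairs <- which(lower.tri(matrix(0, D, D)), arr.ind = TRUE) # i > j
  list(D = D, Dx = Dx, H = H, K = K, npair = npair,
       pair_i = pairs[, 1], pair_j = pairs[, 2],
       n_out = K * (1 + 2 * D + npair),
       off_logit = 0L,
       off_mu = K,
       off_dg = K + K * D,
       off_od = K + 2 * K * D)
}

mdn_init <- function(layout, theta_z, seed = 1) {
  set.seed(seed)
  H <- layout$H; Dx <- layout$Dx; D <- layout$D; K <- layout$K
  W1 <- matrix(rnorm(H * Dx, sd = 1 / sqrt(Dx)), H, Dx)
  b1 <- rep(0, H)
  W2 <- matrix(rnorm(layout$n_out * H, sd = 0.01), layout$n_out, H)
  b2 <- rep(0, layout$n_out)
  # spread component means over the data
  anchors <- theta_z[sample(nrow(theta_z), K, replace = nrow(theta_z) < K), ,
                     drop = FALSE]
  for (k in seq_len(K)) b2[layout$off_mu + (k - 1) * D + seq_len(D)] <- anchors[k, ]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

# split the raw output matrix O (N x n_out) into mixture parameters for
# component k
mdn_split <- function(O, layout, k) {
  D <- layout$D
  list(mu = O[, layout$off_mu + (k - 1) * D + seq_len(D), drop = FALSE],
       dg = pmin(pmax(O[, layout$off_dg + (k - 1) * D + seq_len(D),
                        drop = FALSE], -8), 8),
       od = O[, layout$off_od + (k - 1) * layout$npair + seq_len(layout$npair),
              drop = FALSE])
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# Loss (mean negative conditional log-likelihood) and gradients.
mdn_loss_grad <- function(par, X, Theta, layout, want_grad = TRUE) {
  N <- nrow(X); D <- layout$D; K <- layout$K
  A <- tanh(X %*% t(par$W1) + matrix(par$b1, N, layout$H, byrow = TRUE))
  O <- A %*% t(par$W2) + matrix(par$b2, N, layout$n_out, byrow = TRUE)
  G <- O[, seq_len(K), drop = FALSE]
  logpi <- G - logsumexp_rows(G)

  logphi <- matrix(0, N, K)
  comp <- vector("list", K)
  for (k in seq_len(K)) {
    pk <- mdn_split(O, layout, k)
    E <- Theta - pk$mu
    Ld <- exp(pk$dg)
    U <- Ld * E
    for (p in seq_len(layout$npair)) {
      j <- layout$pair_j[p]; i <- layout$pair_i[p]
      U[, j] <- U[, j] + pk$od[, p] * E[, i]
    }
    logphi[, k] <- rowSums(pk$dg) - 0.5 * D * log(2 * pi) - 0.5 * rowSums(U^2)
    comp[[k]] <- list(E = E, Ld = Ld, U = U, od = pk$od, dg_raw = pk$dg)
  }
  logjoint <- logpi + logphi
  logp <- logsumexp_rows(logjoint)
  loss <- -mean(logp)
  if (!want_grad) return(list(loss = loss, logp = logp))

  R <- exp(logjoint - logp)            # responsibilities
  Pi <- exp(logpi)
  dO <- matrix(0, N, layout$n_out)
  dO[, seq_len(K)] <- Pi - R
  for (k in seq_len(K)) {
    ck <- comp[[k]]; w <- R[, k]
    # d(-logp)/dmu_i = -r * (L u)_i
    LU <- ck$Ld * ck$U
    for (p in seq_len(layout$npair)) {
      j <- layout$pair_j[p]; i <- layout$pair_i[p]
      LU[, i] <- LU[, i] + ck$od[, p] * ck$U[, j]
    }
    dO[, layout$off_mu + (k - 1) * D + seq_len(D)] <- -w * LU
    dO[, layout$off_dg + (k - 1) * D + seq_len(D)] <-
      -w * (1 - ck$U * ck$E * ck$Ld)
    dOd <- matrix(0, N, layout$npair)
    for (p in seq_len(layout$npair)) {
      j <- layout$pair_j[p]; i <- layout$pair_i[p]
      dOd[, p] <- w * ck$U[, j] * ck$E[, i]
    }
    dO[, layout$off_od + (k - 1) * layout$npair + seq_len(layout$npair)] <- dOd
  }
  dW2 <- crossprod(dO, A) / N
  db2 <- colMeans(dO)
  dA <- dO %*% par$W2
  dZ <- dA * (1 - A^2)
  dW1 <- crossprod(dZ, X) / N
  db1 <- colMeans(dZ)
  list(loss = loss,
       grad = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

adam_state <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0)
}

adam_step <- function(par, grad, st, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(par)) {
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * grad[[nm]]
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * grad[[nm]]^2
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, st = st)
}

# mixture parameters at a single conditioning vector x0
mdn_params_at <- function(model, x0) {
  layout <- model$layout
  x0 <- matrix(x0, nrow = 1)
  A <- tanh(x0 %*% t(model$par$W1) + model$par$b1)
  O <- A %*% t(model$par$W2) + model$par$b2
  K <- layout$K; D <- layout$D
  G <- O[1, seq_len(K)]
  pi_k <- exp(G - max(G)); pi_k <- pi_k / sum(pi_k)
  comps <- lapply(seq_len(K), function(k) {
    pk <- mdn_split(O, layout, k)
    L <- diag(as.numeric(exp(pk$dg)), D)
    for (p in seq_len(layout$npair))
      L[layout$pair_i[p], layout$pair_j[p]] <- pk$od[1, p]
    list(mu = as.numeric(pk$mu), L = L, dg = as.numeric(pk$dg))
  })
  list(pi = pi_k, comps = comps)
}
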