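# noiseless rank-2 ground truth: Y = X W0 V0' with 10 active genes of 100
make_lowrank_data <- function(n = 120, p = 100, q = 13, active = 10,
                              noise = 0, seed = 1) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n, p))
  W0 <- matrix(0, p, 2)
  W0[seq_len(active), ] <- matrix(rnorm(active * 2), active)
  V0 <- qr.Q(qr(matrix(rnorm(q * 2), q, 2)))
  Y <- X %*% W0 %*% t(V0) + matrix(rnorm(n * q, sd = noise), n)
  list(X = X, Y = Y, W0 = W0, V0 = V0, active = seq_len(active))
}

test_that("noiseless low-rank data is exactly recovered at small lambda", {
  d <- make_lowrank_data()
  fit <- fit_srrr(d$X, d$Y, rank = 2, lambda = 1e-4, alpha = 0.5)
  r2 <- r2_per_parameter(fit, d$X, d$Y)
  expect_gt(1 - sum((d$Y - predict(fit, d$X))^2) / sum(scale(d$Y, scale = FALSE)^2),
            0.999)
  expect_true(all(d$active %in% fit$selected))
  # decoder orthonormality
  expect_equal(crossprod(fit$V), diag(2), tolerance = 1e-8)
  # fitted encoder column space matches truth (principal angles ~ 0)
  sv <- svd(crossprod(qr.Q(qr(fit$W)), qr.Q(qr(d$W0))))$d
  expect_lt(max(acos(pmin(sv, 1))), 1e-3)
})

test_that("full shrinkage and pure ridge behave as expected", {
  d <- make_lowrank_data(noise = 0.5)
  lam <- srrr_lambda_path(d$X, d$Y, alpha = 0.5)
  fit <- fit_srrr(d$X, d$Y, rank = 2, lambda = lam[1] * 1.01, alpha = 0.5)
  expect_identical(length(fit$selected), 0L)
  p0 <- predict(fit, d$X)
  expect_equal(p0, matrix(colMeans(d$Y), nrow(d$Y), ncol(d$Y), byrow = TRUE),
               tolerance = 1e-10, ignore_attr = TRUE)
  # alpha = 0: ridge keeps every gene (no exact zeros)
  rfit <- fit_srrr(d$X, d$Y, rank = 2, lambda = 0.05, alpha = 0)
  expect_identical(length(rfit$selected), ncol(d$X))
})

test_that("objective is non-increasing across alternations", {
  d <- make_lowrank_data(noise = 0.5)
  fit <- fit_srrr(d$X, d$Y, rank = 2, lambda = 0.05, alpha = 0.5)
  expect_true(all(diff(fit$objective) <= 1e-8))
})

test_that("selected-gene count decreases weakly along the penalty path", {
  d <- make_lowrank_data(noise = 0.3)
  lam <- srrr_lambda_path(d$X, d$Y, alpha = 0.5, n_lambda = 12)
  counts <- integer(length(lam))
  W0 <- NULL; V0 <- NULL
  for (l in seq_along(lam)) {
    fit <- fit_srrr(d$X, d$Y, rank = 2, lambda = lam[l], alpha = 0.5,
                    W0 = W0, V0 = V0)
    W0 <- fit$W; V0 <- fit$V
    counts[l] <- length(fit$selected)
  }
  expect_true(all(diff(counts) >= 0))  # path runs from lambda_max downward
})

test_that("the inner group-elastic-net step agrees with glmnet", {
  skip_if_not_installed("glmnet")
  d <- make_lowrank_data(n = 80, p = 40, noise = 0.4, seed = 3)
  V <- d$V0
  Z <- d$Y %*% V
  lam <- 0.08; alpha <- 0.5
  W <- ephyslink:::srrr_w_step(scale(d$X, scale = FALSE),
                               scale(Z, scale = FALSE),
                               matrix(0, ncol(d$X), 2), lam, alpha,
                               colSums(scale(d$X, scale = FALSE)^2) / nrow(d$X))
  g <- glmnet::glmnet(d$X, Z, family = "mgaussian", alpha = alpha,
                      lambda = lam, standardize = FALSE, intercept = TRUE,
                      standardize.response = FALSE, thresh = 1e-12)
  Wg <- do.call(cbind, lapply(g$beta, function(b) as.numeric(b)))
  expect_equal(W, Wg, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("cross-validation behaves correctly on signal and noise", {
  d <- make_lowrank_data(n = 100, p = 60, noise = 0, seed = 5)
  lam <- srrr_lambda_path(d$X, d$Y, n_lambda = 8)
  cv <- cv_srrr(d$X, d$Y, lam, folds = 4, seed = 2)
  expect_gt(max(cv$r2_mean), 0.99)      # noiseless: CV R2 -> 1 at small lambda
  # pure-noise response: no lambda should look predictive
  set.seed(6)
  Ynull <- matrix(rnorm(100 * 13), 100)
  cvn <- cv_srrr(d$X, Ynull, srrr_lambda_path(d$X, Ynull, n_lambda = 8),
                 folds = 4, seed = 2)
  expect_lt(max(cvn$r2_mean), 0.05)
  # fold assignment is seed-stable
  cv2 <- cv_srrr(d$X, d$Y, lam, folds = 4, seed = 2)
  expect_equal(cv$r2_mean, cv2$r2_mean)
})

test_that("per-parameter R2 isolates a permuted column", {
  d <- make_lowrank_data(noise = 0.1, seed = 7)
  fit <- fit_srrr(d$X, d$Y, rank = 2, lambda = 1e-3)
  r2 <- r2_per_parameter(fit, d$X, d$Y)
  expect_true(all(r2 > 0.9))
  Yperm <- d$Y; Yperm[, 4] <- sample(Yperm[, 4])
  r2p <- r2_per_parameter(fit, d$X, Yperm)
  expect_lt(r2p[4], 0.2)
  expect_true(all(r2p[-4] > 0.9))
})

test_that("latent coordinates are the encoded expression", {
  d <- make_lowrank_data()
  fit <- fit_srrr(d$X, d$Y, rank = 2, lambda = 1e-3)
  lc <- latent_coords(fit, d$X)
  expect_identical(ncol(lc), 2L)
  expect_equal(lc, sweep(d$X, 2, fit$x_center) %*% fit$W)
  # duplicated cells coincide
  X2 <- rbind(d$X[1, ], d$X[1, ])
  lc2 <- latent_coords(fit, X2)
  expect_equal(lc2[1, ], lc2[2, ])
})

test_that("group comparison is zero at identity and one for a 1-sd shift", {
  set.seed(8)
  theta <- matrix(rnorm(60 * 13), 60, dimnames = list(NULL, param_names()))
  labels <- rep(c("a", "b", "c"), each = 20)
  expect_equal(group_compare(theta, theta, labels)$distance, 0)
  # single group, prediction shifted by one cohort sd in one parameter
  one <- rep("g", 60)
  pred <- theta; pred[, 2] <- pred[, 2] + sd(theta[, 2])
  expect_equal(group_compare(theta, pred, one)$distance, 1)
  # invariance to a common relabeling
  perm <- sample(c("a", "b", "c"))
  relab <- perm[match(labels, c("a", "b", "c"))]
  pred2 <- theta + 0.1
  expect_equal(group_compare(theta, pred2, labels)$distance,
               group_compare(theta, pred2, relab)$distance)
})

test_that("expression preprocessing is scale-invariant per cell", {
  set.seed(9)
  counts <- matrix(rpois(20 * 30, 5), 20, 30,
                   dimnames = list(NULL, paste0("g", 1:30)))
  counts[, 30] <- 0                      # zero-variance gene
  expect_warning(X <- preprocess_expression(counts), "zero-variance")
  expect_identical(ncol(X), 29L)
  expect_equal(unname(colMeans(X)), rep(0, 29), tolerance = 1e-12)
  # doubling a cell's library leaves its normalized row unchanged
  c2 <- counts; c2[1, ] <- counts[1, ] * 2
  suppressWarnings({
    X2 <- preprocess_expression(c2)
  })
  # compare against a reference recomputed with the same global scaling
  norm1 <- counts[1, 1:29] / sum(counts[1, ])
  norm2 <- c2[1, 1:29] / sum(c2[1, ])
  expect_equal(norm1, norm2)
  # identical cells give identical rows
  c3 <- counts; c3[2, ] <- c3[1, ]
  suppressWarnings(X3 <- preprocess_expression(c3))
  expect_equal(X3[1, ], X3[2, ])
})
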