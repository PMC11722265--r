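# Sparse reduced-rank regression: Y ~ X W V' with V orthonormal (q x rank)
# and a row-wise (per-gene) elastic-net penalty on W selecting genes:
#   1/(2n) ||Y - X W V'||_F^2 + lambda * sum_j ( alpha ||w_j||_2
#                                              + (1-alpha)/2 ||w_j||_2^2 ).
# Alternating optimization: given W, V solves the orthogonal Procrustes
# problem (SVD of Y'XW); given V, W solves a group-elastic-net regression of
# YV on X by block coordinate descent. Since the rank columns share the
# design matrix, each gene's block update has the closed form
#   w_j = soft(z_j; lambda*alpha) / (||x_j||^2/n + lambda*(1-alpha)),
# with z_j = x_j' R_j / n the block gradient at w_j = 0.

srrr_objective <- function(X, Y, W, V, lambda, alpha) {
  n <- nrow(X)
  fit <- sum((Y - X %*% W %*% t(V))^2) / (2 * n)
  rn <- sqrt(rowSums(W^2))
  fit + lambda * sum(alpha * rn + (1 - alpha) / 2 * rn^2)
}

# one block-coordinate-descent pass solving min_W 1/(2n)||Z - XW||^2 + pen(W)
srrr_w_step <- function(X, Z, W, lambda, alpha, cj, tol = 1e-8,
                        max_sweeps = 200) {
  n <- nrow(X); p <- ncol(X)
  R <- Z - X %*% W
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(p)) {
      wj <- W[j, ]
      zj <- crossprod(X[, j], R)[1, ] / n + cj[j] * wj
      nz <- sqrt(sum(zj^2))
      shrink <- max(0, 1 - lambda * alpha / nz)
      wj_new <- if (nz > 0) shrink * zj / (cj[j] + lambda * (1 - alpha)) else zj * 0
      dj <- wj_new - wj
      if (any(dj != 0)) {
        R <- R - outer(X[, j], dj)
        W[j, ] <- wj_new
        delta <- max(delta, max(abs(dj)))
      }
    }
    if (delta < tol) break
  }
  W
}

#' Fit a sparse reduced-rank regression of parameters on gene expression
#'
#' Predicts a (column-standardized) parameter matrix from gene expression
#' through a low-rank bottleneck: `Y ~ X W V'` with orthonormal decoder `V`
#' and a per-gene group elastic-net penalty on the encoder `W`, so that genes
#' are selected in or out of the model as whole rows.
#'
#' @param X Expression matrix, cells x genes (columns standardized).
#' @param Y Parameter matrix, cells x d (columns standardized).
#' @param rank Latent dimension (default 2).
#' @param lambda Penalty strength.
#' @param alpha Elastic-net mixing in (0, 1]; `alpha = 1` is the group lasso,
#'   `alpha = 0` pure ridge (no exact zeros). Default 0.5.
#' @param max_iter,tol Alternation cap and relative objective tolerance.
#' @param W0,V0 Optional warm starts.
#' @return Object of class `srrr_model` with `W` (genes x rank), `V`
#'   (d x rank, `V'V = I`), `selected` (gene indices with nonzero rows),
#'   `lambda`, `alpha`, `objective` (per-iteration trace), and the column
#'   centers used for prediction.
#' @export
fit_srrr <- function(X, Y, rank = 2, lambda = 0.1, alpha = 0.5,
                     max_iter = 200, tol = 1e-6, W0 = NULL, V0 = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  stopifnot(nrow(Y) == n)
  if (rank > min(p, q)) stop("rank exceeds min(genes, parameters)")
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  cj <- colSums(Xc^2) / n

  if (is.null(V0)) {
    B <- tryCatch(solve(crossprod(Xc) / n + 1e-3 * diag(p), crossprod(Xc, Yc) / n),
                  error = function(e) crossprod(Xc, Yc) / n)
    sv <- svd(Xc %*% B, nu = 0, nv = rank)
    V0 <- sv$v[, seq_len(rank), drop = FALSE]
  }
  V <- V0
  W <- if (is.null(W0)) matrix(0, p, rank) else W0
  obj <- srrr_objective(Xc, Yc, W, V, lambda, alpha)
  trace <- obj
  for (it in seq_len(max_iter)) {
    W <- srrr_w_step(Xc, Yc %*% V, W, lambda, alpha, cj)
    if (all(W == 0)) { trace <- c(trace, srrr_objective(Xc, Yc, W, V, lambda, alpha)); break }
    M <- crossprod(Yc, Xc %*% W)              # q x rank
    sv <- svd(M)
    V <- sv$u %*% t(sv$v)
    obj_new <- srrr_objective(Xc, Yc, W, V, lambda, alpha)
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) < tol * max(1, abs(obj))) { obj <- obj_new; break }
    obj <- obj_new
  }
  structure(list(W = W, V = V, lambda = lambda, alpha = alpha, rank = rank,
                 x_center = xc, y_center = yc,
                 selected = which(rowSums(W^2) > 0), objective = trace,
                 gene_names = colnames(X), param_names = colnames(Y)),
            class = "srrr_model")
}

#' @export
print.srrr_model <- function(x, ...) {
  cat(sprintf("<srrr_model> rank %d, lambda %.4g, alpha %.2f, %d genes selected\n",
              x$rank, x$lambda, x$alpha, length(x$selected)))
  invisible(x)
}

#' Predict parameters from expression with a fitted sRRR model
#' @param object An `srrr_model`.
#' @param X Expression matrix (same gene columns as in training).
#' @param ... Unused.
#' @return Predicted parameter matrix.
#' @export
predict.srrr_model <- function(object, X, ...) {
  Xc <- sweep(as.matrix(X), 2, object$x_center)
  P <- Xc %*% object$W %*% t(object$V)
  sweep(P, 2, object$y_center, "+")
}

#' Latent coordinates of cells in the sRRR bottleneck
#' @param model An `srrr_model`.
#' @param X Expression matrix.
#' @return Matrix cells x rank (`X W` on centered expression).
#' @export
latent_coords <- function(model, X) {
  sweep(as.matrix(X), 2, model$x_center) %*% model$W
}

#' Per-parameter predictive R-squared
#' @param model An `srrr_model`.
#' @param X,Y Expression and parameter matrices.
#' @return Named numeric vector, one R-squared per parameter column.
#' @export
r2_per_parameter <- function(model, X, Y) {
  Y <- as.matrix(Y)
  P <- predict(model, X)
  num <- colSums((Y - P)^2)
  den <- colSums(sweep(Y, 2, colMeans(Y))^2)
  stats::setNames(1 - num / den, colnames(Y))
}

#' Default log-spaced penalty path
#'
#' Starts at the smallest lambda for which the encoder is entirely zero and
#' descends over `n_lambda` log-spaced values.
#'
#' @param X,Y Centered-scale data matrices.
#' @param alpha Elastic-net mixing.
#' @param n_lambda Path length (default 50).
#' @param lambda_min_ratio Smallest lambda as a fraction of the maximum.
#' @return Decreasing numeric vector.
#' @export
srrr_lambda_path <- function(X, Y, alpha = 0.5, n_lambda = 50,
                             lambda_min_ratio = 1e-3) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  B <- tryCatch(solve(crossprod(Xc) / nrow(X) + 1e-3 * diag(ncol(X)),
                      crossprod(Xc, Yc) / nrow(X)),
                error = function(e) crossprod(Xc, Yc) / nrow(X))
  r <- min(2, ncol(Yc))
  sv <- svd(Xc %*% B, nu = 0, nv = r)
  V0 <- sv$v[, seq_len(r), drop = FALSE]
  Z <- Yc %*% V0
  lam_max <- max(sqrt(rowSums((crossprod(Xc, Z) / nrow(X))^2))) / max(alpha, 1e-3)
  exp(seq(log(lam_max), log(lam_max * lambda_min_ratio), length.out = n_lambda))
}

#' Cross-validated sRRR performance along a penalty path
#'
#' K-fold cross-validation; per lambda the held-out
#' `R^2 = 1 - ||Y - Yhat||^2 / ||Y - Ybar_train||^2` (overall, all parameter
#' columns pooled) and the number of selected genes in the training-fold
#' fits. Fits are warm-started down the path.
#'
#' @param X,Y Data matrices (cells x genes / cells x parameters).
#' @param lambda Penalty path (default [srrr_lambda_path()]).
#' @param alpha Elastic-net mixing.
#' @param rank Latent dimension.
#' @param folds Number of folds (default 10).
#' @param seed Seed fixing the fold assignment.
#' @return Data frame with columns `lambda`, `r2_mean`, `r2_sd`,
#'   `n_genes_mean`.
#' @export
cv_srrr <- function(X, Y, lambda = NULL, alpha = 0.5, rank = 2, folds = 10,
                    seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(lambda)) lambda <- srrr_lambda_path(X, Y, alpha)
  n <- nrow(X)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  r2 <- matrix(NA_real_, length(lambda), folds)
  ng <- matrix(NA_real_, length(lambda), folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    W0 <- NULL; V0 <- NULL
    for (l in seq_along(lambda)) {
      fit <- fit_srrr(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                      rank = rank, lambda = lambda[l], alpha = alpha,
                      W0 = W0, V0 = V0)
      W0 <- fit$W; V0 <- fit$V
      P <- predict(fit, X[te, , drop = FALSE])
      ybar <- colMeans(Y[tr, , drop = FALSE])
      sse <- sum((Y[te, , drop = FALSE] - P)^2)
      sst <- sum(sweep(Y[te, , drop = FALSE], 2, ybar)^2)
      r2[l, f] <- 1 - sse / sst
      ng[l, f] <- length(fit$selected)
    }
  }
  data.frame(lambda = lambda,
             r2_mean = rowMeans(r2), r2_sd = apply(r2, 1, sd),
             n_genes_mean = rowMeans(ng))
}

#' Compare group-averaged fitted and predicted parameter matrices
#'
#' Both matrices are Z-scored column-wise with the mean and standard
#' deviation of the *fitted* (MAP) cohort, averaged within groups, and
#' compared by the Euclidean (Frobenius) norm of their difference.
#'
#' @param theta_map Fitted parameter matrix (cells x d), the Z-scoring
#'   reference cohort.
#' @param theta_pred Predicted parameter matrix (same shape).
#' @param labels Group labels (length = number of cells).
#' @return List with `map_means`, `pred_means` (groups x d, Z units) and
#'   `distance`.
#' @export
group_compare <- function(theta_map, theta_pred, labels) {
  theta_map <- as.matrix(theta_map); theta_pred <- as.matrix(theta_pred)
  stopifnot(nrow(theta_map) == nrow(theta_pred),
            length(labels) == nrow(theta_map))
  m <- colMeans(theta_map); s <- apply(theta_map, 2, sd)
  if (any(s <= 0)) stop("degenerate parameter column in MAP cohort")
  zm <- sweep(sweep(theta_map, 2, m), 2, s, "/")
  zp <- sweep(sweep(theta_pred, 2, m), 2, s, "/")
  gm <- apply(zm, 2, function(col) tapply(col, labels, mean))
  gp <- apply(zp, 2, function(col) tapply(col, labels, mean))
  if (is.null(dim(gm))) { gm <- t(gm); gp <- t(gp) }
  list(map_means = gm, pred_means = gp,
       distance = sqrt(sum((gm - gp)^2)))
}

#' Preprocess a raw count matrix for the gene-linkage stage
#'
#' Library-size normalization (counts scaled to the median total count),
#' `log(1 + x)`, restriction to a gene subset (e.g. ion-channel and marker
#' genes), and per-gene Z-scoring. Genes with zero variance after transform
#' are dropped with a warning.
#'
#' @param counts Cells x genes count matrix with gene column names.
#' @param genes Optional character vector of genes to keep (subset applied
#'   after size normalization, so scaling uses the full library size).
#' @return Standardized expression matrix (cells x genes kept), with
#'   attributes `gene_means`, `gene_sds`.
#' @export
preprocess_expression <- function(counts, genes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("gene", seq_len(ncol(counts)))
  if (anyDuplicated(colnames(counts))) stop("gene names must be unique")
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("cells with zero total counts")
  norm <- counts / tot * median(tot)
  if (!is.null(genes)) {
    missing <- setdiff(genes, colnames(norm))
    if (length(missing)) stop("unknown genes: ", paste(head(missing), collapse = ", "))
    norm <- norm[, genes, drop = FALSE]
  }
  lg <- log1p(norm)
  mm <- colMeans(lg); ss <- apply(lg, 2, sd)
  drop <- ss <= 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance gene(s): ",
            paste(head(colnames(lg)[drop]), collapse = ", "))
    lg <- lg[, !drop, drop = FALSE]; mm <- mm[!drop]; ss <- ss[!drop]
  }
  out <- sweep(sweep(lg, 2, mm), 2, ss, "/")
  attr(out, "gene_means") <- mm
  attr(out, "gene_sds") <- ss
  out
}
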