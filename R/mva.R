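# Multivariate engine: NIPALS PCA and PLS1, goodness-of-fit and LOO
# cross-validation per dimensionality, PLS-DA cutoff estimation.
#
# Conventions fixed here and relied on everywhere else:
#   * autoscaling uses the sample SD (divisor n-1);
#   * LOO refits the scaling inside every fold, so the left-out sample never
#     leaks into the column means/scales;
#   * q2(A) = 1 - PRESS(A)/TSS with TSS about the FULL-data mean;
#   * SDEP(A) = sqrt(PRESS(A)/n), SDEC(A) = sqrt(RSS(A)/n).

NIPALS_TOL <- 1e-12
NIPALS_MAXIT <- 500L

#' Fit column scaling
#'
#' Centers and optionally autoscales a descriptor matrix. Autoscaling divides
#' by the sample standard deviation (divisor n-1).
#'
#' @param X numeric matrix (n x p)
#' @param mode one of "none", "center", "autoscale"
#' @return list with `Xs` (scaled matrix) and `state`, a `ScalingState`
#'   (`mode`, `means`, `scales`)
#' @export
#' @examples
#' s <- scale_fit(matrix(c(1, 3), ncol = 1), "center")
#' s$Xs  # -1, 1
scale_fit <- function(X, mode = c("autoscale", "center", "none")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (nrow(X) < 2L) qstop("scaling requires at least 2 rows")
  p <- ncol(X)
  means <- rep(0, p); scales <- rep(1, p)
  if (mode != "none") {
    means <- colMeans(X)
    if (mode == "autoscale") {
      scales <- apply(X, 2L, stats::sd)
      if (any(scales <= 0 | !is.finite(scales)))
        qstop("autoscale: zero-variance column(s) %s (mask them upstream)",
              paste(which(scales <= 0 | !is.finite(scales)), collapse = ","))
    }
  }
  state <- list(mode = mode, means = means, scales = scales)
  class(state) <- "ScalingState"
  list(Xs = scale_apply(X, state), state = state)
}

# Tolerant variant used inside cross-validation folds: a column that is
# constant within a fold (possible for count descriptors after leaving one
# sample out) gets scale 1; its centered values are all zero, so it is
# inert rather than an error.
scale_fit_tolerant <- function(X, mode) {
  if (mode != "autoscale") return(scale_fit(X, mode))
  X <- as.matrix(X)
  means <- colMeans(X)
  scales <- apply(X, 2L, stats::sd)
  scales[scales <= 0 | !is.finite(scales)] <- 1
  state <- list(mode = "autoscale", means = means, scales = scales)
  class(state) <- "ScalingState"
  list(Xs = scale_apply(X, state), state = state)
}

#' Apply a fitted scaling to new data
#' @param X numeric matrix with the same number of columns as the training set
#' @param state a `ScalingState` from [scale_fit()]
#' @return scaled matrix
#' @export
scale_apply <- function(X, state) {
  X <- as.matrix(X)
  if (ncol(X) != length(state$means)) qstop("scale_apply: dimension mismatch")
  if (state$mode == "none") return(X)
  sweep(sweep(X, 2L, state$means, "-"), 2L, state$scales, "/")
}

#' Invert a fitted scaling
#' @inheritParams scale_apply
#' @return matrix on the original scale
#' @export
scale_invert <- function(X, state) {
  X <- as.matrix(X)
  if (state$mode == "none") return(X)
  sweep(sweep(X, 2L, state$scales, "*"), 2L, state$means, "+")
}

# Core PLS1 NIPALS on centered data. Returns W, P (x-loadings), c
# (y-loadings), T (scores) and the per-dimensionality coefficient matrix
# b[, A] = W (P'W)^-1 c. Stops early when the X or y residual is numerically
# exhausted; the achieved number of components is `A`.
pls1_core <- function(Xs, ys, A_max) {
  n <- nrow(Xs); p <- ncol(Xs)
  if (A_max < 1L) qstop("A_max must be >= 1")
  A_max <- min(A_max, n - 1L, p)
  W <- matrix(0, p, A_max); P <- matrix(0, p, A_max)
  Tm <- matrix(0, n, A_max); cvec <- numeric(A_max)
  E <- Xs; f <- ys
  A <- 0L
  for (a in seq_len(A_max)) {
    # PLS1: w maximizes cov(Ew, f); converges in one pass, but we keep the
    # NIPALS iteration for uniformity with the multi-response formulation.
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14 * max(1, sqrt(sum(ys^2)))) break
    w <- w / nw
    for (it in seq_len(NIPALS_MAXIT)) {
      tvec <- E %*% w
      w_new <- crossprod(E, f)
      w_new <- w_new / sqrt(sum(w_new^2))
      if (max(abs(w_new - w)) < NIPALS_TOL) { w <- w_new; break }
      w <- w_new
    }
    tvec <- as.numeric(E %*% w)
    tt <- sum(tvec^2)
    if (tt < 1e-28) break
    cc <- sum(tvec * f) / tt
    pvec <- as.numeric(crossprod(E, tvec)) / tt
    E <- E - tcrossprod(tvec, pvec)
    f <- f - tvec * cc
    A <- a
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- tvec; cvec[a] <- cc
    if (sqrt(sum(f^2)) < 1e-12 * max(1, sqrt(sum(ys^2)))) break
  }
  if (A == 0L) qstop("PLS: no usable component (X'y numerically zero)")
  W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
  Tm <- Tm[, seq_len(A), drop = FALSE]; cvec <- cvec[seq_len(A)]
  # b for every truncation 1..A
  b <- matrix(0, p, A)
  for (a in seq_len(A)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    R <- Wa %*% solve(crossprod(Pa, Wa))
    b[, a] <- R %*% cvec[seq_len(a)]
  }
  list(W = W, P = P, c = cvec, T = Tm, b = b, A = A)
}

#' Fit a PLS1 model by NIPALS on pre-scaled data
#'
#' @param Xs centered (optionally autoscaled) descriptor matrix
#' @param ys centered response vector
#' @param A_max maximum number of latent variables; truncated to
#'   `min(n-1, p)` and further if the response is exhausted early
#' @return list with weights `W` (p x A), x-loadings `P`, y-loadings `c`,
#'   scores `T` (n x A), coefficients `b` (p x A; column A holds the
#'   A-component model) and the achieved dimensionality `A`
#' @export
fit_pls <- function(Xs, ys, A_max) {
  Xs <- as.matrix(Xs); ys <- as.numeric(ys)
  if (nrow(Xs) != length(ys)) qstop("fit_pls: X/y length mismatch")
  pls1_core(Xs, ys, A_max)
}

# Project query rows (already scaled) onto a fitted PLS structure.
# Returns scores (nq x A) and the X-residual matrix at full A.
pls_project <- function(Xq, fit) {
  R <- fit$W %*% solve(crossprod(fit$P, fit$W))
  Tq <- Xq %*% R
  E <- Xq - Tq %*% t(fit$P)
  list(T = Tq, E = E)
}

#' Leave-one-out cross-validation of a PLS model
#'
#' For each left-out sample the scaling and the PLS model are re-fitted on
#' the remaining n-1 samples and the sample is predicted at every
#' dimensionality.
#'
#' @param X raw (unscaled) descriptor matrix
#' @param y response vector
#' @param A_max maximum dimensionality; truncated to n-2 with a warning when
#'   `A_max >= n-1`
#' @param scaling_mode passed to [scale_fit()]
#' @return list with `q2`, `SDEP` (length-A vectors), `loo_pred` (n x A
#'   matrix of cross-validated predictions) and `A` (achieved dimensionality)
#' @export
loo_cv <- function(X, y, A_max, scaling_mode = "autoscale") {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) qstop("LOO cross-validation requires n >= 3")
  if (A_max >= n - 1L) {
    warning(sprintf("A_max truncated from %d to %d (n = %d)",
                    A_max, n - 2L, n), call. = FALSE)
    A_max <- n - 2L
  }
  A_max <- min(A_max, ncol(X))
  loo_pred <- matrix(NA_real_, n, A_max)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    sc <- scale_fit_tolerant(Xi, scaling_mode)
    ym <- mean(yi)
    fit <- pls1_core(sc$Xs, yi - ym, A_max)
    xq <- scale_apply(X[i, , drop = FALSE], sc$state)
    pred <- as.numeric(xq %*% fit$b) + ym
    Ai <- fit$A
    loo_pred[i, seq_len(Ai)] <- pred
    if (Ai < A_max) loo_pred[i, (Ai + 1L):A_max] <- pred[Ai]
  }
  tss <- sum((y - mean(y))^2)
  press <- colSums((loo_pred - y)^2)
  list(q2 = 1 - press / tss, SDEP = sqrt(press / n),
       loo_pred = loo_pred, A = A_max)
}

#' Select the optimal dimensionality
#'
#' Argmax of q2; ties resolved toward the smallest dimensionality.
#' @param q2 vector of cross-validated q2 per dimensionality
#' @return integer index of the chosen dimensionality
#' @export
select_A_opt <- function(q2) {
  if (length(q2) == 0L) qstop("select_A_opt: empty q2")
  which.max(q2)  # which.max returns the first maximum
}

#' Estimate the discriminant cutoff balancing sensitivity and specificity
#'
#' Candidate cutoffs are the midpoints of adjacent sorted unique scores. The
#' chosen cutoff minimizes |sensitivity - specificity|; ties are resolved by
#' maximizing sensitivity + specificity, then by the smaller cutoff.
#' Predicted class is 1 iff score >= cutoff.
#'
#' @param scores numeric scores (e.g., LOO predictions of a 0/1 response)
#' @param labels 0/1 class labels
#' @return list with `cutoff`, `sensitivity`, `specificity`
#' @export
estimate_cutoff <- function(scores, labels) {
  scores <- as.numeric(scores); labels <- as.numeric(labels)
  if (length(scores) != length(labels)) qstop("length mismatch")
  if (!all(labels %in% c(0, 1))) qstop("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    qstop("cutoff estimation requires both classes present")
  u <- sort(unique(scores))
  if (length(u) == 1L) cand <- u else cand <- (u[-1] + u[-length(u)]) / 2
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  best <- NULL
  for (ct in cand) {
    pred1 <- scores >= ct
    se <- sum(pred1 & labels == 1) / n1
    sp <- sum(!pred1 & labels == 0) / n0
    key <- c(abs(se - sp), -(se + sp), ct)
    if (is.null(best) ||
        key[1] < best$key[1] - 1e-12 ||
        (abs(key[1] - best$key[1]) <= 1e-12 && key[2] < best$key[2] - 1e-12) ||
        (abs(key[1] - best$key[1]) <= 1e-12 &&
         abs(key[2] - best$key[2]) <= 1e-12 && ct < best$cutoff)) {
      best <- list(cutoff = ct, sensitivity = se, specificity = sp, key = key)
    }
  }
  best$key <- NULL
  best
}

#' NIPALS principal component analysis
#'
#' @param Xs centered (optionally scaled) matrix
#' @param A number of components, at most `min(n-1, p)`
#' @return list with `scores` (n x A), `loadings` (p x A, orthonormal) and
#'   `explained` (fraction of total variance per component)
#' @export
fit_pca <- function(Xs, A) {
  Xs <- as.matrix(Xs)
  n <- nrow(Xs); p <- ncol(Xs)
  if (A > min(n - 1L, p)) qstop("fit_pca: A exceeds min(n-1, p)")
  total_ss <- sum(Xs^2)
  scores <- matrix(0, n, A); loadings <- matrix(0, p, A)
  expl <- numeric(A)
  E <- Xs
  for (a in seq_len(A)) {
    j <- which.max(apply(E, 2L, function(x) sum(x^2)))
    t_vec <- E[, j]
    if (sum(t_vec^2) < 1e-28) { A <- a - 1L; break }
    for (it in seq_len(NIPALS_MAXIT)) {
      p_vec <- as.numeric(crossprod(E, t_vec)) / sum(t_vec^2)
      p_vec <- p_vec / sqrt(sum(p_vec^2))
      t_new <- as.numeric(E %*% p_vec)
      if (max(abs(t_new - t_vec)) < NIPALS_TOL * max(1, max(abs(t_vec)))) {
        t_vec <- t_new; break
      }
      t_vec <- t_new
    }
    p_vec <- as.numeric(crossprod(E, t_vec)) / sum(t_vec^2)
    p_vec <- p_vec / sqrt(sum(p_vec^2))
    t_vec <- as.numeric(E %*% p_vec)
    E <- E - tcrossprod(t_vec, p_vec)
    scores[, a] <- t_vec; loadings[, a] <- p_vec
    expl[a] <- sum(t_vec^2) / total_ss
  }
  scores <- scores[, seq_len(A), drop = FALSE]
  loadings <- loadings[, seq_len(A), drop = FALSE]
  list(scores = scores, loadings = loadings, explained = expl[seq_len(A)])
}

#' Scatter plots of experimental vs recalculated and predicted values
#'
#' Writes two PNG files (`<path>_recalculated.png`, `<path>_predicted.png`)
#' with the identity line.
#'
#' @param y experimental values
#' @param y_recalc fitted (recalculated) values
#' @param y_pred cross-validated predictions
#' @param path file-path prefix for the two images
#' @return invisibly, the two file paths
#' @export
plot_fit <- function(y, y_recalc, y_pred, path) {
  if (length(y) == 0L) qstop("plot_fit: empty input")
  if (length(y_recalc) != length(y) || length(y_pred) != length(y))
    qstop("plot_fit: length mismatch")
  files <- paste0(path, c("_recalculated.png", "_predicted.png"))
  panels <- list(list(v = y_recalc, lab = "recalculated"),
                 list(v = y_pred, lab = "LOO predicted"))
  for (k in 1:2) {
    grDevices::png(files[k], width = 600, height = 600)
    graphics::plot(y, panels[[k]]$v, xlab = "experimental",
                   ylab = panels[[k]]$lab, pch = 19,
                   main = sprintf("experimental vs %s", panels[[k]]$lab))
    graphics::abline(0, 1, col = "grey40")
    grDevices::dev.off()
  }
  invisible(files)
}
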