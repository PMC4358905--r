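# Applicability-domain and reliability assessment.
#
# Six training-derived criteria, each thresholded at its 95th empirical
# percentile (linear interpolation between order statistics, R quantile
# type 7); the number of violated criteria (0-6) is the reliability
# category, mapped to a 95% CI half-width calibrated on the LOO residuals
# of the training compounds in that category.
#
# The six criteria, computed in the model's scaled descriptor space and
# A_opt-dimensional score space:
#   1. Euclidean distance to the descriptor-space centroid
#   2. distance to the nearest training neighbour, descriptor space
#   3. distance to the score-space centroid
#   4. distance to the nearest training neighbour, score space
#   5. DModX = sqrt(e'e / (p - A_opt)), e = X-residual after projection
#   6. SD of the activities of the k nearest score-space neighbours
# Neighbour-based criteria are self-excluded on the training set. This is
# a documented reconstruction at the granularity of the published method
# (six criteria, categories 0-6, 95th-percentile thresholds); it is not a
# reproduction of the original formulas, which are not printed here.

euclid_to <- function(M, v) sqrt(rowSums(sweep(M, 2L, v, "-")^2))

# nearest-neighbour distance of each row of Q against rows of M;
# self_index[i] > 0 excludes that row of M for query i
nn_dist <- function(Q, M, self_index = rep(0L, nrow(Q))) {
  vapply(seq_len(nrow(Q)), function(i) {
    d <- euclid_to(M, Q[i, ])
    if (self_index[i] > 0L) d <- d[-self_index[i]]
    min(d)
  }, numeric(1))
}

# SD of activities of the k nearest score-space neighbours
knn_act_sd <- function(Q, M, y, k, self_index = rep(0L, nrow(Q))) {
  vapply(seq_len(nrow(Q)), function(i) {
    d <- euclid_to(M, Q[i, ])
    yy <- y
    if (self_index[i] > 0L) { d <- d[-self_index[i]]; yy <- yy[-self_index[i]] }
    stats::sd(yy[order(d)[seq_len(k)]])
  }, numeric(1))
}

adan_criteria <- function(Xs, Tsc, state, self = FALSE) {
  n <- nrow(Xs)
  self_idx <- if (self) seq_len(n) else rep(0L, n)
  dmodx_den <- max(1L, ncol(Xs) - ncol(Tsc))
  E <- Xs - Tsc %*% t(state$P_opt)
  cbind(
    c1 = euclid_to(Xs, state$x_centroid),
    c2 = nn_dist(Xs, state$training_Xs, self_idx),
    c3 = euclid_to(Tsc, state$t_centroid),
    c4 = nn_dist(Tsc, state$training_T, self_idx),
    c5 = sqrt(rowSums(E^2) / dmodx_den),
    c6 = knn_act_sd(Tsc, state$training_T, state$training_y, state$k_nn,
                    self_idx)
  )
}

#' Fit the applicability-domain state on the training set
#'
#' Computes the six criterion values for every training compound
#' (self-excluded where a neighbour search is involved), sets each
#' threshold at the 95th percentile, assigns training categories and
#' calibrates per-category 95% CI half-widths from the LOO residuals
#' (fallback: 1.96 x global SDEP at A_opt for categories with fewer than 5
#' members).
#'
#' @param Xs scaled training descriptor matrix (model variable set)
#' @param Tsc training score matrix at A_opt
#' @param y training activities
#' @param P_opt x-loading matrix restricted to A_opt components
#' @param loo_resid LOO residuals at A_opt (length n)
#' @param sdep_opt global SDEP at A_opt
#' @param k_nn neighbours for the activity-SD criterion (default 5)
#' @return an `ADANState`
#' @export
fit_adan <- function(Xs, Tsc, y, P_opt, loo_resid, sdep_opt, k_nn = 5L) {
  Xs <- as.matrix(Xs); Tsc <- as.matrix(Tsc)
  n <- nrow(Xs)
  if (n < 10L) qstop("training series too small for ADAN (n >= 10 required)")
  if (k_nn > n - 1L) qstop("k_nn exceeds n - 1")
  state <- list(x_centroid = colMeans(Xs), t_centroid = colMeans(Tsc),
                training_Xs = Xs, training_T = Tsc, training_y = y,
                P_opt = as.matrix(P_opt), k_nn = as.integer(k_nn))
  crit <- adan_criteria(Xs, Tsc, state, self = TRUE)
  state$thresholds <- apply(crit, 2L, stats::quantile, probs = 0.95,
                            type = 7, names = FALSE)
  state$training_categories <- as.integer(
    rowSums(sweep(crit, 2L, state$thresholds, ">")))
  ci <- numeric(7)
  for (cat_i in 0:6) {
    members <- which(state$training_categories == cat_i)
    ci[cat_i + 1L] <- if (length(members) >= 5L)
      1.96 * sqrt(mean(loo_resid[members]^2))
    else 1.96 * sdep_opt
  }
  state$category_ci95 <- ci
  state$sdep_opt <- sdep_opt
  class(state) <- "ADANState"
  state
}

#' Assess the reliability category of a query
#'
#' @param x_query_scaled query descriptor row(s), aligned to the model's
#'   variable set and scaled with the model's scaling
#' @param t_query query score row(s) at A_opt
#' @param state an `ADANState`
#' @return integer vector of categories 0-6 (count of violated criteria)
#' @export
adan_assess <- function(x_query_scaled, t_query, state) {
  Xq <- if (is.matrix(x_query_scaled)) x_query_scaled
        else matrix(x_query_scaled, nrow = 1L)
  Tq <- if (is.matrix(t_query)) t_query else matrix(t_query, nrow = 1L)
  if (ncol(Xq) != ncol(state$training_Xs) ||
      ncol(Tq) != ncol(state$training_T) || nrow(Xq) != nrow(Tq))
    qstop("adan_assess: dimension mismatch")
  crit <- adan_criteria(Xq, Tq, state, self = FALSE)
  as.integer(rowSums(sweep(crit, 2L, state$thresholds, ">")))
}

#' 95% CI half-width for a reliability category
#'
#' @param category integer 0-6
#' @param state an `ADANState`
#' @return CI half-width (1.96 x category-calibrated RMSE, or 1.96 x global
#'   SDEP for sparse categories)
#' @export
adan_ci95 <- function(category, state) {
  if (any(category < 0L | category > 6L | is.na(category)))
    qstop("category must be in 0..6")
  state$category_ci95[category + 1L]
}
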