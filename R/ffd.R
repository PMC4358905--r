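# FFD variable selection: estimate each variable's effect on cross-validated
# error against dummy variables and prune variables whose presence worsens
# SDEP, following the GOLPE convention (dummies ~ 20% of the variables,
# effects compared to the mean absolute dummy effect).
#
# A true 2-level fractional factorial constrains the number of columns to
# specific sizes, so a seeded balanced random +/-1 design of the same shape
# is used instead (documented deviation). One selection pass only.

#' Build a balanced two-level design matrix
#'
#' R x (p + d) matrix of +1/-1 with every column balanced (R/2 of each
#' sign), reproducible from the seed.
#'
#' @param p number of real variables
#' @param d number of dummy variables
#' @param R number of design rows (must be even; `2 * (p + d)` recommended)
#' @param seed integer seed
#' @return design matrix of +1/-1
#' @export
build_design <- function(p, d, R, seed = 1) {
  if (R %% 2L != 0L) qstop("design size R must be even")
  if (d < 1L) qstop("at least one dummy variable required")
  with_seed(seed, {
    cols <- replicate(p + d, sample(rep(c(1, -1), R / 2)))
    matrix(cols, nrow = R, ncol = p + d)
  })
}

# Per-row LOO SDEP and difference-of-means effects for a given design.
# Split out of ffd_select so effects can be recomputed on modified designs.
ffd_effects <- function(X, y, A, design, d, scaling_mode = "autoscale") {
  n <- nrow(X); p <- ncol(X)
  R <- nrow(design)
  sdep_row <- numeric(R)
  for (r in seq_len(R)) {
    keep <- which(design[r, seq_len(p)] > 0)
    if (length(keep) == 0L) { sdep_row[r] <- NA_real_; next }
    Ar <- min(A, length(keep), n - 2L)
    cv <- loo_cv(X[, keep, drop = FALSE], y, Ar, scaling_mode)
    sdep_row[r] <- cv$SDEP[min(Ar, cv$A)]
  }
  ok <- !is.na(sdep_row)
  effect <- numeric(p + d)
  for (v in seq_len(p + d)) {
    incl <- ok & design[, v] > 0
    excl <- ok & design[, v] < 0
    effect[v] <- mean(sdep_row[excl]) - mean(sdep_row[incl])
  }
  list(sdep_row = sdep_row, effects = effect,
       dummy_effect_scale = mean(abs(effect[p + seq_len(d)])))
}

#' FFD variable selection
#'
#' For each design row a PLS model is fitted on the variables marked +1
#' (dummies occupy design columns but carry no data) and its LOO SDEP at
#' dimensionality `A` is recorded. The effect of a variable is the mean
#' SDEP over rows excluding it minus the mean over rows including it
#' (positive effect: the variable helps). A variable is removed iff its
#' effect is negative and exceeds `threshold_factor` times the mean
#' absolute dummy effect in magnitude. The model is refit on the retained
#' mask; if the refit q2 at `A` is lower than before, the original variable
#' set is kept (`applied = FALSE`).
#'
#' @param X raw descriptor matrix (n x p), p >= 4, n >= 5
#' @param y response vector
#' @param A dimensionality at which SDEP/q2 are evaluated
#' @param d number of dummy variables; default `max(1, round(p / 5))`
#' @param R number of design rows; default `2 * (p + d)`
#' @param threshold_factor dummy-effect multiplier (default 2.0)
#' @param seed integer seed for the design
#' @param scaling_mode passed to the LOO routine
#' @return an `FFDResult`: list with `design`, `effects`,
#'   `dummy_effect_scale`, `mask`, `q2_before`, `q2_after`, `applied`
#' @export
ffd_select <- function(X, y, A, d = max(1L, round(ncol(X) / 5)),
                       R = 2L * (ncol(X) + d), threshold_factor = 2.0,
                       seed = 1, scaling_mode = "autoscale") {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 4L) qstop("FFD selection requires at least 4 variables")
  if (n < 5L) qstop("FFD selection requires at least 5 samples")
  design <- build_design(p, d, R, seed)
  ef <- ffd_effects(X, y, A, design, d, scaling_mode)
  effect <- ef$effects
  dummy_scale <- ef$dummy_effect_scale
  remove <- effect[seq_len(p)] < 0 &
    abs(effect[seq_len(p)]) > threshold_factor * dummy_scale
  if (all(remove)) {
    warning("FFD flagged every variable; keeping the best-effect one",
            call. = FALSE)
    remove[which.max(effect[seq_len(p)])] <- FALSE
  }
  mask <- !remove
  A_full <- min(A, p, n - 2L)
  q2_before <- loo_cv(X, y, A_full, scaling_mode)$q2[A_full]
  A_red <- min(A, sum(mask), n - 2L)
  cv_after <- loo_cv(X[, mask, drop = FALSE], y, A_red, scaling_mode)
  q2_after <- cv_after$q2[min(A_red, cv_after$A)]
  applied <- q2_after >= q2_before
  if (!applied) mask <- rep(TRUE, p)
  structure(list(design = design, effects = effect[seq_len(p)],
                 dummy_effect_scale = dummy_scale, mask = mask,
                 q2_before = q2_before,
                 q2_after = if (applied) q2_after else q2_before,
                 applied = applied),
            class = "FFDResult")
}
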