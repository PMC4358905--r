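# Deterministic synthetic-fixture generators: latent-structure descriptor
# matrices and toy valence-legal SDF molecule sets with activities that are
# exact functions of the built-in descriptors. Everything is a pure
# function of its arguments (seed included).

#' Generate a latent-structure regression dataset
#'
#' X = (T + E) P', with T (n x k) standard-normal scores, E a small
#' within-subspace perturbation (SD 0.01) and P (p x k) random orthonormal
#' loadings; y = T beta + noise_sd * eps with beta = 1..k. The perturbation
#' is applied inside the latent subspace so X has exact rank k: the
#' response information beyond k components is nil by construction, which
#' is what makes the dimensionality of the generating process recoverable
#' (see the methods vignette for why an out-of-subspace perturbation would
#' destroy that property).
#'
#' @param n,p matrix dimensions
#' @param k number of latent factors, at most `min(n, p)`
#' @param noise_sd SD of the additive response noise
#' @param seed integer seed; same seed, same data, bit for bit
#' @return list with `X`, `y`, `scores` (T), `loadings` (P), `beta`
#' @export
gen_latent <- function(n, p, k, noise_sd = 0, seed = 1) {
  if (k > min(n, p)) qstop("k must be <= min(n, p)")
  with_seed(seed, {
    Tm <- matrix(stats::rnorm(n * k), n, k)
    P <- qr.Q(qr(matrix(stats::rnorm(p * k), p, k)))
    beta <- seq_len(k)
    X <- (Tm + 0.01 * matrix(stats::rnorm(n * k), n, k)) %*% t(P)
    y <- as.numeric(Tm %*% beta) + noise_sd * stats::rnorm(n)
    colnames(X) <- sprintf("V%02d", seq_len(p))
    list(X = X, y = y, scores = Tm, loadings = P, beta = beta)
  })
}

# Random valence-legal heavy-atom tree (optional single ring closure) over
# C/N/O/S. Returns the internal graph representation.
random_molecule_graph <- function() {
  n_atoms <- sample(3:12, 1L)
  pool <- c("C", "C", "C", "C", "N", "O", "S")  # carbon-rich, realistic-ish
  elem <- sample(pool, n_atoms, replace = TRUE)
  used <- integer(n_atoms)
  val <- as.integer(DEFAULT_VALENCE[elem])
  bonds <- matrix(0L, 0L, 3L, dimnames = list(NULL, c("a", "b", "order")))
  for (i in seq(2L, n_atoms)) {
    free <- which(seq_len(n_atoms) < i & used < val)
    if (length(free) == 0L) { n_atoms <- i - 1L; break }
    j <- if (length(free) == 1L) free else sample(free, 1L)
    bonds <- rbind(bonds, c(j, i, 1L))
    used[j] <- used[j] + 1L; used[i] <- used[i] + 1L
  }
  elem <- elem[seq_len(n_atoms)]
  used <- used[seq_len(n_atoms)]; val <- val[seq_len(n_atoms)]
  # one optional ring closure between non-adjacent atoms with free valence
  if (n_atoms >= 4L && stats::runif(1) < 0.3) {
    cand <- which(used < val)
    if (length(cand) >= 2L) {
      pairs <- utils::combn(cand, 2L)
      adjacent <- apply(pairs, 2L, function(pr)
        any(bonds[, 1] == pr[1] & bonds[, 2] == pr[2]) ||
        any(bonds[, 1] == pr[2] & bonds[, 2] == pr[1]))
      pairs <- pairs[, !adjacent, drop = FALSE]
      if (ncol(pairs) > 0L) {
        pick <- pairs[, sample.int(ncol(pairs), 1L)]
        bonds <- rbind(bonds, c(pick[1], pick[2], 1L))
      }
    }
  }
  xyz <- cbind(seq_len(n_atoms) * 1.0, rep(0, n_atoms), rep(0, n_atoms))
  list(elem = elem, xyz = xyz, bonds = bonds,
       header = c("", "  qsarkit synthetic", ""),
       n_atoms = n_atoms, n_bonds = nrow(bonds))
}

# Default activity rule: a fixed linear combination of built-in
# descriptors, so an end-to-end PLS build can reach r2 = 1 at noise 0.
default_activity_rule <- function(desc) {
  1.0 * desc[["n_C"]] + 2.0 * desc[["n_N"]] + 3.0 * desc[["n_O"]] +
    4.0 * desc[["n_S"]] + 0.5 * desc[["n_heavy"]] + 0.1 * desc[["wiener"]]
}

#' Generate a toy SDF molecule set with computable activities
#'
#' Writes `n` small valence-legal molecules (random trees over C/N/O/S,
#' 3-12 heavy atoms, optional one ring closure) as a V2000 SDF whose
#' `activity` field is `rule(built-in descriptors) + noise`.
#'
#' @param n number of molecules
#' @param seed integer seed
#' @param rule function(named descriptor vector) -> numeric activity;
#'   default: fixed linear combination of atom counts, heavy-atom count and
#'   Wiener index
#' @param noise_sd SD of additive activity noise (default 0)
#' @param path output SDF path (default: a tempfile)
#' @param activity_field data-field name to write (default "activity")
#' @return list with `path`, `activities` (ground truth, noise-free) and
#'   `records`
#' @export
gen_toy_sdf <- function(n, seed = 1, rule = default_activity_rule,
                        noise_sd = 0, path = tempfile(fileext = ".sdf"),
                        activity_field = "activity") {
  stopifnot(n >= 1L)
  with_seed(seed, {
    records <- vector("list", n)
    truth <- numeric(n)
    for (i in seq_len(n)) {
      g <- random_molecule_graph()
      g$header[1] <- sprintf("mol_%03d", i)
      rec <- new_molecule_record(paste(write_molblock(g), collapse = "\n"),
                                 name = g$header[1], list())
      desc <- compute_builtin(normalize_record(rec))
      truth[i] <- rule(desc)
      act <- truth[i] + noise_sd * stats::rnorm(1)
      rec$extra_fields[[activity_field]] <- sprintf("%.10f", act)
      records[[i]] <- rec
    }
    write_sdf(records, path)
    list(path = path, activities = truth, records = records)
  })
}

#' Generate a binary-class dataset for discriminant-mode tests
#'
#' Matrix mode: two Gaussian clouds in p-dimensional descriptor space whose
#' class means differ by `separation` standard deviations along a random
#' unit direction. SDF mode: toy molecules labelled by thresholding the
#' default activity rule at its median, discarding molecules within
#' `separation/2` rule-SDs of the threshold so the classes are separable in
#' descriptor space.
#'
#' @param n_per_class compounds per class (>= 5)
#' @param separation class-mean shift (matrix mode) or exclusion margin
#'   (SDF mode), in SD units
#' @param seed integer seed
#' @param format `"matrix"` or `"sdf"`
#' @param p number of descriptor columns (matrix mode)
#' @param path output SDF path (SDF mode)
#' @return matrix mode: list with `X`, `labels`; SDF mode: list with
#'   `path`, `labels`
#' @export
gen_da_set <- function(n_per_class, separation, seed = 1,
                       format = c("matrix", "sdf"), p = 10,
                       path = tempfile(fileext = ".sdf")) {
  format <- match.arg(format)
  if (n_per_class < 5L) qstop("n_per_class must be >= 5")
  if (format == "matrix") {
    return(with_seed(seed, {
      u <- stats::rnorm(p); u <- u / sqrt(sum(u^2))
      n <- 2L * n_per_class
      X <- matrix(stats::rnorm(n * p), n, p)
      labels <- rep(c(0, 1), each = n_per_class)
      X[labels == 1, ] <- X[labels == 1, ] +
        matrix(separation * u, n_per_class, p, byrow = TRUE)
      colnames(X) <- sprintf("V%02d", seq_len(p))
      list(X = X, labels = labels)
    }))
  }
  # SDF mode: oversample molecules, score by the default rule, keep the
  # n_per_class most extreme per side of the median
  with_seed(seed, {
    pool_n <- max(8L * n_per_class, 60L)
    recs <- vector("list", pool_n)
    score <- numeric(pool_n)
    for (i in seq_len(pool_n)) {
      g <- random_molecule_graph()
      g$header[1] <- sprintf("da_%03d", i)
      rec <- new_molecule_record(paste(write_molblock(g), collapse = "\n"),
                                 name = g$header[1], list())
      score[i] <- default_activity_rule(compute_builtin(normalize_record(rec)))
      recs[[i]] <- rec
    }
    med <- stats::median(score); s <- stats::sd(score)
    margin <- separation / 2 * s
    lo <- order(score)[seq_len(n_per_class)]
    hi <- order(score, decreasing = TRUE)[seq_len(n_per_class)]
    if (separation > 0 &&
        (max(score[lo]) > med - margin || min(score[hi]) < med + margin))
      warning("requested separation not fully achieved in SDF mode",
              call. = FALSE)
    keep <- c(lo, hi)
    labels <- rep(c(0, 1), each = n_per_class)
    out <- vector("list", length(keep))
    for (j in seq_along(keep)) {
      rec <- recs[[keep[j]]]
      rec$extra_fields[["activity"]] <- as.character(labels[j])
      out[[j]] <- rec
    }
    write_sdf(out, path)
    list(path = path, labels = labels)
  })
}
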