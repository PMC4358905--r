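# Shared fixtures and independent oracles. The oracle implementations are
# deliberately written from first principles (SVD pseudo-inverse, explicit
# per-fold loops, exhaustive scans) so they share no code path with the
# engine they check.

mk_molblock <- function(name, elems, bonds) {
  # bonds: matrix/list of c(a, b, order)
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    matrix(0L, 0L, 3L)
  lines <- c(name, "  fixture", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     length(elems), nrow(bonds)),
             vapply(seq_along(elems), function(i)
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0", i * 1.0, 0, 0,
                       elems[i]), character(1)),
             if (nrow(bonds)) vapply(seq_len(nrow(bonds)), function(i)
               sprintf("%3d%3d%3d  0", bonds[i, 1], bonds[i, 2],
                       bonds[i, 3]), character(1)),
             "M  END")
  paste(lines, collapse = "\n")
}

mk_record <- function(name, elems, bonds, fields = list()) {
  rec <- list(mol_text = mk_molblock(name, elems, bonds), name = name,
              activity_raw = NA_character_, extra_fields = fields,
              structure_key = NA_character_)
  class(rec) <- "MoleculeRecord"
  rec
}

ethanol_rec <- function(fields = list())
  mk_record("ethanol", c("C", "C", "O"),
            list(c(1L, 2L, 1L), c(2L, 3L, 1L)), fields)

benzene_rec <- function()
  mk_record("benzene", rep("C", 6),
            list(c(1L, 2L, 4L), c(2L, 3L, 4L), c(3L, 4L, 4L),
                 c(4L, 5L, 4L), c(5L, 6L, 4L), c(6L, 1L, 4L)))

# sodium acetate: CH3-COO(-) . Na(+), two fragments
sodium_acetate_rec <- function()
  mk_record("sodium acetate", c("C", "C", "O", "O", "Na"),
            list(c(1L, 2L, 1L), c(2L, 3L, 2L), c(2L, 4L, 1L)))

write_fixture_sdf <- function(records, activities = NULL,
                              field = "activity",
                              path = tempfile(fileext = ".sdf")) {
  if (!is.null(activities))
    for (i in seq_along(records))
      records[[i]]$extra_fields[[field]] <- as.character(activities[i])
  qsarkit:::write_sdf(records, path)
  path
}

# random permutation of the atom order of a mol block, rewritten as V2000
permute_molblock <- function(mol_text, perm) {
  g <- qsarkit:::parse_molblock(strsplit(mol_text, "\n")[[1]])
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  g2 <- g
  g2$elem <- g$elem[perm]
  g2$xyz <- g$xyz[perm, , drop = FALSE]
  if (nrow(g$bonds)) {
    g2$bonds[, 1] <- inv[g$bonds[, 1]]
    g2$bonds[, 2] <- inv[g$bonds[, 2]]
  }
  paste(qsarkit:::write_molblock(g2), collapse = "\n")
}

# --- independent oracles ----------------------------------------------------

# least squares via SVD pseudo-inverse (oracle for PLS at full rank)
ols_oracle <- function(Xs, ys) {
  sv <- svd(Xs)
  pos <- sv$d > max(sv$d) * 1e-12
  as.numeric(sv$v[, pos, drop = FALSE] %*%
               ((t(sv$u[, pos, drop = FALSE]) %*% ys) / sv$d[pos]))
}

# minimal PLS1 written independently: classic deflation, no shared code
pls1_oracle_coef <- function(Xs, ys, A) {
  p <- ncol(Xs)
  W <- matrix(0, p, A); P <- matrix(0, p, A); q <- numeric(A)
  E <- Xs; f <- ys
  for (a in 1:A) {
    w <- t(E) %*% f
    w <- w / sqrt(sum(w * w))
    t_ <- E %*% w
    q[a] <- sum(t_ * f) / sum(t_ * t_)
    p_ <- t(E) %*% t_ / sum(t_ * t_)
    E <- E - t_ %*% t(p_)
    f <- f - q[a] * t_
    W[, a] <- w; P[, a] <- p_
  }
  W %*% solve(t(P) %*% W, q)
}

# brute-force LOO: an explicit per-fold loop around the independent PLS1
loo_oracle <- function(X, y, A) {
  n <- nrow(X)
  pred <- matrix(NA_real_, n, A)
  for (i in 1:n) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    mu <- colMeans(Xi); sg <- apply(Xi, 2, sd)
    sg[sg <= 0] <- 1
    Zs <- sweep(sweep(Xi, 2, mu), 2, sg, "/")
    zq <- (X[i, ] - mu) / sg
    for (a in 1:A) {
      b <- pls1_oracle_coef(Zs, yi - mean(yi), a)
      pred[i, a] <- sum(zq * b) + mean(yi)
    }
  }
  tss <- sum((y - mean(y))^2)
  press <- colSums((pred - y)^2)
  list(q2 = 1 - press / tss, SDEP = sqrt(press / n), pred = pred)
}

# exhaustive midpoint-scan cutoff oracle
cutoff_oracle <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- if (length(u) == 1) u else (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (ct in cand) {
    se <- mean(scores[labels == 1] >= ct)
    sp <- mean(scores[labels == 0] < ct)
    rec <- list(cutoff = ct, se = se, sp = sp)
    better <- FALSE
    if (is.null(best)) better <- TRUE
    else {
      d1 <- abs(se - sp); d0 <- abs(best$se - best$sp)
      if (d1 < d0 - 1e-12) better <- TRUE
      else if (abs(d1 - d0) <= 1e-12) {
        s1 <- se + sp; s0 <- best$se + best$sp
        if (s1 > s0 + 1e-12) better <- TRUE
        else if (abs(s1 - s0) <= 1e-12 && ct < best$cutoff) better <- TRUE
      }
    }
    if (better) best <- rec
  }
  best
}

with_seed_rnorm <- function(seed, n) {
  set.seed(13L * seed + 1L)
  rnorm(n)
}

# run fn(root) against a throw-away model store
with_store <- function(fn) {
  root <- tempfile("store")
  dir.create(root)
  on.exit(unlink(root, recursive = TRUE))
  fn(root)
}
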