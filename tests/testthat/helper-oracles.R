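# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive alternative route: closed forms, double loops, grid
# searches, or a different algorithm for the same quantity.

# Horn's quaternion method for the minimized superposition RMSD: an
# eigenvalue route independent of the SVD-based Kabsch implementation.
quaternion_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  S <- t(P) %*% Q
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz
  ), nrow = 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

# Exhaustive all-pairs contact scan (the O(N^2) reference for the grid).
brute_force_contacts <- function(A, B, cutoff) {
  hits <- data.frame(ia = integer(0), ja = integer(0))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      if (sqrt(sum((A[i, ] - B[j, ])^2)) <= cutoff) {
        hits <- rbind(hits, data.frame(ia = i, ja = j))
      }
    }
  }
  hits
}

# Direct double-loop nonbonded sums.
brute_force_energy <- function(xyzA, xyzB, qA, qB, epsA, epsB, rminA, rminB,
                               k = 332.0636, cutoff = NULL) {
  e_elec <- 0
  e_vdw <- 0
  for (i in seq_len(nrow(xyzA))) {
    for (j in seq_len(nrow(xyzB))) {
      r <- sqrt(sum((xyzA[i, ] - xyzB[j, ])^2))
      if (!is.null(cutoff) && r > cutoff) next
      e_elec <- e_elec + k * qA[i] * qB[j] / r
      eps <- sqrt(epsA[i] * epsB[j])
      rmin <- rminA[i] / 2 + rminB[j] / 2
      e_vdw <- e_vdw + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    }
  }
  c(e_elec = e_elec, e_vdw = e_vdw)
}

# Iteratively refined grid search for the chi-square scale coefficient.
grid_search_scale <- function(Ic, Ie, sigma, n_grid = 1e4, n_stages = 4) {
  chi2_of <- function(cc) sum(((Ie - cc * Ic) / sigma)^2)
  lo <- 0
  hi <- 4 * max(abs(Ie)) / max(abs(Ic))
  best <- NA
  for (s in seq_len(n_stages)) {
    grid <- seq(lo, hi, length.out = n_grid)
    vals <- vapply(grid, chi2_of, numeric(1))
    k <- which.min(vals)
    best <- grid[k]
    step <- grid[2] - grid[1]
    lo <- best - 2 * step
    hi <- best + 2 * step
  }
  best
}

# Literal double-loop NSD (same definition, naive nearest-neighbour loops).
double_loop_nsd <- function(A, B) {
  nn_to <- function(X, Y) {
    sapply(seq_len(nrow(X)), function(i) {
      min(sapply(seq_len(nrow(Y)), function(j) sum((X[i, ] - Y[j, ])^2)))
    })
  }
  spacing <- function(X) {
    mean(sapply(seq_len(nrow(X)), function(i) {
      sqrt(min(sapply(setdiff(seq_len(nrow(X)), i), function(j) {
        sum((X[i, ] - X[j, ])^2)
      })))
    }))
  }
  sqrt(0.5 * (mean(nn_to(A, B)) / spacing(B)^2 +
                mean(nn_to(B, A)) / spacing(A)^2))
}

# Closed-form pooled-variance two-sample t-test (textbook formulas).
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tstat, p = 2 * pt(-abs(tstat), na + nb - 2))
}

# Uniform bead sampling of a solid ball (for sphere fixtures in tests).
ball_beads <- function(n, radius, seed) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(3 * n), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    v * radius * runif(n)^(1 / 3)
  })
}

beads_structure <- function(beads, chain = "A") {
  structure_model(data.frame(
    serial = seq_len(nrow(beads)), name = "CA", element = "C",
    chain = chain, resno = seq_len(nrow(beads)), resname = "ALA",
    x = beads[, 1], y = beads[, 2], z = beads[, 3], mass = 1,
    stringsAsFactors = FALSE
  ))
}

# Random rigid transform (proper rotation + translation).
random_rigid <- function(seed) {
  withr::with_seed(seed, {
    M <- matrix(rnorm(9), 3)
    s <- svd(M)
    R <- s$u %*% t(s$v)
    if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
    list(R = R, t = rnorm(3, sd = 10))
  })
}
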