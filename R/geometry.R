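# Rigid-body superposition, composite-model grafting, and the angle
# statistics used to compare crosslinker rigidity.

#' Mass-weighted center of mass
#'
#' @param structure a `structure_model`.
#' @param selection optional [select_atoms()] selection (default: all atoms).
#' @param xyz optional replacement coordinate matrix (e.g. one trajectory
#'   frame) congruent with the structure's atom table.
#' @return numeric length-3 vector (Angstrom).
#' @export
center_of_mass <- function(structure, selection = NULL, xyz = NULL) {
  idx <- if (is.null(selection)) seq_len(n_atoms(structure)) else selection$indices
  m <- atom_masses(structure, idx)
  if (sum(m) <= 0) stop("zero total mass in selection")
  p <- if (is.null(xyz)) coords(structure) else as.matrix(xyz)
  p <- p[idx, , drop = FALSE]
  as.numeric(colSums(p * m) / sum(m))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing the (weighted)
#' RMSD between `R %*% mobile + t` and `reference`. The reflection branch of
#' the SVD solution is corrected so that det(R) = +1. Degenerate inputs
#' (fewer than 3 points, or collinear point sets, for which the rotation is
#' not unique) are rejected.
#'
#' @param mobile,reference n x 3 coordinate matrices (Angstrom), equal n >= 3.
#' @param weights optional non-negative per-point weights.
#' @return An object of class `fit_result` with fields `rotation` (3x3,
#'   det +1), `translation` (length 3, Angstrom), `rmsd` (Angstrom, the
#'   minimized value) and `n_atoms`.
#' @export
kabsch_fit <- function(mobile, reference, weights = NULL) {
  P <- as.matrix(mobile)
  Q <- as.matrix(reference)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3) {
    stop("mobile and reference must be equal-size n x 3 matrices")
  }
  n <- nrow(P)
  if (n < 3) stop("kabsch_fit needs at least 3 points")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) == 0) {
    stop("weights must be non-negative with positive sum")
  }
  w <- w / sum(w)
  cP <- colSums(P * w)
  cQ <- colSums(Q * w)
  Pc <- sweep(P, 2, cP)
  Qc <- sweep(Q, 2, cQ)
  # collinearity check: second singular value of the centered reference
  if (svd(Qc, nu = 0, nv = 0)$d[2] < 1e-8 || svd(Pc, nu = 0, nv = 0)$d[2] < 1e-8) {
    stop("degenerate (collinear) point set: rotation not uniquely determined")
  }
  H <- t(Pc) %*% (Qc * w)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  tr <- cQ - as.numeric(R %*% cP)
  fitted <- sweep(P %*% t(R), 2, tr, "+")
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  out <- list(rotation = R, translation = tr, rmsd = rmsd, n_atoms = n)
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d atoms, rmsd %.4f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a rigid-body fit to coordinates
#' @param xyz n x 3 matrix (Angstrom).
#' @param fit a [kabsch_fit()] result.
#' @return transformed n x 3 matrix.
#' @export
apply_fit <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Graft a ligand structure onto a target via shared atoms
#'
#' Superposes the ligand's shared atoms onto the target's shared atoms
#' (Kabsch fit) and transforms the whole ligand accordingly. The assembled
#' structure is the target plus the transformed ligand with the ligand's
#' shared atoms dropped (the target's copies are kept). A warning is emitted
#' when the fit RMSD exceeds `rmsd_warn` (default 1.8 Angstrom, the quality
#' bound used for receptor-crosslinker assembly). Steric clashes between the
#' two bodies (any inter-body distance below `clash_cutoff`) are reported via
#' `message()`, not as an error.
#'
#' @param target,ligand `structure_model` objects.
#' @param shared_target,shared_ligand equal-length [select_atoms()] selections
#'   pairing the shared atoms (same order).
#' @param rmsd_warn RMSD warning threshold (Angstrom).
#' @param clash_cutoff inter-body clash distance (Angstrom).
#' @return list with `structure` (the assembly) and `fit` (the `fit_result`).
#' @export
graft_structure <- function(target, ligand, shared_target, shared_ligand,
                            rmsd_warn = 1.8, clash_cutoff = 1.0) {
  it <- shared_target$indices
  il <- shared_ligand$indices
  if (length(it) != length(il)) {
    stop("shared selections must pair equal numbers of atoms")
  }
  fit <- kabsch_fit(coords(ligand)[il, , drop = FALSE],
                    coords(target)[it, , drop = FALSE])
  if (fit$rmsd > rmsd_warn) {
    warning(sprintf("graft RMSD %.2f A exceeds %.2f A", fit$rmsd, rmsd_warn))
  }
  lig <- set_coords(ligand, apply_fit(coords(ligand), fit))
  keep <- setdiff(seq_len(n_atoms(lig)), il)
  lat <- lig$atoms[keep, , drop = FALSE]
  tat <- target$atoms
  lat$serial <- max(tat$serial) + seq_len(nrow(lat))
  out <- structure_model(rbind(tat, lat),
                         title = paste(target$title, "+", ligand$title))
  d2min <- min_cross_dist2(as.matrix(tat[, c("x", "y", "z")]),
                           as.matrix(lat[, c("x", "y", "z")]))
  if (d2min < clash_cutoff^2) {
    message(sprintf("graft clash: inter-body contact at %.2f A (< %.2f A)",
                    sqrt(d2min), clash_cutoff))
  }
  list(structure = out, fit = fit)
}

# smallest squared distance between two coordinate sets, blocked to bound memory
min_cross_dist2 <- function(A, B, block = 2000L) {
  best <- Inf
  for (i0 in seq(1, nrow(A), by = block)) {
    ia <- i0:min(i0 + block - 1, nrow(A))
    a2 <- rowSums(A[ia, , drop = FALSE]^2)
    for (j0 in seq(1, nrow(B), by = block)) {
      jb <- j0:min(j0 + block - 1, nrow(B))
      b2 <- rowSums(B[jb, , drop = FALSE]^2)
      d2 <- outer(a2, b2, "+") -
        2 * A[ia, , drop = FALSE] %*% t(B[jb, , drop = FALSE])
      best <- min(best, min(d2))
    }
  }
  max(best, 0)
}

# angle between two vectors in degrees, clamped into [0, 180]
vec_angle_deg <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) stop("zero-length vector in angle computation")
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Fab-Fab angle from domain center-of-mass vectors
#'
#' Each Fab is described by a constant-domain and a variable-domain
#' definition; the Fab axis is the vector from the constant-domain center of
#' mass to the variable-domain center of mass. The Fab-Fab angle is the
#' unsigned angle between the two axes, in [0, 180] degrees.
#'
#' @param structure a `structure_model`.
#' @param fab1,fab2 lists with elements `constant` and `variable`, each a
#'   [domain_definition()].
#' @param xyz optional replacement coordinates (one trajectory frame).
#' @return angle in degrees.
#' @export
fab_fab_angle <- function(structure, fab1, fab2, xyz = NULL) {
  axis_of <- function(fab) {
    c1 <- center_of_mass(structure, select_atoms(structure, domain = fab$constant),
                         xyz = xyz)
    c2 <- center_of_mass(structure, select_atoms(structure, domain = fab$variable),
                         xyz = xyz)
    c2 - c1
  }
  vec_angle_deg(axis_of(fab1), axis_of(fab2))
}

#' Per-frame Fab-Fab angle series with windowed summary
#'
#' Computes the [fab_fab_angle()] for every trajectory frame and summarizes
#' mean, standard deviation (n-1 denominator) and range (max - min) over the
#' frames whose timestamps fall inside `window_ns` (both endpoints
#' inclusive). Windows extending beyond the trajectory are clamped with a
#' warning.
#'
#' @param trajectory an `md_trajectory`.
#' @param fab1,fab2 Fab domain definitions, as for [fab_fab_angle()].
#' @param window_ns length-2 numeric, summary window in ns (default 20-100).
#' @return data.frame of class `angle_series` with columns `time_ns`,
#'   `angle_deg`; the summary (mean, sd, range, n, window) in attribute
#'   `summary`.
#' @export
angle_series <- function(trajectory, fab1, fab2, window_ns = c(20, 100)) {
  st <- trajectory$structure
  sel <- list(
    c1 = select_atoms(st, domain = fab1$constant),
    v1 = select_atoms(st, domain = fab1$variable),
    c2 = select_atoms(st, domain = fab2$constant),
    v2 = select_atoms(st, domain = fab2$variable)
  )
  m <- lapply(sel, function(s) atom_masses(st, s$indices))
  com <- function(f, s, mm) colSums(f[s$indices, , drop = FALSE] * mm) / sum(mm)
  ang <- vapply(trajectory$frames, function(f) {
    v1 <- com(f, sel$v1, m$v1) - com(f, sel$c1, m$c1)
    v2 <- com(f, sel$v2, m$v2) - com(f, sel$c2, m$c2)
    vec_angle_deg(v1, v2)
  }, numeric(1))
  t <- trajectory$times_ns
  w <- sort(as.numeric(window_ns))
  if (w[1] < min(t) || w[2] > max(t)) {
    w <- c(max(w[1], min(t)), min(w[2], max(t)))
    warning(sprintf("summary window clamped to trajectory span: %.3g-%.3g ns",
                    w[1], w[2]))
  }
  inw <- t >= w[1] & t <= w[2]
  if (sum(inw) < 2) stop("fewer than 2 frames in summary window: SD undefined")
  out <- data.frame(time_ns = t, angle_deg = ang)
  attr(out, "summary") <- list(
    mean = mean(ang[inw]), sd = stats::sd(ang[inw]),
    range = max(ang[inw]) - min(ang[inw]), n = sum(inw), window_ns = w
  )
  class(out) <- c("angle_series", "data.frame")
  out
}

#' Summary of an angle series
#' @param object an `angle_series`.
#' @param ... unused.
#' @return list with `mean`, `sd`, `range` (degrees), `n`, `window_ns`.
#' @export
summary.angle_series <- function(object, ...) attr(object, "summary")

#' Two-sample t-test on per-model angle standard deviations
#'
#' Compares the windowed Fab-Fab angle SDs of two groups of models with a
#' two-tailed two-sample t-test (equal-variance pooled by default; set
#' `welch = TRUE` for the Welch correction).
#'
#' @param group_a,group_b numeric vectors of per-model SDs (degrees), each of
#'   length >= 2.
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @param welch use the Welch unequal-variance test.
#' @export
compare_angle_sd <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values")
  }
  res <- tryCatch(
    stats::t.test(group_a, group_b, var.equal = !welch),
    error = function(e) NULL
  )
  if (is.null(res)) {
    # both groups constant: identical means mean p = 1, else infinitely distinct
    if (isTRUE(all.equal(mean(group_a), mean(group_b)))) {
      return(list(t = 0, p = 1, df = length(group_a) + length(group_b) - 2,
                  mean_a = mean(group_a), mean_b = mean(group_b)))
    }
    stop("degenerate t-test: zero variance with unequal means")
  }
  list(t = unname(res$statistic), p = res$p.value, df = unname(res$parameter),
       mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Transmembrane vector of a helix bundle
#'
#' Each transmembrane helix contributes the vector from its first-residue
#' C-alpha to its last-residue C-alpha; the bundle's TM vector is the
#' normalized sum of the per-helix vectors. The anchor is the centroid of all
#' first/last C-alpha positions used.
#'
#' @param structure a `structure_model`.
#' @param helices data.frame with columns `chain`, `first`, `last` (residue
#'   numbers), one row per helix.
#' @param xyz optional replacement coordinates.
#' @return An object of class `tm_vector` with fields `vector` (unit length-3),
#'   `helix_count`, `anchor` (Angstrom).
#' @export
tm_vector <- function(structure, helices, xyz = NULL) {
  stopifnot(all(c("chain", "first", "last") %in% names(helices)))
  p <- if (is.null(xyz)) coords(structure) else as.matrix(xyz)
  at <- structure$atoms
  ca_at <- function(ch, rn) {
    i <- which(at$chain == ch & at$resno == rn & at$name == "CA")
    if (length(i) == 0) {
      stop("missing CA atom: chain ", ch, " residue ", rn)
    }
    p[i[1], ]
  }
  vsum <- c(0, 0, 0)
  anchors <- matrix(0, nrow = 0, ncol = 3)
  for (k in seq_len(nrow(helices))) {
    a <- ca_at(helices$chain[k], helices$first[k])
    b <- ca_at(helices$chain[k], helices$last[k])
    vsum <- vsum + (b - a)
    anchors <- rbind(anchors, a, b)
  }
  nv <- sqrt(sum(vsum^2))
  if (nv < 1e-6) stop("near-zero transmembrane vector sum")
  out <- list(vector = vsum / nv, helix_count = nrow(helices),
              anchor = colMeans(anchors))
  class(out) <- "tm_vector"
  out
}

#' Angle between two transmembrane vectors
#'
#' Unsigned angle in [0, 180] degrees. By convention 0 degrees means the two
#' receptors point the same way (compatible with a single membrane) and
#' angles near 180 degrees mean they sit in opposing, parallel membranes.
#'
#' @param v1,v2 `tm_vector` objects (or unit length-3 vectors).
#' @return angle in degrees.
#' @export
tm_angle <- function(v1, v2) {
  u <- if (inherits(v1, "tm_vector")) v1$vector else v1
  v <- if (inherits(v2, "tm_vector")) v2$vector else v2
  vec_angle_deg(u, v)
}
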