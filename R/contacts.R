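# Inter-group contact detection, per-window contact persistence, pairwise
# nonbonded energies, and the LIE stability score and dissociation verdict.
# No periodic-boundary minimum-image handling anywhere in this module:
# inputs are assumed to be whole, imaged molecules.

#' Contact-analysis parameters
#'
#' Defaults encode the persistence rule used for interface analysis: atoms
#' are in non-covalent contact when within 2 Angstrom, trajectories are cut
#' into 1 ns windows, and a pair is persistent in a window when in contact
#' for at least half of it. All atoms (including hydrogens) participate by
#' default; a 2 Angstrom all-atom cutoff effectively selects hydrogen-bond
#' and salt-bridge contacts.
#'
#' @param cutoff contact distance cutoff (Angstrom).
#' @param window_ns persistence window length (ns).
#' @param occupancy_threshold persistent-fraction threshold in (0, 1].
#' @param include_hydrogens keep hydrogen atoms in the groups.
#' @return list of class `contact_params`.
#' @export
contact_params <- function(cutoff = 2.0, window_ns = 1.0,
                           occupancy_threshold = 0.5, include_hydrogens = TRUE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (occupancy_threshold <= 0 || occupancy_threshold > 1) {
    stop("occupancy_threshold must be in (0, 1]")
  }
  if (window_ns <= 0) stop("window_ns must be positive")
  out <- list(cutoff = cutoff, window_ns = window_ns,
              occupancy_threshold = occupancy_threshold,
              include_hydrogens = include_hydrogens)
  class(out) <- "contact_params"
  out
}

drop_hydrogens <- function(structure, sel) {
  keep <- structure$atoms$element[sel$indices] != "H"
  sel$indices <- sel$indices[keep]
  if (length(sel$indices) == 0) stop("selection '", sel$label,
                                     "' empty after hydrogen removal")
  sel
}

# Cell-list neighbor search: returns all cross pairs (ia, ja) of rows of A, B
# with distance <= cutoff. Bit-identical to the all-pairs scan because the
# grid only prunes pairs strictly farther than the cutoff.
grid_cross_pairs <- function(A, B, cutoff) {
  nA <- nrow(A)
  nB <- nrow(B)
  if (nA == 0 || nB == 0) {
    return(data.frame(ia = integer(0), ja = integer(0), dist = numeric(0)))
  }
  origin <- pmin(apply(A, 2, min), apply(B, 2, min))
  cell <- function(P) {
    ix <- floor(sweep(P, 2, origin) / cutoff)
    paste(ix[, 1], ix[, 2], ix[, 3], sep = ",")
  }
  keyB <- cell(B)
  bmap <- split(seq_len(nB), keyB)
  ixA <- floor(sweep(A, 2, origin) / cutoff)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ia_all <- integer(0); ja_all <- integer(0); d_all <- numeric(0)
  for (i in seq_len(nA)) {
    neigh <- paste(ixA[i, 1] + off[, 1], ixA[i, 2] + off[, 2],
                   ixA[i, 3] + off[, 3], sep = ",")
    js <- unlist(bmap[neigh], use.names = FALSE)
    if (length(js) == 0) next
    d2 <- colSums((t(B[js, , drop = FALSE]) - A[i, ])^2)
    hit <- d2 <= cutoff^2
    if (any(hit)) {
      ia_all <- c(ia_all, rep.int(i, sum(hit)))
      ja_all <- c(ja_all, js[hit])
      d_all <- c(d_all, sqrt(d2[hit]))
    }
  }
  ord <- order(ia_all, ja_all)
  data.frame(ia = ia_all[ord], ja = ja_all[ord], dist = d_all[ord])
}

#' Detect inter-group atomic contacts in one frame
#'
#' All cross-group atom pairs within `params$cutoff` (boundary inclusive).
#' Uses a cell-list spatial grid; results are identical to an exhaustive
#' all-pairs scan. The two groups must be disjoint.
#'
#' @param structure a `structure_model` (or its frame via `xyz`).
#' @param group_a,group_b disjoint [select_atoms()] selections.
#' @param params a [contact_params()].
#' @param xyz optional replacement coordinates (one trajectory frame).
#' @return data.frame with columns `i`, `j` (atom-table row indices,
#'   `i` from group_a, `j` from group_b) and `dist` (Angstrom).
#' @export
detect_contacts <- function(structure, group_a, group_b,
                            params = contact_params(), xyz = NULL) {
  if (length(intersect(group_a$indices, group_b$indices)) > 0) {
    stop("groups overlap: contact groups must be disjoint")
  }
  if (!params$include_hydrogens) {
    group_a <- drop_hydrogens(structure, group_a)
    group_b <- drop_hydrogens(structure, group_b)
  }
  p <- if (is.null(xyz)) coords(structure) else as.matrix(xyz)
  A <- p[group_a$indices, , drop = FALSE]
  B <- p[group_b$indices, , drop = FALSE]
  hits <- grid_cross_pairs(A, B, params$cutoff)
  data.frame(i = group_a$indices[hits$ia], j = group_b$indices[hits$ja],
             dist = hits$dist)
}

#' Contact persistence over 1 ns windows
#'
#' Cuts the trajectory into consecutive windows of `params$window_ns`
#' (window k covers times [ (k-1) w, k w )), computes for every cross-group
#' atom pair the fraction of that window's frames in which the pair is
#' within the cutoff, and flags the pair persistent in the window when the
#' occupancy reaches `params$occupancy_threshold` (boundary inclusive -
#' "at least half" for the default 0.5). Pairs never in contact are omitted.
#'
#' @param trajectory an `md_trajectory`.
#' @param group_a,group_b disjoint selections on the trajectory's structure.
#' @param params a [contact_params()].
#' @return data.frame of class `contact_table` with columns `i`, `j`,
#'   `window`, `occupancy`, `persistent`; attribute `pair_persistence` holds
#'   per-pair total persistent time (ns), attribute `n_windows` the window
#'   count.
#' @export
contact_persistence <- function(trajectory, group_a, group_b,
                                params = contact_params()) {
  t <- trajectory$times_ns
  w <- params$window_ns
  dt_eff <- if (length(t) > 1) stats::median(diff(t)) else 0
  span <- max(t) - min(t) + dt_eff   # count each frame's sampling interval
  if (span < w) {
    warning(sprintf("trajectory span %.3g ns shorter than window %.3g ns: %s",
                    span, w, "single truncated window"))
  }
  win <- pmax(1L, 1L + as.integer(floor((t - min(t)) / w + 1e-9)))
  # counts per (pair, window)
  tab <- new.env(parent = emptyenv())
  nfr <- tabulate(win)
  for (k in seq_along(trajectory$frames)) {
    hits <- detect_contacts(trajectory$structure, group_a, group_b, params,
                            xyz = trajectory$frames[[k]])
    if (nrow(hits) == 0) next
    keys <- paste(hits$i, hits$j, win[k], sep = "_")
    for (key in keys) {
      tab[[key]] <- (if (is.null(tab[[key]])) 0L else tab[[key]]) + 1L
    }
  }
  keys <- ls(tab)
  if (length(keys) == 0) {
    out <- data.frame(i = integer(0), j = integer(0), window = integer(0),
                      occupancy = numeric(0), persistent = logical(0))
  } else {
    parts <- do.call(rbind, strsplit(keys, "_"))
    out <- data.frame(
      i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
      window = as.integer(parts[, 3]),
      count = vapply(keys, function(k) tab[[k]], integer(1))
    )
    out$occupancy <- out$count / nfr[out$window]
    out$persistent <- out$occupancy >= params$occupancy_threshold
    out <- out[order(out$i, out$j, out$window),
               c("i", "j", "window", "occupancy", "persistent")]
    rownames(out) <- NULL
  }
  per_pair <- if (nrow(out) == 0) {
    data.frame(i = integer(0), j = integer(0), persistent_ns = numeric(0))
  } else {
    agg <- stats::aggregate(persistent ~ i + j, data = out,
                            FUN = function(z) sum(z) * w)
    names(agg)[3] <- "persistent_ns"
    agg[order(-agg$persistent_ns, agg$i, agg$j), ]
  }
  attr(out, "pair_persistence") <- per_pair
  attr(out, "n_windows") <- max(win)
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Nonbonded-energy parameters
#'
#' @param coulomb_constant Coulomb constant in kcal*Angstrom/(mol*e^2).
#' @param cutoff pair cutoff (Angstrom); `NULL` means no cutoff.
#' @return list of class `nonbonded_params`.
#' @export
nonbonded_params <- function(coulomb_constant = 332.0636, cutoff = 9.0) {
  if (!is.null(cutoff) && cutoff <= 0) stop("cutoff must be positive")
  out <- list(coulomb_constant = coulomb_constant, cutoff = cutoff)
  class(out) <- "nonbonded_params"
  out
}

#' Inter-group electrostatic and van der Waals energy of one frame
#'
#' `e_elec = sum k q_i q_j / r_ij` and `e_vdw = sum eps_ij [ (Rmin_ij/r)^12
#' - 2 (Rmin_ij/r)^6 ]` over all cross-group pairs within the cutoff, with
#' Lorentz-Berthelot combining (`eps_ij` geometric mean, `Rmin_ij` the sum
#' of the two half-Rmin values). Every atom in both groups must carry a
#' charge and LJ parameters. This is an analysis estimator without Ewald or
#' other long-range corrections; the cutoff truncates pair sums sharply.
#'
#' @param structure a `structure_model` whose atoms carry `charge`,
#'   `lj_epsilon`, `lj_rmin`.
#' @param group_a,group_b disjoint selections.
#' @param nb a [nonbonded_params()].
#' @param xyz optional replacement coordinates.
#' @return named numeric `c(e_elec = , e_vdw = )` in kcal/mol.
#' @export
nonbonded_energy <- function(structure, group_a, group_b,
                             nb = nonbonded_params(), xyz = NULL) {
  if (length(intersect(group_a$indices, group_b$indices)) > 0) {
    stop("groups overlap: energy groups must be disjoint")
  }
  at <- structure$atoms
  need <- c(group_a$indices, group_b$indices)
  if (any(is.na(at$charge[need])) || any(is.na(at$lj_epsilon[need])) ||
      any(is.na(at$lj_rmin[need]))) {
    stop("every atom in both groups needs charge and LJ parameters")
  }
  p <- if (is.null(xyz)) coords(structure) else as.matrix(xyz)
  A <- p[group_a$indices, , drop = FALSE]
  B <- p[group_b$indices, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  if (any(r < 0.1)) stop("overlapping atoms: inter-group distance < 0.1 A")
  within <- if (is.null(nb$cutoff)) r > 0 else r <= nb$cutoff
  qa <- at$charge[group_a$indices]
  qb <- at$charge[group_b$indices]
  qq <- outer(qa, qb)
  e_elec <- sum((nb$coulomb_constant * qq / r)[within])
  eps <- sqrt(outer(at$lj_epsilon[group_a$indices],
                    at$lj_epsilon[group_b$indices]))
  rmin <- outer(at$lj_rmin[group_a$indices] / 2,
                at$lj_rmin[group_b$indices] / 2, "+")
  sr6 <- (rmin / r)^6
  e_vdw <- sum((eps * (sr6^2 - 2 * sr6))[within])
  c(e_elec = e_elec, e_vdw = e_vdw)
}

#' Linear interaction energy
#'
#' Weighted sum of electrostatic and van der Waals inter-group energies used
#' as a binding-stability score: `e_lie = a_elec * e_elec + a_vdw * e_vdw`.
#' The default coefficients are (0.5, 0.18); the variant (0.5, 0.15) used in
#' some interface plots is available by passing `coeffs`.
#'
#' @param e_elec,e_vdw energies (kcal/mol), vectorized.
#' @param coeffs named coefficients `c(elec = , vdw = )`.
#' @return e_lie in kcal/mol.
#' @export
lie_energy <- function(e_elec, e_vdw, coeffs = c(elec = 0.5, vdw = 0.18)) {
  unname(coeffs[["elec"]] * e_elec + coeffs[["vdw"]] * e_vdw)
}

#' Classify an interface as stable or dissociated
#'
#' An interface is called dissociated when the mean LIE over the final
#' `tail_fraction` of the trajectory (by time) is positive, operationalizing
#' the rule that models ending with positive interaction energy have come
#' apart; otherwise it is stable.
#'
#' @param series an [energy_series()].
#' @param tail_fraction fraction of the time span forming the tail window.
#' @return `"stable"` or `"dissociated"`; the tail mean (kcal/mol) is
#'   attached as attribute `tail_mean`.
#' @export
classify_association <- function(series, tail_fraction = 0.2) {
  if (nrow(series) < 5) stop("need at least 5 frames to classify")
  if (tail_fraction <= 0 || tail_fraction > 1) {
    stop("tail_fraction must be in (0, 1]")
  }
  t <- series$time_ns
  t0 <- max(t) - tail_fraction * (max(t) - min(t))
  tail_mean <- mean(series$e_lie[t >= t0])
  verdict <- if (tail_mean > 0) "dissociated" else "stable"
  attr(verdict, "tail_mean") <- tail_mean
  verdict
}
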