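# One-dimensional SAXS analysis: model profiles from coordinates (Debye sum),
# Guinier and dimensionless Kratky analysis, P(r)/Dmax, Porod volume and
# mass, the printed chi-square fit, concentration-series merging, NSD bead
# model comparison, and simplified ensemble selection.

#' Construct a SAXS profile
#'
#' @param q momentum transfer grid in 1/Angstrom, strictly increasing, > 0.
#' @param intensity intensities (arbitrary units), finite.
#' @param sigma optional per-point errors, > 0 where present.
#' @param label profile label.
#' @return list of class `saxs_profile` with fields `q`, `intensity`,
#'   `sigma`, `label`.
#' @export
saxs_profile <- function(q, intensity, sigma = NULL, label = "") {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) stop("q and intensity lengths differ")
  if (any(q <= 0)) stop("q must be positive")
  if (length(q) > 1 && any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (!all(is.finite(intensity))) stop("non-finite intensities")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma length differs from q")
    if (any(!is.finite(sigma) | sigma <= 0)) stop("sigma must be positive")
  }
  out <- list(q = q, intensity = intensity, sigma = sigma, label = label)
  class(out) <- "saxs_profile"
  out
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("<saxs_profile> '%s': %d points, q %.4g-%.4g 1/A%s\n",
              x$label, length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "" else ", with errors"))
  invisible(x)
}

#' Read a 3-column SAXS profile
#'
#' Whitespace-separated text with columns q (1/Angstrom), I, sigma
#' (sigma optional), `#` comment lines, the common `.dat` dialect. Gzip
#' input accepted.
#'
#' @param path input file.
#' @param label profile label (defaults to the file name).
#' @return A [saxs_profile()].
#' @export
read_saxs_profile <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(gz_to_text(path), header = FALSE, comment.char = "#",
                           strip.white = TRUE)
  if (ncol(tab) < 2) stop("SAXS profile '", path, "' needs >= 2 columns")
  sigma <- if (ncol(tab) >= 3) tab[[3]] else NULL
  saxs_profile(tab[[1]], tab[[2]], sigma, label = label)
}

#' Write a SAXS profile as 3-column text
#' @param profile a `saxs_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_saxs_profile <- function(profile, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# ", profile$label), con)
  writeLines("# q[1/A]  I  sigma", con)
  sg <- if (is.null(profile$sigma)) rep(NA, length(profile$q)) else profile$sigma
  utils::write.table(
    data.frame(q = profile$q, I = profile$intensity, sigma = sg),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

# bead coordinates at the requested granularity: residue = one bead at each
# residue's (mass-weighted) center of mass, atom = every atom
bead_coords <- function(structure, granularity = c("residue", "atom"),
                        xyz = NULL) {
  granularity <- match.arg(granularity)
  p <- if (is.null(xyz)) coords(structure) else as.matrix(xyz)
  if (granularity == "atom") return(p)
  at <- structure$atoms
  key <- paste(at$chain, at$resno, sep = "\r")
  m <- atom_masses(structure)
  mx <- rowsum(p * m, key, reorder = FALSE)
  ms <- rowsum(m, key, reorder = FALSE)
  unname(sweep(mx, 1, ms[, 1], "/"))
}

#' Radius of gyration from coordinates
#'
#' Mass-weighted RMS distance from the center of mass (the direct
#' second-moment formula).
#'
#' @param structure a `structure_model`.
#' @param selection optional selection.
#' @param xyz optional replacement coordinates.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(structure, selection = NULL, xyz = NULL) {
  idx <- if (is.null(selection)) seq_len(n_atoms(structure)) else selection$indices
  p <- if (is.null(xyz)) coords(structure) else as.matrix(xyz)
  p <- p[idx, , drop = FALSE]
  m <- atom_masses(structure, idx)
  com <- colSums(p * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(p, 2, com)^2)) / sum(m))
}

#' Model scattering profile by the Debye formula
#'
#' `I(q) = sum_i sum_j f_i f_j sin(q r_ij)/(q r_ij)` with unit point form
#' factors at the chosen granularity (shape-only modelling), so
#' `I(0) = n^2` for n beads. Residue granularity places one bead at each
#' residue center of mass.
#'
#' @param structure a `structure_model`.
#' @param q_grid momentum-transfer grid (1/Angstrom, positive, increasing).
#' @param granularity `"residue"` (default) or `"atom"`.
#' @param xyz optional replacement coordinates.
#' @return A [saxs_profile()].
#' @export
debye_profile <- function(structure, q_grid, granularity = c("residue", "atom"),
                          xyz = NULL) {
  beads <- bead_coords(structure, granularity, xyz = xyz)
  debye_profile_beads(beads, q_grid, label = structure$title)
}

# Debye sum over explicit bead coordinates (unit form factors)
debye_profile_beads <- function(beads, q_grid, label = "") {
  n <- nrow(beads)
  if (n == 0) stop("no beads")
  q <- as.numeric(q_grid)
  if (n == 1) return(saxs_profile(q, rep(1, length(q)), label = label))
  d <- as.numeric(stats::dist(beads))
  I <- vapply(q, function(qk) {
    x <- qk * d
    n + 2 * sum(ifelse(x < 1e-12, 1, sin(x) / x))
  }, numeric(1))
  saxs_profile(q, I, label = label)
}

#' Guinier fit with self-consistent q*Rg range
#'
#' Weighted linear least squares of ln I versus q^2 on the largest low-q
#' window satisfying `q_max * Rg <= qrg_max` (default 1.3), found by
#' iterating fit -> recompute Rg -> re-trim until self-consistent, starting
#' from the lowest 25% of points. Slope gives `Rg = sqrt(-3 * slope)`,
#' intercept gives I(0). Non-positive intensities in the window are dropped
#' with a warning. Weights are `(I/sigma)^2` when errors are present (the
#' delta-method variance of ln I), else uniform.
#'
#' @param profile a `saxs_profile`.
#' @param qrg_max upper limit for q*Rg in the fitted range.
#' @param min_points minimum points in the fitted window.
#' @return list of class `guinier_result`: `rg` (Angstrom), `i0`,
#'   `fit_range` (q limits), `n_points`, `r_squared`.
#' @export
guinier_fit <- function(profile, qrg_max = 1.3, min_points = 5) {
  q <- profile$q
  I <- profile$intensity
  s <- profile$sigma
  npt <- length(q)
  if (npt < min_points) stop("profile has fewer than ", min_points, " points")
  fit_window <- function(nw) {
    idx <- seq_len(nw)
    ok <- I[idx] > 0
    if (any(!ok)) {
      warning("dropping ", sum(!ok), " non-positive intensities in Guinier window")
      idx <- idx[ok]
    }
    if (length(idx) < min_points) {
      stop("fewer than ", min_points, " usable points in Guinier window")
    }
    w <- if (is.null(s)) rep(1, length(idx)) else (I[idx] / s[idx])^2
    fit <- stats::lm(log(I[idx]) ~ I(q[idx]^2), weights = w)
    slope <- unname(stats::coef(fit)[2])
    y <- log(I[idx])
    ss_tot <- sum(w * (y - sum(w * y) / sum(w))^2)
    r2 <- if (ss_tot <= 0) 1 else 1 - sum(w * stats::residuals(fit)^2) / ss_tot
    list(rg = sqrt(max(0, -3 * slope)), i0 = exp(unname(stats::coef(fit)[1])),
         idx = idx, r2 = r2)
  }
  nw <- max(min_points, ceiling(0.25 * npt))
  seen <- integer(0)
  res <- NULL
  for (iter in 1:100) {
    res <- fit_window(nw)
    new_nw <- if (res$rg <= 0) npt else max(min_points, sum(q <= qrg_max / res$rg))
    new_nw <- min(new_nw, npt)
    if (new_nw == nw || new_nw %in% seen) break
    seen <- c(seen, nw)
    nw <- new_nw
  }
  out <- list(rg = res$rg, i0 = res$i0,
              fit_range = c(q[res$idx[1]], q[res$idx[length(res$idx)]]),
              n_points = length(res$idx), r_squared = res$r2)
  class(out) <- "guinier_result"
  out
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("<guinier_result> Rg %.3f A, I0 %.4g, %d points, q %.4g-%.4g\n",
              x$rg, x$i0, x$n_points, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Dimensionless Kratky transform
#'
#' Returns `(q Rg)^2 I(q)/I(0)` against `q Rg`. For a compact globular
#' scatterer the curve peaks at the Guinier-Kratky point
#' `(sqrt(3), 3/e = 1.104)`; extended or flexible shapes shift the peak up
#' and to the right. The grid maximum is reported as the peak.
#'
#' @param profile a `saxs_profile`.
#' @param guinier a [guinier_fit()] result with `rg > 0` and `i0 > 0`.
#' @return data.frame of class `kratky_curve` with columns `qrg`, `kratky`;
#'   attributes `peak_qrg` and `peak_value`.
#' @export
kratky_dimensionless <- function(profile, guinier) {
  if (guinier$rg <= 0 || guinier$i0 <= 0) {
    stop("dimensionless Kratky needs rg > 0 and i0 > 0")
  }
  x <- profile$q * guinier$rg
  y <- x^2 * profile$intensity / guinier$i0
  out <- data.frame(qrg = x, kratky = y)
  k <- which.max(y)
  attr(out, "peak_qrg") <- x[k]
  attr(out, "peak_value") <- y[k]
  class(out) <- c("kratky_curve", "data.frame")
  out
}

#' Pair-distance distribution from coordinates
#'
#' Normalized histogram of all pairwise bead distances; `dmax` is the exact
#' maximum pairwise distance (not binned). The density integrates to 1.
#'
#' @param structure a `structure_model`.
#' @param bin_width histogram bin width (Angstrom).
#' @param granularity `"residue"` or `"atom"`.
#' @param xyz optional replacement coordinates.
#' @return list of class `pddf`: `r` (bin midpoints), `p` (density, 1/Angstrom),
#'   `dmax` (Angstrom), `bin_width`.
#' @export
pddf_from_structure <- function(structure, bin_width = 1,
                                granularity = c("residue", "atom"), xyz = NULL) {
  beads <- bead_coords(structure, granularity, xyz = xyz)
  if (nrow(beads) < 2) stop("need at least 2 beads for a distance distribution")
  d <- as.numeric(stats::dist(beads))
  dmax <- max(d)
  breaks <- seq(0, (floor(dmax / bin_width) + 1) * bin_width, by = bin_width)
  h <- hist(d, breaks = breaks, plot = FALSE)
  out <- list(r = h$mids, p = h$density, dmax = dmax, bin_width = bin_width)
  class(out) <- "pddf"
  out
}

#' Porod invariant, volume and mass estimate
#'
#' The Porod invariant `Q = integral q^2 I(q) dq` is evaluated by the
#' trapezoid rule on the data, with the `[0, q_min]` head extended
#' analytically using the Guinier form `I0 exp(-(q Rg)^2/3)`. No high-q
#' extrapolation is attempted; when `q^4 I(q)` has not plateaued by the end
#' of the data a truncation-bias warning is emitted (`Q` is then
#' underestimated and `Vp` overestimated). The Porod volume is
#' `Vp = 2 pi^2 I0 / Q` (Angstrom^3) and the molecular-mass estimate for
#' globular proteins is `MM[kDa] = Vp[nm^3] / 1.6`.
#'
#' @param profile a `saxs_profile` (intensities must be non-negative).
#' @param guinier a [guinier_fit()] result for the same profile.
#' @return list of class `porod_result`: `porod_invariant`, `vp` (Angstrom^3),
#'   `mm_kda`.
#' @export
porod_volume <- function(profile, guinier) {
  q <- profile$q
  I <- profile$intensity
  if (any(I < 0)) stop("negative intensities in Porod integration")
  rg <- guinier$rg
  i0 <- guinier$i0
  q1 <- q[1]
  head_q <- if (rg > 0) {
    a <- rg / sqrt(3)
    i0 * (sqrt(pi) * pracma::erf(a * q1) / (4 * a^3) -
            q1 * exp(-(a * q1)^2) / (2 * a^2))
  } else {
    i0 * q1^3 / 3
  }
  Q <- head_q + pracma::trapz(q, q^2 * I)
  # plateau check on q^4 I over the last two deciles of the q range
  n <- length(q)
  i_last <- q >= q[n] - 0.1 * (q[n] - q[1])
  i_prev <- q >= q[n] - 0.2 * (q[n] - q[1]) & !i_last
  if (sum(i_prev) > 2 && sum(i_last) > 2) {
    m1 <- mean((q^4 * I)[i_prev])
    m2 <- mean((q^4 * I)[i_last])
    if (is.finite(m1) && m1 > 0 && abs(m2 - m1) / m1 > 0.2) {
      warning("q^4 I(q) has not plateaued: Porod invariant is truncated ",
              "(Vp biased high)")
    }
  }
  vp <- 2 * pi^2 * i0 / Q
  out <- list(porod_invariant = Q, vp = vp, mm_kda = (vp / 1000) / 1.6)
  class(out) <- "porod_result"
  out
}

#' Chi-square fit of a model curve to experimental data
#'
#' `chi2 = 1/(n-1) sum_j [ (I_exp(q_j) - c I_calc(q_j)) / sigma_j ]^2` with
#' the scale `c` that minimizes chi2 in closed form:
#' `c = sum(I_exp I_calc / sigma^2) / sum(I_calc^2 / sigma^2)`. The model
#' curve is linearly interpolated onto the experimental q grid;
#' extrapolation beyond the model's q range is an error.
#'
#' @param calc model `saxs_profile`.
#' @param exp experimental `saxs_profile` with errors.
#' @return list of class `chi_square_result`: `chi2`, `scale_c`, `n_points`.
#' @export
chi_square_fit <- function(calc, exp) {
  if (is.null(exp$sigma)) stop("experimental profile needs sigma")
  if (min(exp$q) < min(calc$q) - 1e-12 || max(exp$q) > max(calc$q) + 1e-12) {
    stop("experimental q range extends beyond the model curve: ",
         "extrapolation forbidden")
  }
  Ic <- stats::approx(calc$q, calc$intensity, xout = exp$q)$y
  Ie <- exp$intensity
  s2 <- exp$sigma^2
  cc <- sum(Ie * Ic / s2) / sum(Ic^2 / s2)
  n <- length(exp$q)
  chi2 <- sum(((Ie - cc * Ic)^2) / s2) / (n - 1)
  out <- list(chi2 = chi2, scale_c = cc, n_points = n)
  class(out) <- "chi_square_result"
  out
}

#' Merge a concentration series of profiles
#'
#' Scales the low-concentration profile onto the high-concentration profile
#' over the overlap q range by weighted least squares, then splices: scaled
#' low-concentration data below the overlap midpoint, high-concentration
#' data from the midpoint up. Errors of the scaled part are propagated by
#' the same factor.
#'
#' @param low_conc,high_conc `saxs_profile` objects.
#' @param overlap_q length-2 q range present in both profiles.
#' @return merged [saxs_profile()]; the applied scale is attribute `scale`.
#' @export
merge_profiles <- function(low_conc, high_conc, overlap_q) {
  overlap_q <- sort(as.numeric(overlap_q))
  inh <- high_conc$q >= overlap_q[1] & high_conc$q <= overlap_q[2]
  inl <- low_conc$q >= overlap_q[1] & low_conc$q <= overlap_q[2]
  if (sum(inh) < 2 || sum(inl) < 2) stop("overlap range is not populated in both profiles")
  Il <- stats::approx(low_conc$q, low_conc$intensity, xout = high_conc$q[inh])$y
  Ih <- high_conc$intensity[inh]
  w <- if (is.null(high_conc$sigma)) rep(1, sum(inh)) else 1 / high_conc$sigma[inh]^2
  sc <- sum(w * Ih * Il) / sum(w * Il^2)
  mid <- mean(overlap_q)
  keep_lo <- low_conc$q < mid
  keep_hi <- high_conc$q >= mid
  sig_lo <- if (is.null(low_conc$sigma)) NULL else sc * low_conc$sigma[keep_lo]
  sig_hi <- if (is.null(high_conc$sigma)) NULL else high_conc$sigma[keep_hi]
  sigma <- if (is.null(sig_lo) || is.null(sig_hi)) NULL else c(sig_lo, sig_hi)
  out <- saxs_profile(
    c(low_conc$q[keep_lo], high_conc$q[keep_hi]),
    c(sc * low_conc$intensity[keep_lo], high_conc$intensity[keep_hi]),
    sigma,
    label = paste0("merge(", low_conc$label, ", ", high_conc$label, ")")
  )
  attr(out, "scale") <- sc
  out
}

#' Normalized spatial discrepancy between bead models
#'
#' Kozin-Svergun-style NSD: for each point of one set take the distance to
#' the nearest point of the other set; average the squared distances over
#' each set, normalize each one-sided term by the squared mean
#' nearest-neighbour spacing of the partner set, average the two terms and
#' take the square root. Identical sets give 0; superimposable similar
#' shapes give values near 1.
#'
#' @param beads_a,beads_b n x 3 coordinate matrices with n >= 2.
#' @return NSD value >= 0.
#' @export
nsd <- function(beads_a, beads_b) {
  A <- as.matrix(beads_a)
  B <- as.matrix(beads_b)
  if (nrow(A) < 2 || nrow(B) < 2) {
    stop("NSD needs at least 2 beads per set (internal spacing undefined)")
  }
  cross2 <- function(X, Y) {
    outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  }
  nn_spacing <- function(X) {
    d2 <- cross2(X, X)
    diag(d2) <- Inf
    mean(sqrt(pmax(apply(d2, 1, min), 0)))
  }
  dAB <- pmax(cross2(A, B), 0)
  one_sided_a <- mean(apply(dAB, 1, min))   # A -> B, squared
  one_sided_b <- mean(apply(dAB, 2, min))   # B -> A, squared
  dA <- nn_spacing(A)
  dB <- nn_spacing(B)
  sqrt(0.5 * (one_sided_a / dB^2 + one_sided_b / dA^2))
}

#' Simplified ensemble selection against an experimental curve
#'
#' Finds non-negative weights over a pool of model curves minimizing the
#' chi-square of the weighted-average curve against the experimental
#' profile (non-negative least squares on error-whitened intensities; the
#' joint scale is absorbed by the unnormalized solution and reported as
#' `scale_c`). Weighted Rg and Dmax distributions of the selected ensemble
#' are summarized; the weighted SD of the Rg distribution is reported as an
#' explicitly-named flexibility proxy (not comparable to published
#' genetic-algorithm flexibility metrics).
#'
#' @param pool list of model `saxs_profile` curves.
#' @param exp experimental `saxs_profile` with errors.
#' @param rg optional per-model Rg values (Angstrom).
#' @param dmax optional per-model Dmax values (Angstrom).
#' @param max_members optional cap on the number of selected members (the
#'   smallest-weight members are dropped and the fit repeated).
#' @return list of class `ensemble_result`: `weights` (simplex-normalized),
#'   `chi2`, `scale_c`, `rg_mean`, `rg_sd` (flexibility proxy), `dmax_mean`,
#'   `dmax_sd`, `n_points`.
#' @export
ensemble_select <- function(pool, exp, rg = NULL, dmax = NULL,
                            max_members = NULL) {
  if (length(pool) == 0) stop("empty model pool")
  if (is.null(exp$sigma)) stop("experimental profile needs sigma")
  A <- vapply(pool, function(p) {
    if (min(exp$q) < min(p$q) - 1e-12 || max(exp$q) > max(p$q) + 1e-12) {
      stop("pool curve '", p$label, "' does not cover the experimental q range")
    }
    stats::approx(p$q, p$intensity, xout = exp$q)$y
  }, numeric(length(exp$q)))
  Aw <- A / exp$sigma
  bw <- exp$intensity / exp$sigma
  x <- pracma::lsqnonneg(Aw, bw)$x
  active <- which(x > 0)
  if (!is.null(max_members) && length(active) > max_members) {
    keep <- active[order(-x[active])][seq_len(max_members)]
    x2 <- pracma::lsqnonneg(Aw[, keep, drop = FALSE], bw)$x
    x <- numeric(length(pool))
    x[keep] <- x2
  }
  if (sum(x) <= 0) stop("ensemble fit degenerate: all weights zero")
  fitted <- as.numeric(A %*% x)
  n <- length(exp$q)
  chi2 <- sum(((exp$intensity - fitted) / exp$sigma)^2) / (n - 1)
  w <- x / sum(x)
  wstats <- function(v) {
    if (is.null(v)) return(c(NA_real_, NA_real_))
    mu <- sum(w * v)
    c(mu, sqrt(sum(w * (v - mu)^2)))
  }
  rgs <- wstats(rg)
  dms <- wstats(dmax)
  out <- list(weights = w, chi2 = chi2, scale_c = sum(x),
              rg_mean = rgs[1], rg_sd = rgs[2],
              dmax_mean = dms[1], dmax_sd = dms[2], n_points = n)
  class(out) <- "ensemble_result"
  out
}
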