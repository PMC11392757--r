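# Synthetic-data generators with embedded ground truth. Pseudo-Fab bodies
# are C-alpha bead rigid bodies (unit masses): every downstream operation in
# the package is geometric or mass-weighted, so sequence-threaded models are
# not needed. Each generator takes an explicit seed and leaves the global
# random state untouched.

# scatter n beads with zero mean (so a center of mass lands exactly where
# placed), sd controls blob size
centered_blob <- function(n, sd) {
  p <- matrix(stats::rnorm(3 * n, sd = sd), ncol = 3)
  sweep(p, 2, colMeans(p))
}

#' Generate a two-Fab bead dimer with an exact inter-Fab angle
#'
#' Builds two rigid two-domain pseudo-Fabs as C-alpha bead clouds (one bead
#' per residue, unit masses). Each Fab has a light chain (residues
#' `1..n_res_light`) and a heavy chain (`n_res_light+1 .. n_res_light+n_res_heavy`),
#' split into an N-terminal variable and a C-terminal constant domain. The
#' constant-domain centers of mass sit `gap` Angstrom apart and the
#' constant-to-variable domain vectors subtend exactly `inter_fab_angle`.
#' Chains are L/H for Fab 1 and B/A (light/heavy) for Fab 2.
#'
#' @param inter_fab_angle requested Fab-Fab angle in degrees, in [0, 180].
#' @param n_res_light,n_res_heavy residues per light/heavy chain (defaults
#'   213 and 219, i.e. 432 residues per Fab).
#' @param domain_length constant-to-variable center-of-mass distance (Angstrom).
#' @param domain_radius bead-cloud spread per domain (Angstrom).
#' @param gap distance between the two constant-domain centers (Angstrom).
#' @param seed RNG seed for the bead clouds.
#' @return list with `structure`, `fab1`, `fab2` (each a list of `constant`
#'   and `variable` [domain_definition()]s), and `true_angle` (degrees).
#' @export
make_fab_dimer <- function(inter_fab_angle, n_res_light = 213,
                           n_res_heavy = 219, domain_length = 40,
                           domain_radius = 8, gap = 10, seed = 1) {
  if (inter_fab_angle < 0 || inter_fab_angle > 180) {
    stop("inter_fab_angle must be in [0, 180] degrees")
  }
  if (n_res_light < 3 || n_res_heavy < 3) stop("need >= 3 residues per chain")
  th <- inter_fab_angle * pi / 180
  u1 <- c(-sin(th / 2), cos(th / 2), 0)
  u2 <- c(sin(th / 2), cos(th / 2), 0)
  c_const <- list(c(0, 0, 0), c(gap, 0, 0))
  axes <- list(u1, u2)
  nl_var <- floor(n_res_light / 2)
  nh_var <- floor(n_res_heavy / 2)
  chain_sets <- list(c(light = "L", heavy = "H"), c(light = "B", heavy = "A"))
  rows <- list()
  withr::with_seed(seed, {
    for (f in 1:2) {
      var_com <- c_const[[f]] + domain_length * axes[[f]]
      n_var <- nl_var + nh_var
      n_con <- (n_res_light - nl_var) + (n_res_heavy - nh_var)
      var_xyz <- sweep(centered_blob(n_var, domain_radius / 3), 2, var_com, "+")
      con_xyz <- sweep(centered_blob(n_con, domain_radius / 3), 2, c_const[[f]], "+")
      ch <- chain_sets[[f]]
      resno_l <- seq_len(n_res_light)
      resno_h <- n_res_light + seq_len(n_res_heavy)
      # variable beads: light 1..nl_var then heavy first nh_var residues
      xyz <- rbind(
        var_xyz[seq_len(nl_var), , drop = FALSE],
        con_xyz[seq_len(n_res_light - nl_var), , drop = FALSE],
        var_xyz[nl_var + seq_len(nh_var), , drop = FALSE],
        con_xyz[(n_res_light - nl_var) + seq_len(n_res_heavy - nh_var), ,
                drop = FALSE]
      )
      rows[[f]] <- data.frame(
        name = "CA", element = "C",
        chain = c(rep(ch[["light"]], n_res_light), rep(ch[["heavy"]], n_res_heavy)),
        resno = c(resno_l, resno_h), resname = "ALA",
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        mass = 1, stringsAsFactors = FALSE
      )
    }
  })
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  st <- structure_model(at, title = sprintf("synthetic Fab dimer %.1f deg",
                                            inter_fab_angle))
  fab_def <- function(ch) list(
    variable = domain_definition("variable", chain = c(ch[["light"]], ch[["heavy"]]),
                                 from = c(1, n_res_light + 1),
                                 to = c(nl_var, n_res_light + nh_var)),
    constant = domain_definition("constant", chain = c(ch[["light"]], ch[["heavy"]]),
                                 from = c(nl_var + 1, n_res_light + nh_var + 1),
                                 to = c(n_res_light, n_res_light + n_res_heavy))
  )
  list(structure = st, fab1 = fab_def(chain_sets[[1]]),
       fab2 = fab_def(chain_sets[[2]]), true_angle = inter_fab_angle)
}

#' Generate a trajectory whose Fab-Fab angle follows a Gaussian
#'
#' Starts from a [make_fab_dimer()] dimer and, for each frame, rigidly
#' rotates Fab 2 about the hinge (the axis through its constant-domain
#' center of mass, normal to the inter-Fab plane) so the measured Fab-Fab
#' angle equals a Gaussian draw with the requested mean and SD. Draws are
#' clamped to [1, 179] degrees; the clamp count is reported.
#'
#' @param angle_mean,angle_sd Gaussian parameters of the per-frame angle
#'   (degrees).
#' @param n_frames number of frames (>= 2).
#' @param dt_ns frame spacing (ns).
#' @param seed RNG seed (bead clouds and angle draws).
#' @param ... further arguments to [make_fab_dimer()].
#' @return list with `trajectory` (an [md_trajectory()]), `fab1`, `fab2`
#'   domain definitions, `angles_deg` (the realized per-frame angles),
#'   `angle_mean`, `angle_sd`, `n_clamped`.
#' @export
make_angle_trajectory <- function(angle_mean = 130, angle_sd = 5,
                                  n_frames = 106, dt_ns = 1, seed = 1, ...) {
  if (angle_sd < 0) stop("angle_sd must be >= 0")
  if (n_frames < 2) stop("need at least 2 frames")
  dimer <- make_fab_dimer(angle_mean, seed = seed, ...)
  st <- dimer$structure
  base <- coords(st)
  fab2_chains <- c("B", "A")
  i2 <- which(st$atoms$chain %in% fab2_chains)
  sel_c2 <- select_atoms(st, domain = dimer$fab2$constant)
  pivot <- center_of_mass(st, sel_c2)
  draws <- withr::with_seed(seed + 1L, stats::rnorm(n_frames, angle_mean, angle_sd))
  n_clamped <- sum(draws < 1 | draws > 179)
  angles <- pmin(179, pmax(1, draws))
  frames <- lapply(angles, function(th) {
    delta <- -(th - angle_mean) * pi / 180   # clockwise widens the angle
    Rz <- matrix(c(cos(delta), -sin(delta), 0,
                   sin(delta), cos(delta), 0,
                   0, 0, 1), nrow = 3, byrow = TRUE)
    f <- base
    f[i2, ] <- sweep(sweep(f[i2, , drop = FALSE], 2, pivot) %*% t(Rz), 2,
                     pivot, "+")
    f
  })
  traj <- md_trajectory(st, frames, (seq_len(n_frames) - 1) * dt_ns)
  list(trajectory = traj, fab1 = dimer$fab1, fab2 = dimer$fab2,
       angles_deg = angles, angle_mean = angle_mean, angle_sd = angle_sd,
       n_clamped = n_clamped)
}

# Ideal helical C-alpha trace: 19 residues, 100 degrees twist per residue
# (5 exact turns over 18 steps), so the first-to-last CA vector lies exactly
# along the helix axis.
helix_trace <- function(base, axis, helix_length, radius = 2.3) {
  n <- 19
  rise <- helix_length / (n - 1)
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  i <- 0:(n - 1)
  phi <- i * 100 * pi / 180
  t(vapply(seq_along(i), function(k) {
    base + i[k] * rise * axis + radius * (cos(phi[k]) * e1 + sin(phi[k]) * e2)
  }, numeric(3)))
}

#' Generate one transmembrane helix bundle
#'
#' Ideal helical C-alpha traces (19 residues each, five exact turns, so each
#' helix's first-to-last CA vector lies exactly along the bundle axis). The
#' bundle axis is tilted `tilt_deg` from +z toward +x.
#'
#' @param tilt_deg bundle-axis tilt from +z (degrees).
#' @param n_helices helices in the bundle (default 8, an eight-subunit
#'   receptor bundle).
#' @param helix_length first-to-last CA span per helix (Angstrom).
#' @param bundle_radius circle radius of helix placement (Angstrom).
#' @param chains chain ids, one per helix.
#' @param anchor bundle base position (Angstrom).
#' @return list with `structure`, `helices` (data.frame chain/first/last)
#'   and `axis` (the exact unit bundle axis).
#' @export
make_helix_bundle <- function(tilt_deg = 0, n_helices = 8, helix_length = 27,
                              bundle_radius = 15,
                              chains = LETTERS[seq_len(n_helices)],
                              anchor = c(0, 0, 0)) {
  if (length(chains) != n_helices) stop("need one chain id per helix")
  th <- tilt_deg * pi / 180
  axis <- c(sin(th), 0, cos(th))
  rows <- list()
  for (k in seq_len(n_helices)) {
    ang <- 2 * pi * (k - 1) / n_helices
    base <- anchor + bundle_radius * c(cos(ang), sin(ang), 0)
    xyz <- helix_trace(base, axis, helix_length)
    rows[[k]] <- data.frame(
      name = "CA", element = "C", chain = chains[k], resno = 1:19,
      resname = "ALA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      mass = NA_real_, stringsAsFactors = FALSE
    )
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  list(structure = structure_model(at, title = "synthetic TM bundle"),
       helices = data.frame(chain = chains, first = 1, last = 19,
                            stringsAsFactors = FALSE),
       axis = axis)
}

#' Generate a receptor pair with a prescribed inter-membrane angle
#'
#' Two helix bundles (default 8 helices each) whose transmembrane vectors
#' subtend exactly `inter_membrane_angle`, with bundle anchors `separation`
#' Angstrom apart along x - the geometry of two receptors bridged across
#' apposed membranes.
#'
#' @param inter_membrane_angle angle between the two TM vectors (degrees,
#'   0 = same orientation, 180 = opposing parallel membranes).
#' @param separation anchor-to-anchor distance (Angstrom; default just over
#'   150, the span of a near-linear Fab-dimer bridge).
#' @param n_helices helices per bundle.
#' @param helix_length per-helix CA span (Angstrom).
#' @return list with `structure` (both bundles; bundle 1 chains A-H, bundle
#'   2 chains I-P for the default 8), `helices1`, `helices2`, `true_angle`.
#' @export
make_membrane_pair <- function(inter_membrane_angle, separation = 152,
                               n_helices = 8, helix_length = 27) {
  if (inter_membrane_angle < 0 || inter_membrane_angle > 180) {
    stop("inter_membrane_angle must be in [0, 180] degrees")
  }
  ch1 <- LETTERS[seq_len(n_helices)]
  ch2 <- LETTERS[n_helices + seq_len(n_helices)]
  b1 <- make_helix_bundle(0, n_helices, helix_length, chains = ch1,
                          anchor = c(0, 0, 0))
  b2 <- make_helix_bundle(inter_membrane_angle, n_helices, helix_length,
                          chains = ch2, anchor = c(separation, 0, 0))
  at <- rbind(b1$structure$atoms, b2$structure$atoms)
  at$serial <- seq_len(nrow(at))
  list(structure = structure_model(at, title = "synthetic receptor pair"),
       helices1 = b1$helices, helices2 = b2$helices,
       true_angle = inter_membrane_angle)
}

# uniform bead sampling of a solid sphere
sphere_beads <- function(n, radius) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  r <- radius * stats::runif(n)^(1 / 3)
  v * r
}

#' Generate a synthetic scattering profile with known ground truth
#'
#' Three kinds: `"guinier"` is the ideal Guinier curve
#' `I0 exp(-(q Rg)^2/3)`; `"sphere"` is the exact solid-sphere form factor
#' for the given radius (true `Rg = sqrt(3/5) R`); `"dimer"` is the Debye
#' curve of a generated two-lobe bead model whose exact maximum dimension
#' equals `length` (each lobe carries a bead at its outer pole). Optional
#' multiplicative Gaussian noise with coefficient of variation `noise_cv`
#' sets the error column to `noise_cv * I_true`.
#'
#' @param kind `"guinier"`, `"sphere"` or `"dimer"`.
#' @param rg Guinier radius of gyration (Angstrom), for `kind = "guinier"`.
#' @param radius sphere radius (Angstrom), for `kind = "sphere"`.
#' @param length dimer end-to-end maximum dimension (Angstrom).
#' @param i0 forward intensity scale.
#' @param noise_cv multiplicative noise coefficient of variation (>= 0).
#' @param n_q points in the q grid.
#' @param q_max largest q (1/Angstrom).
#' @param n_beads beads per dimer lobe.
#' @param seed RNG seed (noise and dimer beads).
#' @return list with `profile` (a [saxs_profile()]) and `truth` (kind,
#'   `rg_true`, `dmax_true`, `i0`; for `"dimer"` also `structure`, the bead
#'   model as a `structure_model`).
#' @export
make_scatter_profile <- function(kind = c("guinier", "sphere", "dimer"),
                                 rg = 43.17, radius = 30, length = 147,
                                 i0 = 1, noise_cv = 0, n_q = 200,
                                 q_max = 0.3, n_beads = 400, seed = 1) {
  kind <- match.arg(kind)
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  q <- seq(q_max / n_q, q_max, length.out = n_q)
  truth <- list(kind = kind, i0 = i0)
  if (kind == "guinier") {
    I <- i0 * exp(-(q * rg)^2 / 3)
    truth$rg_true <- rg
    truth$dmax_true <- NA_real_
  } else if (kind == "sphere") {
    x <- q * radius
    I <- i0 * (3 * (sin(x) - x * cos(x)) / x^3)^2
    truth$rg_true <- sqrt(3 / 5) * radius
    truth$dmax_true <- 2 * radius
  } else {
    lobe_r <- length / 6
    centers <- c(-(length / 2 - lobe_r), length / 2 - lobe_r)
    lobe <- function(cx, pole_x) {
      b <- sphere_beads(n_beads - 1, lobe_r)
      b[, 1] <- b[, 1] + cx
      rbind(b, c(pole_x, 0, 0))   # outer pole bead fixes the exact Dmax
    }
    beads <- withr::with_seed(seed, rbind(
      lobe(centers[1], -length / 2),
      lobe(centers[2], length / 2)
    ))
    at <- data.frame(
      serial = seq_len(nrow(beads)), name = "CA", element = "C",
      chain = rep(c("X", "Y"), each = n_beads),
      resno = rep(seq_len(n_beads), 2), resname = "ALA",
      x = beads[, 1], y = beads[, 2], z = beads[, 3], mass = 1,
      stringsAsFactors = FALSE
    )
    truth$structure <- structure_model(at, title = "synthetic two-lobe dimer")
    raw <- debye_profile_beads(beads, q, label = "dimer model")
    I <- i0 * raw$intensity / nrow(beads)^2   # I(0) scaled to i0
    com <- colMeans(beads)
    truth$rg_true <- sqrt(mean(rowSums(sweep(beads, 2, com)^2)))
    truth$dmax_true <- length
  }
  sigma_true <- noise_cv * abs(I)
  if (noise_cv > 0) {
    I <- withr::with_seed(seed + 1L, I * (1 + noise_cv * stats::rnorm(n_q)))
    sigma <- sigma_true
  } else {
    sigma <- NULL
  }
  list(profile = saxs_profile(q, I, sigma, label = paste("synthetic", kind)),
       truth = truth)
}

#' Generate a stable or dissociating interaction-energy series
#'
#' `"stable"` is a noisy negative plateau; `"dissociating"` ramps linearly
#' from a negative interface energy through zero at three quarters of the
#' trajectory, so the final-fifth mean LIE is positive.
#'
#' @param kind `"stable"` or `"dissociating"`.
#' @param n_frames frames (>= 10).
#' @param dt_ns frame spacing (ns).
#' @param seed RNG seed.
#' @param coeffs LIE coefficients, see [lie_energy()].
#' @return list with `series` (an [energy_series()]) and `truth_label`.
#' @export
make_energy_series <- function(kind = c("stable", "dissociating"),
                               n_frames = 105, dt_ns = 1, seed = 1,
                               coeffs = c(elec = 0.5, vdw = 0.18)) {
  kind <- match.arg(kind)
  if (n_frames < 10) stop("need at least 10 frames")
  t <- (seq_len(n_frames) - 1) * dt_ns
  withr::with_seed(seed, {
    if (kind == "stable") {
      e_elec <- -60 + stats::rnorm(n_frames, sd = 3)
      e_vdw <- -40 + stats::rnorm(n_frames, sd = 3)
    } else {
      u <- t / (0.75 * max(t))
      e_elec <- -60 * (1 - u) + stats::rnorm(n_frames, sd = 1.5)
      e_vdw <- -40 * (1 - u) + stats::rnorm(n_frames, sd = 1.5)
    }
  })
  list(series = energy_series(t, e_elec, e_vdw, coeffs), truth_label = kind)
}

#' Generate a trajectory with a scripted contact schedule
#'
#' Two atom groups: a probe pair that oscillates across the contact cutoff
#' so that window w contains exactly `round(schedule[w] * frames_per_window)`
#' contact frames, plus one spectator atom that never makes contact.
#'
#' @param schedule per-window target occupancies in [0, 1].
#' @param frames_per_window frames per persistence window.
#' @param window_ns window length (ns).
#' @param contact_dist,apart_dist probe-pair distances in contact /
#'   non-contact frames (Angstrom).
#' @return list with `trajectory`, `group_a`/`group_b` (selections: chains A
#'   and B), `expected_occupancy`, `expected_persistent` (at the 0.5
#'   threshold).
#' @export
make_contact_trajectory <- function(schedule, frames_per_window = 10,
                                    window_ns = 1, contact_dist = 1.5,
                                    apart_dist = 3.0) {
  if (any(schedule < 0 | schedule > 1)) stop("occupancies must be in [0, 1]")
  at <- data.frame(
    serial = 1:3, name = "CA", element = "C",
    chain = c("A", "B", "B"), resno = c(1, 1, 2), resname = "ALA",
    x = c(0, apart_dist, 50), y = 0, z = 0, mass = 12,
    stringsAsFactors = FALSE
  )
  st <- structure_model(at, title = "synthetic contact probe")
  n_con <- round(schedule * frames_per_window)
  frames <- list()
  for (w in seq_along(schedule)) {
    for (k in seq_len(frames_per_window)) {
      f <- coords(st)
      f[2, 1] <- if (k <= n_con[w]) contact_dist else apart_dist
      frames[[length(frames) + 1]] <- f
    }
  }
  nfr <- length(frames)
  traj <- md_trajectory(st, frames, (seq_len(nfr) - 1) * window_ns / frames_per_window)
  list(trajectory = traj,
       group_a = select_atoms(st, chain = "A"),
       group_b = select_atoms(st, chain = "B"),
       expected_occupancy = n_con / frames_per_window,
       expected_persistent = n_con / frames_per_window >= 0.5)
}
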