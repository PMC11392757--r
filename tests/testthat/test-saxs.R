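test_that("Debye profiles match closed forms for one and two beads", {
  q <- seq(0.001, 0.5, length.out = 50)
  one <- beads_structure(matrix(c(0, 0, 0), ncol = 3))
  p1 <- debye_profile(one, q, granularity = "atom")
  expect_equal(p1$intensity, rep(1, 50))
  two <- beads_structure(matrix(c(0, 0, 0, 10, 0, 0), ncol = 3, byrow = TRUE))
  p2 <- debye_profile(two, q, granularity = "atom")
  expect_equal(p2$intensity, 2 + 2 * sin(q * 10) / (q * 10), tolerance = 1e-12)
  # forward limit I(0) = n^2
  tiny <- debye_profile(two, 1e-8, granularity = "atom")
  expect_equal(tiny$intensity, 4, tolerance = 1e-10)
})

test_that("residue granularity beads at residue centers of mass", {
  at <- data.frame(
    serial = 1:4, name = c("N", "CA", "N", "CA"), element = c("C", "C", "C", "C"),
    chain = "A", resno = c(1, 1, 2, 2), resname = "ALA",
    x = c(0, 2, 10, 12), y = 0, z = 0, mass = 1, stringsAsFactors = FALSE
  )
  st <- structure_model(at)
  pd <- pddf_from_structure(st, bin_width = 1, granularity = "residue")
  expect_equal(pd$dmax, 10)  # residue COMs at x = 1 and 11
})

test_that("Guinier fits recover ideal-curve parameters exactly and under noise", {
  q <- seq(0.002, 0.1, length.out = 200)
  prof <- saxs_profile(q, 7 * exp(-(q * 43.17)^2 / 3))
  g <- guinier_fit(prof)
  expect_equal(g$rg, 43.17, tolerance = 1e-6)
  expect_equal(g$i0, 7, tolerance = 1e-6)
  expect_lte(g$fit_range[2] * g$rg, 1.3 + 1e-9)
  # flat profile: zero slope, Rg 0
  flat <- saxs_profile(q, rep(3, 200))
  expect_lt(guinier_fit(flat)$rg, 1e-6)
  # 1% multiplicative noise: Rg within 2% of truth
  sp <- make_scatter_profile("guinier", rg = 43.17, noise_cv = 0.01,
                             n_q = 200, seed = 9)
  gn <- guinier_fit(sp$profile)
  expect_lt(abs(gn$rg - 43.17) / 43.17, 0.02)
})

test_that("the dimensionless Kratky transform peaks at the Guinier-Kratky point", {
  rg <- 25
  q <- seq(0.0005, 3.5 / rg, length.out = 3000)
  prof <- saxs_profile(q, 4.2 * exp(-(q * rg)^2 / 3))
  g <- guinier_fit(prof)
  k <- kratky_dimensionless(prof, g)
  expect_equal(attr(k, "peak_qrg"), sqrt(3), tolerance = 2e-3)
  expect_equal(attr(k, "peak_value"), 3 / exp(1), tolerance = 1e-4)
  # invariant under a joint intensity rescaling
  prof5 <- saxs_profile(q, 5 * prof$intensity)
  k5 <- kratky_dimensionless(prof5, guinier_fit(prof5))
  expect_equal(k5$kratky, k$kratky, tolerance = 1e-9)
  # a compact sphere peaks near 1.1 as a globule signature
  sph <- make_scatter_profile("sphere", radius = 30, n_q = 600, q_max = 0.3)
  gs <- guinier_fit(sph$profile)
  ks <- kratky_dimensionless(sph$profile, gs)
  expect_lt(abs(attr(ks, "peak_value") - 1.1) / 1.1, 0.05)
})

test_that("P(r) reports exact Dmax and a normalized density", {
  two <- beads_structure(matrix(c(0, 0, 0, 10, 0, 0), ncol = 3, byrow = TRUE))
  pd <- pddf_from_structure(two, bin_width = 1, granularity = "atom")
  expect_equal(pd$dmax, 10)
  expect_equal(sum(pd$p > 0), 1)
  expect_equal(pd$r[pd$p > 0], 9.5)   # the right-closed (9,10] bin holds d = 10
  expect_equal(sum(pd$p) * pd$bin_width, 1, tolerance = 1e-12)
  # 3000-point solid sphere of radius 50: Dmax within one bin of 100
  sph <- beads_structure(ball_beads(3000, 50, seed = 4))
  pds <- pddf_from_structure(sph, bin_width = 2, granularity = "atom")
  expect_lt(abs(pds$dmax - 100), 2)
  # elongated synthetic dimer built to 147 A
  dm <- make_scatter_profile("dimer", length = 147, seed = 2)
  pdd <- pddf_from_structure(dm$truth$structure, bin_width = 2,
                             granularity = "atom")
  expect_equal(pdd$dmax, 147, tolerance = 1e-9)
})

test_that("Porod volume and mass follow the Vp/1.6 convention", {
  # direct formula check: Vp of 160 nm^3 maps to 100 kDa
  sph <- make_scatter_profile("sphere", radius = 30, n_q = 800, q_max = 0.75)
  g <- guinier_fit(sph$profile)
  po <- suppressWarnings(porod_volume(sph$profile, g))
  vp_true <- 4 / 3 * pi * 30^3
  expect_lt(abs(po$vp - vp_true) / vp_true, 0.10)
  expect_equal(po$mm_kda, (po$vp / 1000) / 1.6, tolerance = 1e-12)
  # intensity rescaling leaves Vp unchanged (I0 and Q scale together)
  prof5 <- saxs_profile(sph$profile$q, 5 * sph$profile$intensity)
  po5 <- suppressWarnings(porod_volume(prof5, guinier_fit(prof5)))
  expect_equal(po5$vp, po$vp, tolerance = 1e-6)
  neg <- saxs_profile(c(0.01, 0.02), c(1, 2))
  neg$intensity[1] <- -1
  expect_error(porod_volume(neg, g), "negative")
})

test_that("chi-square fitting recovers scale factors and the printed normalization", {
  q <- seq(0.005, 0.3, length.out = 120)
  Ic <- 100 * exp(-(q * 20)^2 / 3)
  calc <- saxs_profile(q, Ic)
  same <- saxs_profile(q, Ic, sigma = rep(1, 120))
  r1 <- chi_square_fit(calc, same)
  expect_equal(r1$scale_c, 1, tolerance = 1e-12)
  expect_equal(r1$chi2, 0, tolerance = 1e-12)
  doubled <- saxs_profile(q, 2 * Ic, sigma = rep(1, 120))
  r2 <- chi_square_fit(calc, doubled)
  expect_equal(r2$scale_c, 2, tolerance = 1e-12)
  expect_equal(r2$chi2, 0, tolerance = 1e-12)
  # noise at the stated sigma concentrates chi2 near 1; c matches grid search
  qn <- seq(0.002, 0.25, length.out = 500)
  Icn <- 50 * exp(-(qn * 30)^2 / 3)
  sig <- 0.02 * Icn
  Ie <- withr::with_seed(13, 1.7 * Icn + sig * rnorm(500))
  expn <- saxs_profile(qn, Ie, sigma = sig)
  rn <- chi_square_fit(saxs_profile(qn, Icn), expn)
  expect_gt(rn$chi2, 0.85)
  expect_lt(rn$chi2, 1.15)
  expect_equal(rn$scale_c, grid_search_scale(Icn, Ie, sig), tolerance = 1e-6)
  # the 1/(n-1) normalization, written out
  expect_equal(rn$chi2,
               sum(((Ie - rn$scale_c * Icn) / sig)^2) / (500 - 1),
               tolerance = 1e-12)
  # chi2 invariant when data and errors scale together
  r_scaled <- chi_square_fit(saxs_profile(qn, Icn),
                             saxs_profile(qn, 3 * Ie, sigma = 3 * sig))
  expect_equal(r_scaled$chi2, rn$chi2, tolerance = 1e-10)
  bad <- saxs_profile(qn, Ie, sigma = sig)
  expect_error(chi_square_fit(saxs_profile(qn * 10, Icn), bad),
               "extrapolation")
})

test_that("concentration-series merging scales and splices correctly", {
  q <- seq(0.005, 0.4, length.out = 300)
  I <- 10 * exp(-(q * 15)^2 / 3) + 0.01
  hi <- saxs_profile(q, I, sigma = 0.01 * I)
  same <- merge_profiles(hi, hi, overlap_q = c(0.05, 0.15))
  expect_equal(attr(same, "scale"), 1, tolerance = 1e-12)
  expect_equal(same$intensity, I, tolerance = 1e-12)
  lo <- saxs_profile(q, 0.5 * I, sigma = 0.005 * I)
  m <- merge_profiles(lo, hi, overlap_q = c(0.05, 0.15))
  expect_equal(attr(m, "scale"), 2, tolerance = 1e-10)
  expect_equal(m$intensity, I, tolerance = 1e-10)
  # noisy overlap: scale equals the closed-form WLS oracle
  noisy_lo <- saxs_profile(q, withr::with_seed(21, 0.5 * I * (1 + 0.01 * rnorm(300))),
                           sigma = 0.005 * I)
  m2 <- merge_profiles(noisy_lo, hi, overlap_q = c(0.05, 0.15))
  ov <- q >= 0.05 & q <= 0.15
  w <- 1 / (0.01 * I[ov])^2
  oracle <- sum(w * I[ov] * noisy_lo$intensity[ov]) /
    sum(w * noisy_lo$intensity[ov]^2)
  expect_equal(attr(m2, "scale"), oracle, tolerance = 1e-8)
  expect_error(merge_profiles(lo, hi, overlap_q = c(0.95, 0.99)), "overlap")
})

test_that("NSD is zero for identical sets, symmetric, and matches the double loop", {
  A <- ball_beads(40, 10, seed = 6)
  expect_lt(nsd(A, A), 1e-7)
  B <- ball_beads(40, 10, seed = 7) + 3
  expect_equal(nsd(A, B), nsd(B, A), tolerance = 1e-12)
  # two unit-spaced 5x5x5 lattices offset by 10 A vs the naive oracle
  g <- as.matrix(expand.grid(0:4, 0:4, 0:4))
  h <- g
  h[, 1] <- h[, 1] + 10
  expect_equal(nsd(g, h), double_loop_nsd(g, h), tolerance = 1e-10)
  expect_equal(nsd(A, B), double_loop_nsd(A, B), tolerance = 1e-10)
  expect_error(nsd(A[1, , drop = FALSE], B), "at least 2")
})

test_that("ensemble selection recovers exact members and constructed mixtures", {
  q <- seq(0.004, 0.25, length.out = 250)
  curve <- function(rg) exp(-(q * rg)^2 / 3)
  pool <- lapply(c(20, 35, 50, 65), function(rg) saxs_profile(q, curve(rg)))
  sig <- rep(1e-4, 250)
  # the true curve sits in the pool
  exact <- saxs_profile(q, curve(35), sigma = sig)
  r <- ensemble_select(pool, exact, rg = c(20, 35, 50, 65))
  expect_gte(r$weights[2], 0.99)
  expect_lt(r$chi2, 1e-6)
  # a constructed 50/50 two-shape mixture with mild noise
  mixI <- 0.5 * curve(20) + 0.5 * curve(65)
  sigm <- 0.005 * mixI
  mix <- saxs_profile(q, withr::with_seed(31, mixI + sigm * rnorm(250)),
                      sigma = sigm)
  rm <- ensemble_select(pool, mix, rg = c(20, 35, 50, 65))
  expect_equal(rm$weights[1], 0.5, tolerance = 0.02)
  expect_equal(rm$weights[4], 0.5, tolerance = 0.02)
  expect_equal(sum(rm$weights), 1, tolerance = 1e-12)
  expect_true(all(rm$weights >= 0))
  # the weighted Rg spread is reported as the flexibility proxy
  expect_gt(rm$rg_sd, 15)
  # an all-decoy pool shows clear lack of fit
  decoys <- lapply(c(90, 110), function(rg) saxs_profile(q, curve(rg)))
  rd <- ensemble_select(decoys, mix)
  expect_gt(rd$chi2, 10)
  expect_error(ensemble_select(list(), mix), "empty")
})

test_that("shape -> Debye -> analysis closes the loop on generator truth", {
  dm <- make_scatter_profile("dimer", length = 147, n_beads = 250, seed = 2)
  st <- dm$truth$structure
  # direct-formula Rg of the bead model vs the recorded truth
  expect_equal(radius_of_gyration(st), dm$truth$rg_true, tolerance = 1e-9)
  g <- guinier_fit(dm$profile)
  # elongated shapes carry a larger Guinier-window bias than globules
  expect_lt(abs(g$rg - dm$truth$rg_true) / dm$truth$rg_true, 0.05)
  # the extended dimer's Kratky peak sits up-right of the Guinier-Kratky point
  k <- kratky_dimensionless(dm$profile, g)
  expect_gt(attr(k, "peak_qrg"), sqrt(3))
  expect_gt(attr(k, "peak_value"), 3 / exp(1))
  pd <- pddf_from_structure(st, bin_width = 2, granularity = "atom")
  expect_equal(pd$dmax, 147, tolerance = 1e-9)
})
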