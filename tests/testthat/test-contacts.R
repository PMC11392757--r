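two_atom_structure <- function(d) {
  structure_model(data.frame(
    serial = 1:2, name = "CA", element = "C", chain = c("A", "B"),
    resno = 1, resname = "ALA", x = c(0, d), y = 0, z = 0, mass = 12,
    stringsAsFactors = FALSE
  ))
}

test_that("contact detection honors the 2 A cutoff inclusively", {
  st <- two_atom_structure(1.9)
  ga <- select_atoms(st, chain = "A")
  gb <- select_atoms(st, chain = "B")
  expect_equal(nrow(detect_contacts(st, ga, gb)), 1)
  st2 <- two_atom_structure(2.1)
  expect_equal(nrow(detect_contacts(st2, select_atoms(st2, chain = "A"),
                                    select_atoms(st2, chain = "B"))), 0)
  st3 <- two_atom_structure(2.0)
  expect_equal(nrow(detect_contacts(st3, select_atoms(st3, chain = "A"),
                                    select_atoms(st3, chain = "B"))), 1)
  expect_error(detect_contacts(st, ga, ga), "disjoint")
})

test_that("grid-accelerated contacts equal the all-pairs oracle on random configs", {
  st_template <- function(A, B) {
    n <- nrow(A) + nrow(B)
    structure_model(data.frame(
      serial = seq_len(n), name = "CA", element = "C",
      chain = rep(c("A", "B"), c(nrow(A), nrow(B))),
      resno = seq_len(n), resname = "ALA",
      x = c(A[, 1], B[, 1]), y = c(A[, 2], B[, 2]), z = c(A[, 3], B[, 3]),
      mass = 12, stringsAsFactors = FALSE
    ))
  }
  for (cfg in 1:200) {
    withr::with_seed(3000 + cfg, {
      A <- matrix(runif(150, 0, 30), ncol = 3)
      B <- matrix(runif(150, 0, 30), ncol = 3)
      cutoff <- runif(1, 2, 6)
    })
    st <- st_template(A, B)
    got <- detect_contacts(st, select_atoms(st, chain = "A"),
                           select_atoms(st, chain = "B"),
                           contact_params(cutoff = cutoff))
    want <- brute_force_contacts(A, B, cutoff)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      want_keys <- sort(paste(want$ia, want$ja + 50))
      got_keys <- sort(paste(got$i, got$j))
      expect_identical(got_keys, want_keys)
    }
  }
})

test_that("per-window occupancy implements the at-least-half persistence rule", {
  ct <- make_contact_trajectory(c(0.6))
  tab <- contact_persistence(ct$trajectory, ct$group_a, ct$group_b)
  expect_equal(tab$occupancy, 0.6)
  expect_true(tab$persistent)
  ct5 <- make_contact_trajectory(c(0.5))  # exactly 5 of 10 frames
  tab5 <- contact_persistence(ct5$trajectory, ct5$group_a, ct5$group_b)
  expect_equal(tab5$occupancy, 0.5)
  expect_true(tab5$persistent)            # boundary inclusive
  ct3 <- make_contact_trajectory(c(0.2, 0.5, 0.9))
  tab3 <- contact_persistence(ct3$trajectory, ct3$group_a, ct3$group_b)
  expect_equal(tab3$persistent, c(FALSE, TRUE, TRUE))
  expect_equal(tab3$occupancy, c(0.2, 0.5, 0.9))
  # occupancy summed over windows times window length = total contact time
  total_ns <- sum(tab3$occupancy) * 1.0
  expect_equal(total_ns, sum(c(0.2, 0.5, 0.9)))
  pp <- attr(tab3, "pair_persistence")
  expect_equal(pp$persistent_ns, 2)       # two persistent 1 ns windows
})

test_that("a trajectory shorter than one window warns and truncates", {
  ct <- make_contact_trajectory(c(1.0), frames_per_window = 5, window_ns = 10)
  short <- md_trajectory(ct$trajectory$structure, ct$trajectory$frames[1:3],
                         c(0, 1, 2))
  expect_warning(contact_persistence(short, ct$group_a, ct$group_b,
                                     contact_params(window_ns = 10)),
                 "truncated")
})

param_structure <- function(n, seed, box = 12) {
  withr::with_seed(seed, structure_model(data.frame(
    serial = seq_len(n), name = "CA", element = "C",
    chain = rep(c("A", "B"), each = n / 2), resno = seq_len(n),
    resname = "ALA",
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    mass = 12, charge = runif(n, -1, 1),
    lj_epsilon = runif(n, 0.05, 0.3), lj_rmin = runif(n, 2.5, 4),
    stringsAsFactors = FALSE
  )))
}

test_that("nonbonded energies match closed forms and the direct-sum oracle", {
  st <- two_atom_structure(3.320636)
  st$atoms$charge <- c(1, -1)
  st$atoms$lj_epsilon <- 0
  st$atoms$lj_rmin <- 1
  e <- nonbonded_energy(st, select_atoms(st, chain = "A"),
                        select_atoms(st, chain = "B"))
  expect_equal(unname(e["e_elec"]), -100, tolerance = 1e-10)
  expect_equal(unname(e["e_vdw"]), 0)
  # a single LJ pair at its Rmin sits at the well depth -eps
  st2 <- two_atom_structure(3.5)
  st2$atoms$charge <- 0
  st2$atoms$lj_epsilon <- c(0.2, 0.2)
  st2$atoms$lj_rmin <- c(3.5, 3.5)
  e2 <- nonbonded_energy(st2, select_atoms(st2, chain = "A"),
                         select_atoms(st2, chain = "B"))
  expect_equal(unname(e2["e_vdw"]), -0.2, tolerance = 1e-12)
  # random parameterized groups, no cutoff, vs brute force
  st3 <- param_structure(40, seed = 17)
  ga <- select_atoms(st3, chain = "A")
  gb <- select_atoms(st3, chain = "B")
  got <- nonbonded_energy(st3, ga, gb, nonbonded_params(cutoff = NULL))
  at <- st3$atoms
  want <- brute_force_energy(
    coords(st3)[ga$indices, ], coords(st3)[gb$indices, ],
    at$charge[ga$indices], at$charge[gb$indices],
    at$lj_epsilon[ga$indices], at$lj_epsilon[gb$indices],
    at$lj_rmin[ga$indices], at$lj_rmin[gb$indices]
  )
  expect_equal(got, want, tolerance = 1e-8)
  # symmetry in the two groups, and with the 9 A cutoff applied
  got_sym <- nonbonded_energy(st3, gb, ga, nonbonded_params(cutoff = NULL))
  expect_equal(unname(got_sym), unname(got), tolerance = 1e-10)
  got9 <- nonbonded_energy(st3, ga, gb, nonbonded_params(cutoff = 9))
  want9 <- brute_force_energy(
    coords(st3)[ga$indices, ], coords(st3)[gb$indices, ],
    at$charge[ga$indices], at$charge[gb$indices],
    at$lj_epsilon[ga$indices], at$lj_epsilon[gb$indices],
    at$lj_rmin[ga$indices], at$lj_rmin[gb$indices], cutoff = 9
  )
  expect_equal(got9, want9, tolerance = 1e-8)
})

test_that("electrostatics are linear in each charge and vdW has its minimum at Rmin", {
  st <- param_structure(20, seed = 23)
  ga <- select_atoms(st, chain = "A")
  gb <- select_atoms(st, chain = "B")
  nb <- nonbonded_params(cutoff = NULL)
  e1 <- nonbonded_energy(st, ga, gb, nb)["e_elec"]
  st2 <- st
  st2$atoms$charge[ga$indices] <- 3 * st$atoms$charge[ga$indices]
  expect_equal(unname(nonbonded_energy(st2, ga, gb, nb)["e_elec"]),
               unname(3 * e1), tolerance = 1e-10)
  # additivity over a partition of group B
  gb1 <- select_atoms(st, resno = gb$indices[1:5])
  gb2 <- select_atoms(st, resno = gb$indices[6:10])
  eb <- nonbonded_energy(st, ga, gb, nb)
  expect_equal(unname(eb),
               unname(nonbonded_energy(st, ga, gb1, nb) +
                        nonbonded_energy(st, ga, gb2, nb)),
               tolerance = 1e-10)
  # energy at Rmin is lower than slightly to either side
  vdw_at <- function(d) {
    s <- two_atom_structure(d)
    s$atoms$charge <- 0
    s$atoms$lj_epsilon <- 0.3
    s$atoms$lj_rmin <- 3.2
    unname(nonbonded_energy(s, select_atoms(s, chain = "A"),
                            select_atoms(s, chain = "B"))["e_vdw"])
  }
  expect_lt(vdw_at(3.2), vdw_at(3.1))
  expect_lt(vdw_at(3.2), vdw_at(3.3))
  # overlapping atoms are an error
  stc <- two_atom_structure(0.05)
  stc$atoms$charge <- 0; stc$atoms$lj_epsilon <- 0.1; stc$atoms$lj_rmin <- 3
  expect_error(nonbonded_energy(stc, select_atoms(stc, chain = "A"),
                                select_atoms(stc, chain = "B")), "overlap")
})

test_that("LIE is the stated linear combination with configurable coefficients", {
  expect_equal(lie_energy(-100, -50), -59)
  expect_equal(lie_energy(0, 0), 0)
  expect_equal(lie_energy(-100, -50, c(elec = 0.5, vdw = 0.15)), -57.5)
  # linear in both inputs
  e1 <- lie_energy(-20, -10)
  expect_equal(lie_energy(-40, -20), 2 * e1)
  expect_equal(lie_energy(c(-100, 0), c(-50, 0)), c(-59, 0))
})

test_that("association verdicts follow the positive-tail-mean rule", {
  flat <- energy_series(0:49, rep(-60, 50), rep(-40, 50))
  expect_equal(as.character(classify_association(flat)), "stable")
  ramp <- energy_series(0:49, seq(-60, 20, length.out = 50),
                        seq(-40, 10, length.out = 50))
  v <- classify_association(ramp)
  expect_equal(as.character(v), "dissociated")
  expect_gt(attr(v, "tail_mean"), 0)
  # generator fixtures carry their truth labels
  for (s in c(5, 6)) {
    expect_equal(as.character(classify_association(
      make_energy_series("stable", seed = s)$series)), "stable")
    dis <- make_energy_series("dissociating", seed = s)$series
    v2 <- classify_association(dis)
    expect_equal(as.character(v2), "dissociated")
    # tail mean matches a hand computation over the final fifth
    t <- dis$time_ns
    expect_equal(attr(v2, "tail_mean"),
                 mean(dis$e_lie[t >= max(t) - 0.2 * (max(t) - min(t))]),
                 tolerance = 1e-12)
  }
  # frames added before the tail (tail window held fixed in ns) are irrelevant
  base <- energy_series(50:99, seq(-60, 20, length.out = 50),
                        seq(-40, 10, length.out = 50))
  ext <- energy_series(c(0:49, 50:99),
                       c(rep(-500, 50), seq(-60, 20, length.out = 50)),
                       c(rep(-500, 50), seq(-40, 10, length.out = 50)))
  tail_ns <- 0.2 * (99 - 50)
  expect_equal(as.character(classify_association(base, tail_fraction = 0.2)),
               as.character(classify_association(ext,
                                                 tail_fraction = tail_ns / 99)))
})
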