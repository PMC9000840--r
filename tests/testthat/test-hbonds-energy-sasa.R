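test_that("the geometric hydrogen-bond criterion applies both cutoffs", {
  expect_equal(hydrogen_bonds(hb_fixture(0.29, 0),
                              c("water", "water"), n_blocks = 0)$mean, 1)
  expect_equal(hydrogen_bonds(hb_fixture(0.29, 10),
                              c("water", "water"), n_blocks = 0)$mean, 1)
  expect_equal(hydrogen_bonds(hb_fixture(0.40, 0),
                              c("water", "water"), n_blocks = 0)$mean, 0)
  expect_equal(hydrogen_bonds(hb_fixture(0.29, 45),
                              c("water", "water"), n_blocks = 0)$mean, 0)
})

test_that("hydrogen-bond counts are invariant under rigid motion of the frame", {
  s <- toy_solution(30, 3, 6, box = box(4), seed = 19)
  tr <- one_frame_traj(s$frame$positions, s$topology, s$frame$box)
  base <- hydrogen_bonds(tr, c("water", "water"), n_blocks = 0)$mean
  set.seed(20)
  R <- random_proper_rotation()
  ctr <- colMeans(s$frame$positions)
  rot <- sweep(sweep(s$frame$positions, 2, ctr) %*% t(R), 2, ctr, "+")
  # large box so the rotation does not push sites across the boundary
  big <- box(40)
  tr1 <- one_frame_traj(s$frame$positions + 10, s$topology, big)
  tr2 <- one_frame_traj(rot + 10, s$topology, big)
  expect_equal(hydrogen_bonds(tr2, c("water", "water"), n_blocks = 0)$mean,
               hydrogen_bonds(tr1, c("water", "water"), n_blocks = 0)$mean)
  expect_true(is.finite(base))
})

test_that("stray hydrogens with no bonded donor are a configuration error", {
  pos <- rbind(c(1, 1, 1), c(2, 2, 2))
  top <- atom_table(c("OW", "HW1"), c("SOL", "SOL"), c(1, 1),
                    mass = c(15.999, 1.008))
  tr <- one_frame_traj(pos, top, box(10))
  expect_error(hydrogen_bonds(tr, c("water", "water"), n_blocks = 0),
               "no bonded")
})

test_that("pair energies reproduce the electric conversion factor and LJ landmarks", {
  e <- coulomb_pair()
  expect_equal(e$coulomb, 138.935458, tolerance = 1e-9)
  expect_equal(e$vdw, 0)

  # LJ at r = sigma vanishes; at the minimum it equals -eps
  e_sigma <- coulomb_pair(q1 = 0, q2 = 0, r = 0.3, sigma = 0.3, eps = 0.5)
  expect_equal(e_sigma$vdw, 0, tolerance = 1e-10)
  e_min <- coulomb_pair(q1 = 0, q2 = 0, r = 2^(1 / 6) * 0.3, sigma = 0.3,
                        eps = 0.5)
  expect_equal(e_min$vdw, -0.5, tolerance = 1e-9)

  # beyond the cutoff everything is zero
  e_far <- coulomb_pair(r = 1.2)
  expect_equal(e_far$coulomb, 0)
  expect_equal(e_far$vdw, 0)
  expect_equal(e$total, e$coulomb + e$vdw)
})

test_that("group energies are symmetric and additive over partitions", {
  s <- toy_solution(25, 4, 6, box = box(4), seed = 23)
  tr <- one_frame_traj(s$frame$positions, s$topology, s$frame$box)
  prot <- which(s$topology$molecule_class == "protein")
  solv <- which(s$topology$molecule_class != "protein")
  ab <- interaction_energy(tr, prot, solv, n_blocks = 0)$series
  ba <- interaction_energy(tr, solv, prot, n_blocks = 0)$series
  expect_equal(ab$total, ba$total, tolerance = 1e-10)

  wat <- which(s$topology$molecule_class == "water")
  peg <- which(s$topology$molecule_class == "peg4")
  e_w <- interaction_energy(tr, prot, wat, n_blocks = 0)$series
  e_p <- interaction_energy(tr, prot, peg, n_blocks = 0)$series
  expect_equal(e_w$total + e_p$total, ab$total, tolerance = 1e-9)
})

test_that("missing Lennard-Jones parameters name the offending atom", {
  top <- atom_table(c("C1", "C2"), c("PRO", "PRO"), c(1, 1), mass = 12,
                    charge = 0)
  tr <- one_frame_traj(rbind(c(1, 1, 1), c(1.3, 1, 1)), top, box(5))
  expect_error(interaction_energy(tr, 1, 2, n_blocks = 0), "C1")
  expect_error(interaction_energy(tr, 1, 1, n_blocks = 0), "disjoint")
})

test_that("an isolated sphere has the closed-form accessible area", {
  top <- atom_table("C", "PRO", 1, mass = 12, charge = 0)
  f <- frame(matrix(c(1, 1, 1), 1), box(4))
  got <- sasa(f, top, atoms = 1, radii = c(C = 0.15))
  expect_equal(got$total, 4 * pi * 0.29^2, tolerance = 1e-9)
})

test_that("well-separated atoms add their isolated-sphere areas", {
  top <- atom_table(c("C", "O"), c("PRO", "PRO"), c(1, 1), mass = c(12, 16),
                    charge = c(0.0, -0.5))
  f <- frame(rbind(c(0.5, 0.5, 0.5), c(2.5, 2.5, 2.5)), box(8))
  got <- sasa(f, top)
  iso <- 4 * pi * ((vdw_radii_bondi()[c("C", "O")] + 0.14)^2)
  expect_equal(got$total, sum(iso), tolerance = 1e-9)
  # partition identity with charges straddling the threshold
  expect_equal(got$hydrophilic + got$hydrophobic, got$total,
               tolerance = 1e-12)
  expect_equal(got$hydrophobic, unname(iso["C"]), tolerance = 1e-9)
})

test_that("sasa decomposition partitions exactly on a mixed random cluster", {
  s <- toy_solution(0, 0, 20, box = box(6), seed = 29)
  got <- sasa(s$frame, s$topology)
  expect_equal(got$hydrophilic + got$hydrophobic, got$total,
               tolerance = 1e-12)
  expect_true(all(got$per_atom >= 0))
})

test_that("sasa is converged at the default sphere-point count", {
  s <- toy_solution(0, 0, 12, box = box(6), seed = 31)
  a1 <- sasa(s$frame, s$topology, n_sphere_points = 960L)
  a2 <- sasa(s$frame, s$topology, n_sphere_points = 1920L)
  expect_lt(abs(a1$total / a2$total - 1), 0.005)
})

test_that("unknown elements are refused in the radius lookup", {
  top <- atom_table("C", "PRO", 1, mass = 12)
  f <- frame(matrix(1, 1, 3), box(4))
  expect_error(sasa(f, top, radii = c(O = 0.152)), "radius")
})
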