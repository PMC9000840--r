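gro_line <- function(resid, resname, name, serial, x, y, z) {
  sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", resid, resname, name, serial,
          x, y, z)
}

test_that("GRO files parse into topology, coordinates and box", {
  gro <- c("three waters, one atom each",
           "    3",
           gro_line(1, "SOL", "OW", 1, 1, 2, 3),
           gro_line(2, "SOL", "OW", 2, 0.5, 0.5, 0.5),
           gro_line(3, "SOL", "OW", 3, 3.9, 3.9, 3.9),
           "   4.00000   4.00000   4.00000")
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(gro, path)
  cfg <- read_configuration(path, "gro")
  expect_equal(nrow(cfg$topology), 3L)
  expect_equal(cfg$topology$molecule_class, rep("water", 3))
  expect_equal(cfg$frame$box$volume, 64)
  expect_equal(cfg$frame$positions[1, ], c(1, 2, 3))
})

test_that("PDB round trip matches GRO coordinates within format precision", {
  s <- toy_solution(5, 1, 4, box = box(4), seed = 3)
  g <- withr::local_tempfile(fileext = ".gro")
  p <- withr::local_tempfile(fileext = ".pdb")
  write_configuration(s$topology, s$frame, g, "gro")
  write_configuration(s$topology, s$frame, p, "pdb")
  from_gro <- read_configuration(g, "gro")
  from_pdb <- read_configuration(p, "pdb")
  # each format's own rounding: 1e-3 nm for GRO, 1e-4 nm for PDB
  expect_lt(max(abs(from_gro$frame$positions - s$frame$positions)), 6e-4)
  expect_lt(max(abs(from_pdb$frame$positions - s$frame$positions)), 6e-5)
  expect_lt(max(abs(from_pdb$frame$positions - from_gro$frame$positions)),
            7e-4)
  expect_equal(from_pdb$frame$box$lengths, from_gro$frame$box$lengths,
               tolerance = 1e-6)
  expect_equal(from_pdb$topology$residue_name, from_gro$topology$residue_name)
})

test_that("malformed coordinate files fail with the offending line", {
  gro <- c("truncated", "    2",
           gro_line(1, "SOL", "OW", 1, 1, 2, 3),
           "    2SOL    OW    2   0.500",
           "   4.0 4.0 4.0")
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(gro, path)
  expect_error(read_configuration(path, "gro"), "line 4")
  # missing box line
  noloc <- c("no box", "    1", gro_line(1, "SOL", "OW", 1, 1, 2, 3))
  writeLines(noloc, path)
  expect_error(read_configuration(path, "gro"), "box")
})

test_that("triclinic boxes are rejected explicitly", {
  gro <- c("triclinic", "    1", gro_line(1, "SOL", "OW", 1, 1, 2, 3),
           "   4.0 4.0 4.0 0.0 0.0 1.0 0.0 0.0 0.0")
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(gro, path)
  expect_error(read_configuration(path, "gro"), "triclinic")
})

test_that("frames_text trajectories round-trip and validate atom counts", {
  g <- brownian_trajectory(7, 9, 1.0, seed = 5)
  path <- withr::local_tempfile(fileext = ".traj")
  write_frames_text(g$wrapped, path)
  back <- read_trajectory(path, g$wrapped$topology)
  expect_equal(back$coords, g$wrapped$coords, tolerance = 1e-8)
  expect_equal(back$times, g$wrapped$times)
  expect_equal(n_frames(back), 10L)

  # single frame
  one <- trajectory(g$wrapped$coords[1, , , drop = FALSE],
                    g$wrapped$times[1], g$wrapped$boxes[1, , drop = FALSE])
  p1 <- withr::local_tempfile()
  write_frames_text(one, p1)
  expect_equal(n_frames(read_trajectory(p1, NULL)), 1L)

  # atom-count mismatch reports both counts
  small_top <- atom_table(rep("P", 3), rep("SOL", 3), 1:3, mass = 18)
  expect_error(read_trajectory(path, small_top), "7.*3|3.*7")
  # binary XTC is declared unsupported, not silently misread
  expect_error(read_trajectory(path, NULL, format = "xtc"), "frames_text")
})

test_that("velocities survive the frames_text round trip", {
  g <- cosine_flow_trajectory(25, 1.0, n_frames = 2, seed = 8)
  path <- withr::local_tempfile()
  write_frames_text(g$trajectory, path)
  back <- read_trajectory(path, g$trajectory$topology)
  expect_equal(back$velocities, g$trajectory$velocities, tolerance = 1e-8)
})

test_that("unwrap inverts wrapping and is idempotent", {
  # hand case: crossing +x at L = 4
  co <- array(0, c(2, 1, 3))
  co[1, 1, ] <- c(3.6, 1, 1); co[2, 1, ] <- c(0.2, 1, 1)
  tr <- trajectory(co, 0:1, box(4))
  expect_equal(unwrap(tr)$coords[2, 1, 1], 4.2)

  # stationary particle untouched
  co2 <- array(rep(c(1, 2, 3), each = 5), c(5, 1, 3))
  tr2 <- trajectory(co2, 0:4, box(4))
  expect_equal(unwrap(tr2)$coords, co2)

  # generator inversion on a random walk
  g <- brownian_trajectory(40, 200, 2.0, seed = 11)
  expect_equal(unwrap(g$wrapped)$coords, g$unwrapped$coords,
               tolerance = 1e-9)
  # idempotence on the continuous result
  u <- unwrap(g$wrapped)
  expect_equal(unwrap(u)$coords, u$coords)
})

test_that("pressure series I/O: CSV round trip is bit-identical, XVG skips directives", {
  o <- ou_pressure_series(100, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pressure_csv(o$series, path)
  back <- read_pressure_series(path, "csv", volume = 64,
                               temperature = 298.15)
  expect_identical(back$components, o$series$components)
  expect_identical(back$times, o$series$times)

  xvg <- c("# GROMACS-style comment", "@ title \"Pressure\"",
           "@ s0 legend \"Pxy\"",
           apply(cbind(o$series$times, o$series$components), 1,
                 function(r) paste(sprintf("%.8g", r), collapse = " ")))
  px <- withr::local_tempfile(fileext = ".xvg")
  writeLines(xvg, px)
  bx <- read_pressure_series(px, "xvg", volume = 64, temperature = 298.15)
  expect_equal(nrow(bx$components), 100L)
  expect_equal(unname(bx$components), unname(o$series$components),
               tolerance = 1e-7)

  zeros <- pressure_series(0:99, matrix(0, 100, 3), 64, 300)
  expect_equal(ncol(zeros$components), 6L)
  expect_true(all(zeros$components == 0))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,Pxy", "0,1"), bad)
  expect_error(read_pressure_series(bad, "csv", 64, 300), "3 or 6")
})

test_that("the constants table carries the canonical values exactly once", {
  expect_identical(crowd_constants$f_coulomb, 138.935458)
  expect_identical(crowd_constants$kB, 1.380649e-23)
  expect_identical(crowd_constants$xi_cubic, 2.837297)
  expect_false(any(duplicated(names(crowd_constants))))
  # conversion audit: the three pairings every module leans on
  expect_identical(crowd_constants$ang_to_nm, 0.1)
  expect_identical(crowd_constants$bar_to_Pa, 1e5)
  expect_identical(crowd_constants$nm2ps_to_1e5cm2s, 1000)
})

test_that("unmapped residues are an error, not a silent class guess", {
  expect_error(atom_table("X1", "XYZ", 1, mass = 1), "XYZ")
})
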