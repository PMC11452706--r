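test_that("PDB reader takes model 1, altloc A, ATOM records only", {
  f <- tempfile(fileext = ".pdb")
  write_pdb_fixture(f, c(
    pdb_atom_line(1, "N", "CYS", "A", 61, 1, 2, 3, "N"),
    pdb_atom_line(2, "CA", "CYS", "A", 61, 2, 3, 4, "C"),
    pdb_atom_line(3, "SG", "CYS", "A", 61, 3.5, 4.5, 5.5, "S"),
    "END"))
  s <- read_structure(f)
  expect_identical(nrow(s), 3L)
  expect_equal(s$x[3], 3.5)
  expect_equal(s$radius[3], 1.80)   # sulfur vdW
  expect_equal(s$radius[1], 1.55)   # nitrogen vdW

  # two MODELs: only the first is kept
  f2 <- tempfile(fileext = ".pdb")
  write_pdb_fixture(f2, c(
    "MODEL        1",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3, 0, 0, "C"),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 9, 9, 9, "C"),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 12, 9, 9, "C"),
    "ENDMDL", "END"))
  s2 <- read_structure(f2)
  expect_identical(nrow(s2), 2L)
  expect_equal(s2$x, c(0, 3))

  # altloc A/B pairs collapse to one atom per pair
  f3 <- tempfile(fileext = ".pdb")
  write_pdb_fixture(f3, c(
    pdb_atom_line(1, "CA", "SER", "A", 1, 0, 0, 0, "C", alt = "A"),
    pdb_atom_line(2, "CA", "SER", "A", 1, 0.5, 0, 0, "C", alt = "B"),
    pdb_atom_line(3, "OG", "SER", "A", 1, 1, 1, 1, "O", alt = "A"),
    pdb_atom_line(4, "OG", "SER", "A", 1, 1.5, 1, 1, "O", alt = "B"),
    pdb_atom_line(5, "CB", "SER", "A", 1, 2, 2, 2, "C"),
    "END"))
  s3 <- read_structure(f3)
  expect_identical(nrow(s3), 3L)   # manual count: 2 pairs + 1 plain
  unlink(c(f, f2, f3))
})

test_that("toy structure generators produce the named geometries", {
  lone <- generate_toy_structure("lone_atom")
  expect_identical(nrow(lone), 1L)
  wall <- generate_toy_structure("planar_wall", extent = 60, spacing = 1.5)
  expect_true(all(wall$z[wall$chain == "W"] == 0))
  cav <- generate_toy_structure("spherical_cavity", cavity_radius = 15,
                                spacing = 1.5)
  d <- sqrt(cav$x[-1]^2 + cav$y[-1]^2 + cav$z[-1]^2)
  expect_lt(max(abs(d - 15)), 1e-6)
  expect_error(generate_toy_structure("helix"), "arg")
})

test_that("lone-atom AV reproduces the analytic sphere", {
  toy <- generate_toy_structure("lone_atom")
  p <- av_params(linker_length = 10, grid_spacing = 0.5)
  av <- compute_av(toy, "A:1:X1", p, dye_radius = 1.5)
  v_sphere <- 4 / 3 * pi * 10^3
  expect_lt(abs(av$volume - v_sphere) / v_sphere, 0.05)
  expect_lt(sqrt(sum((av$mean_position - c(0, 0, 0))^2)), 0.5)
  # halving the spacing changes the volume by < 3 percent
  av2 <- compute_av(toy, "A:1:X1",
                    av_params(linker_length = 10, grid_spacing = 0.25),
                    dye_radius = 1.5)
  expect_lt(abs(av2$volume - av$volume) / av$volume, 0.03)
})

test_that("wall geometry yields the hemisphere centroid at 3L/8", {
  wall <- generate_toy_structure("planar_wall", extent = 60, spacing = 0.75,
                                 atom_radius = 0.3, wall_z = -0.75)
  p <- av_params(linker_length = 21, linker_width = 1.0, grid_spacing = 0.7)
  av <- compute_av(wall, "A:1:X1", p, dye_radius = 0.5)
  expect_true(all(av$points[, 3] >= 0))
  expect_lt(abs(av$mean_position[3] - 3 * 21 / 8), 0.5)
  expect_lt(max(abs(av$mean_position[1:2])), 0.2)
})

test_that("buried sites raise an explicit error", {
  cav <- generate_toy_structure("spherical_cavity", cavity_radius = 4,
                                spacing = 1.0, atom_radius = 1.7)
  # cavity clearance below the dye radius: nothing is allowed
  expect_error(compute_av(cav, "A:1:X1", av_params(linker_length = 10),
                          dye_radius = 5.5), "buried site")
  expect_error(compute_av(cav, "A:999:X1", av_params()), "not found")
})

test_that("three-radii AV reduces, orders and averages correctly", {
  toy <- generate_toy_structure("lone_atom")
  p_eq <- av_params(linker_length = 8, dye_radii = c(2, 2, 2),
                    grid_spacing = 0.6)
  av3 <- compute_av3(toy, "A:1:X1", p_eq)
  av1 <- compute_av(toy, "A:1:X1", p_eq, dye_radius = 2)
  expect_equal(av3$volume, av1$volume)
  expect_equal(sort(av3$points[, 1]), sort(av1$points[, 1]))
  # clearance monotonicity: smaller dye radius, larger AV
  cav <- generate_toy_structure("spherical_cavity", cavity_radius = 12,
                                spacing = 1.0)
  pr <- av_params(linker_length = 8, grid_spacing = 0.6)
  v_small <- compute_av(cav, "A:1:X1", pr, dye_radius = 1.5)$volume
  v_large <- compute_av(cav, "A:1:X1", pr, dye_radius = 5.5)$volume
  expect_gte(v_small, v_large)
  # AV3 mean position equals the weight-averaged mean of the three AVs
  wall <- generate_toy_structure("planar_wall", extent = 40, spacing = 0.75,
                                 atom_radius = 0.3, wall_z = -0.75)
  pw <- av_params(linker_length = 10, linker_width = 1.0,
                  dye_radii = c(2, 1.2, 0.5), grid_spacing = 0.7)
  av3w <- compute_av3(wall, "A:1:X1", pw)
  avs <- lapply(pw$dye_radii, function(r)
    compute_av(wall, "A:1:X1", pw, dye_radius = r))
  n_tot <- sum(vapply(avs, function(a) a$n_points, 1))
  mp <- Reduce(`+`, lapply(avs, function(a) a$mean_position * a$n_points)) / n_tot
  expect_lt(max(abs(av3w$mean_position - mp)), 1e-6)
})

test_that("AV is monotone under added atoms and invariant to atom order", {
  toy <- generate_toy_structure("lone_atom")
  p <- av_params(linker_length = 8, grid_spacing = 0.6)
  v0 <- compute_av(toy, "A:1:X1", p, dye_radius = 1.5)$volume
  wall <- generate_toy_structure("planar_wall", extent = 30, spacing = 1.0,
                                 atom_radius = 1.0, wall_z = -4.5)
  v1 <- compute_av(wall, "A:1:X1", p, dye_radius = 1.5)$volume
  expect_lt(v1, v0)
  set.seed(12)
  shuf <- wall[sample(nrow(wall)), ]
  class(shuf) <- class(wall)
  v1b <- compute_av(shuf, "A:1:X1", p, dye_radius = 1.5)$volume
  expect_equal(v1b, v1)
})

test_that("AV pair statistics match the exhaustive pair oracle", {
  # two lone attachment atoms 80 A apart, spherical AVs of radius 5
  s <- rbind(generate_toy_structure("lone_atom"),
             generate_toy_structure("lone_atom"))
  s$chain[2] <- "B"; s$x[2] <- 80
  class(s) <- c("av_structure", "data.frame")
  p <- av_params(linker_length = 5, grid_spacing = 1.0)
  av1 <- compute_av(s, "A:1:X1", p, dye_radius = 1.5)
  av2 <- compute_av(s, "B:1:X1", p, dye_radius = 1.5)
  st <- av_pair_stats(av1, av2, R0 = 59, n_samples = 2e5, seed = 3)
  # exhaustive double sum over the full grids
  dd <- sqrt(outer(rowSums(av1$points^2), rowSums(av2$points^2), "+") -
               2 * av1$points %*% t(av2$points))
  expect_lt(abs(st$mean_RDA - mean(dd)), 0.2)
  expect_equal(st$Rmp, sqrt(sum((av1$mean_position - av2$mean_position)^2)))
  expect_gte(st$mean_RDA, st$Rmp)   # Jensen-type inequality
  E_exh <- mean(1 / (1 + (dd / 59)^6))
  expect_lt(abs(st$mean_E - E_exh), 5 * st$se_E + 1e-4)
  # determinism given the seed
  st2 <- av_pair_stats(av1, av2, R0 = 59, n_samples = 2e5, seed = 3)
  expect_identical(st$mean_RDA, st2$mean_RDA)
  # coincident AVs have zero mean-position distance
  expect_equal(av_pair_stats(av1, av1, seed = 1)$Rmp, 0)
})

test_that("AV cloud export writes parseable pseudo-atom PDB", {
  toy <- generate_toy_structure("lone_atom")
  av <- compute_av(toy, "A:1:X1", av_params(linker_length = 5,
                                            grid_spacing = 1))
  f <- tempfile(fileext = ".pdb")
  write_av_pdb(av, f)
  txt <- readLines(f)
  expect_identical(sum(startsWith(txt, "HETATM")), av$n_points)
  unlink(f)
})
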