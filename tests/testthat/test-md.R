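# Conformation metrics: density profiles, mass centers, contact counts
# (cell list vs exhaustive oracle), RMSD, and profile comparison.

test_that("density profiles conserve mass under any binning", {
  set.seed(6)
  atoms <- random_atoms(800, lim = 25)
  atoms$xyz[, 3] <- abs(atoms$xyz[, 3])  # keep above the surface
  a <- atom_set(atoms$xyz, atoms$mass)
  for (bw in c(0.5, 1, 2, 5)) {
    p <- density_profile(a, bin_width = bw)
    expect_equal(sum(p$density) * bw * p$area, sum(a$mass), tolerance = 1e-9)
  }
  # halving the bin width leaves the integral unchanged
  p1 <- density_profile(a, bin_width = 2)
  p2 <- density_profile(a, bin_width = 1)
  expect_equal(sum(p1$density) * 2, sum(p2$density) * 1, tolerance = 1e-9)
  # all mass in one point -> single occupied bin holding the total
  one <- atom_set(matrix(c(0, 0, 30), 1), 99)
  po <- density_profile(one, bin_width = 1)
  expect_equal(sum(po$density > 0), 1)
  expect_equal(po$total_mass, 99)
  # atoms below the surface are flagged but binned
  below <- atom_set(matrix(c(0, 0, -3, 0, 0, 5), 2, byrow = TRUE), c(1, 1))
  expect_warning(pb <- density_profile(below), "below the surface")
  expect_equal(pb$total_mass, 2)
})

test_that("a uniform synthetic slab gives a flat profile with the right integral", {
  set.seed(7)
  n <- 40000
  a <- atom_set(cbind(runif(n, -20, 20), runif(n, -20, 20), runif(n, 0, 40)),
                rep(1, n))
  p <- density_profile(a, bin_width = 4)
  mid <- p$density[p$z > 4 & p$z < 36]
  expect_lt(sd(mid) / mean(mid), 0.05)  # flat within counting noise
  expect_equal(sum(p$density) * p$bin_width, n, tolerance = 1e-9)
})

test_that("mass centers are mass-weighted means and translate exactly", {
  two <- atom_set(matrix(c(0, 0, 10, 0, 0, 30), 2, byrow = TRUE), c(5, 5))
  expect_equal(md_mass_center_distance(two), 20)
  set.seed(8)
  a <- random_atoms(300)
  c0 <- md_mass_center_distance(a)
  shifted <- atom_set(sweep(a$xyz, 2, c(0, 0, 5)), a$mass)
  expect_equal(md_mass_center_distance(shifted), c0 - 5, tolerance = 1e-12)
  # surface_z offsets subtract directly
  expect_equal(md_mass_center_distance(a, surface_z = 3), c0 - 3, tolerance = 1e-12)
})

test_that("cell-list contact counts equal the exhaustive pairwise oracle", {
  surf <- make_silica_surface(lx = 60, ly = 60, spacing = 4)
  set.seed(9)
  for (rep in 1:100) {
    n <- sample(30:250, 1)
    prot <- atom_set(cbind(runif(n, -35, 35), runif(n, -35, 35),
                           runif(n, -2, 18)), rep(12, n))
    cutoff <- runif(1, 2, 8)
    expect_identical(contact_count(prot, surf, cutoff),
                     brute_contact_count(prot, surf, cutoff))
  }
  # larger configuration once, near the spec's upper size
  n <- 2000
  prot <- atom_set(cbind(runif(n, -50, 50), runif(n, -50, 50), runif(n, 0, 12)),
                   rep(12, n))
  expect_identical(contact_count(prot, surf, 5), brute_contact_count(prot, surf, 5))
})

test_that("contact counting uses a closed boundary and handles edge cases", {
  surf <- atom_set(matrix(c(0, 0, 0), 1), 20, group = "surface")
  at_cut <- atom_set(matrix(c(0, 0, 5), 1), 12)
  expect_identical(contact_count(at_cut, surf, 5), 1L)  # exactly at cutoff
  above <- atom_set(matrix(c(0, 0, 5.0001), 1), 12)
  expect_identical(contact_count(above, surf, 5), 0L)
  far <- atom_set(matrix(c(0, 0, 50), 1), 12)
  expect_identical(contact_count(far, surf, 5), 0L)
})

test_that("RMSD is zero for identical and rotated (superposed) sets", {
  set.seed(10)
  a <- matrix(rnorm(90), ncol = 3)
  expect_equal(rmsd(a, a), 0)
  # rigid rotation: raw RMSD > 0, superposed ~ 0
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
  b <- a %*% t(R) + matrix(rep(c(3, -2, 7), each = nrow(a)), ncol = 3)
  expect_gt(rmsd(a, b), 1)
  expect_lt(rmsd(a, b, superpose = TRUE), 1e-8)
  # pure translation by d: raw RMSD is exactly d
  d <- c(3, 4, 12)  # |d| = 13
  bt <- a + matrix(rep(d, each = nrow(a)), ncol = 3)
  expect_equal(rmsd(a, bt), 13, tolerance = 1e-12)
  # superposed never exceeds raw
  nz <- a + matrix(rnorm(90, 0, 0.3), ncol = 3)
  expect_lte(rmsd(a, nz, superpose = TRUE), rmsd(a, nz))
  expect_error(rmsd(a, a[1:10, ]), "mismatched")
})

test_that("superposition agrees with the reference implementation", {
  set.seed(12)
  a <- matrix(rnorm(150), ncol = 3)
  b <- a + matrix(rnorm(150, 0, 0.5), ncol = 3)
  ours <- rmsd(a, b, superpose = TRUE)
  ref <- bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("raw RMSD satisfies the triangle inequality", {
  set.seed(13)
  a <- matrix(rnorm(60), ncol = 3)
  for (i in 1:20) {
    b <- a + matrix(rnorm(60, 0, 0.5), ncol = 3)
    c2 <- a + matrix(rnorm(60, 0, 1.0), ncol = 3)
    expect_lte(rmsd(a, c2), rmsd(a, b) + rmsd(b, c2) + 1e-12)
  }
})

test_that("profile comparison is 1 for identity and 0 for disjoint supports", {
  prof <- density_profile(make_pseudo_protein("flat_on", 27.5, seed = 3),
                          bin_width = 2)
  # density profile vs itself recast as a volume-fraction profile
  self_nr <- structure(list(z = prof$z, phi = prof$density), class = "nr_profile")
  cmp <- compare_profiles(prof, self_nr)
  expect_equal(cmp$overlap, 1, tolerance = 1e-6)
  expect_equal(cmp$center_diff, 0, tolerance = 1e-9)
  # disjoint boxes
  nr_far <- structure(list(z = seq(200, 240, by = 1),
                           phi = rep(0.5, 41)), class = "nr_profile")
  expect_equal(compare_profiles(prof, nr_far)$overlap, 0, tolerance = 1e-12)
})

test_that("conformation at 27.5 A sits ~1.1 A beyond the reflectivity mass center", {
  atoms <- make_pseudo_protein("flat_on", center_z = 27.5, seed = 5)
  prof_md <- density_profile(atoms, bin_width = 1)
  prof_nr <- volume_fraction_profile(make_table1_stack("5.5"))
  cmp <- compare_profiles(prof_md, prof_nr)
  expect_equal(cmp$center_diff, 27.5 - mass_center_distance(make_table1_stack("5.5")),
               tolerance = 0.1)
  expect_equal(cmp$center_diff, 1.1, tolerance = 0.15)
  expect_gt(cmp$overlap, 0.5)  # the two profiles describe the same layer
})

test_that("XYZ-with-mass and PDB readers produce usable atom sets", {
  p <- tempfile(fileext = ".txt")
  writeLines(c("# pseudo atoms", "x,y,z,mass,label,group",
               "0,0,10,12,C,protein", "0,0,20,16,O,protein",
               "1,1,0,28,Si,surface"), p)
  a <- read_xyz_mass(p)
  expect_equal(nrow(a$xyz), 3)
  expect_equal(md_mass_center_distance(a), (10 * 12 + 20 * 16) / 28)
  expect_equal(surface_plane(a), 0)
  # headerless whitespace variant
  p2 <- tempfile(fileext = ".xyz")
  writeLines(c("0 0 10 12", "0 0 20 16"), p2)
  a2 <- read_xyz_mass(p2)
  expect_equal(a2$mass, c(12, 16))
  # minimal PDB through the bio3d-backed reader
  p3 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000  10.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000  11.000  1.00  0.00           C",
    "ATOM      3  O   ALA A   1       2.500   1.000  12.000  1.00  0.00           O",
    "END"), p3)
  a3 <- read_pdb_atoms(p3)
  expect_equal(nrow(a3$xyz), 3)
  expect_true(all(a3$mass > 10))
  expect_equal(unname(a3$xyz[2, "x"]), 1.5)
})
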