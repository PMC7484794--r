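test_that("volume and radius follow the partial-specific-volume scalings", {
  expect_equal(protein_volume(1000), 1.212)
  expect_equal(protein_volume(66000), 79.99, tolerance = 1e-4)
  expect_equal(protein_volume(2e5) / protein_volume(1e5), 2)
  expect_equal(protein_radius(1000), 0.66)
  expect_equal(protein_radius(1e6), 6.6)
  expect_equal(protein_radius(66000), 2.667, tolerance = 1e-3)
  expect_error(protein_volume(0), "invalid-measurement")
  expect_error(protein_radius(-1), "invalid-measurement")
})

test_that("sphere volume of R(M) matches V(M) within the rounding tolerance", {
  m <- 10^seq(3, 7, length.out = 200)
  rel <- abs((4 / 3) * pi * protein_radius(m)^3 - protein_volume(m)) /
    protein_volume(m)
  expect_lt(max(rel), 0.015)
})

test_that("sphere fallback footprint equals the equivalent-sphere cross-section", {
  fr <- cross_section_range(mass_da = 66000)
  expect_equal(fr$a_min, fr$a_max)
  expect_equal(fr$a_min, 22.34, tolerance = 1e-3)
  expect_equal(fr$source, "sphere_model")
})

test_that("projected footprints match a dense brute-force oracle", {
  tet <- tetrahedron_coords()
  got <- cross_section_range(coords = tet)
  oracle <- brute_force_cross_sections(tet, n_dirs = 4000)
  expect_equal(got$a_min, unname(oracle["min"]), tolerance = 0.02)
  expect_equal(got$a_max, unname(oracle["max"]), tolerance = 0.02)
  # a globular random cloud as a second shape
  set.seed(21)
  cloud <- matrix(rnorm(120), ncol = 3)
  got2 <- cross_section_range(coords = cloud)
  oracle2 <- brute_force_cross_sections(cloud, n_dirs = 4000)
  expect_equal(got2$a_min, unname(oracle2["min"]), tolerance = 0.02)
  expect_equal(got2$a_max, unname(oracle2["max"]), tolerance = 0.02)
})

test_that("degenerate geometries are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(cross_section_range(coords = line), "degenerate-geometry")
  plane <- cbind(runif(6), runif(6), 0)
  expect_error(cross_section_range(coords = plane), "degenerate-geometry")
  expect_error(cross_section_range(coords = tetrahedron_coords()[1:3, ]),
               "degenerate-geometry")
})

test_that("PDB ATOM records parse to nm coordinates", {
  pdb <- c(
    "HEADER    SYNTHETIC TEST",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CB AALA A   1      12.000   7.000  -4.000  1.00  0.00           C",
    "ATOM      4  CB BALA A   1      13.000   8.000  -3.000  1.00  0.00           C",
    "ENDMDL",
    "ATOM      5  N   ALA A   2      99.000  99.000  99.000  1.00  0.00           N")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  xyz <- read_pdb_coords(f)
  expect_equal(nrow(xyz), 3)  # altloc B and second model dropped
  expect_equal(xyz[1, 1], 1.1104)
})

test_that("coverage ratio is copy-weighted footprint over particle area", {
  copies <- rbind(p1 = c(100, 100))
  m <- cm_from_copies(copies, mw = 66000, captured = 2)
  fp <- data.frame(accession = "p1", a_min = 22.34, a_max = 22.34)
  cov <- coverage_ratio(m, fp, diameter_nm = 70, sample = "S1")
  expect_equal(unname(cov["lower"]), 0.1451, tolerance = 1e-3)
  expect_equal(unname(cov["lower"]), unname(cov["upper"]))
  # doubling copies doubles both bounds
  m2 <- cm_from_copies(2 * copies, mw = 66000, captured = 2)
  cov2 <- coverage_ratio(m2, fp, diameter_nm = 70, sample = "S1")
  expect_equal(unname(cov2), unname(2 * cov))
  # proteins with zero copies in a sample need no footprint there
  m0 <- cm_from_copies(rbind(p1 = c(0, 10), p2 = c(8, 4)),
                       mw = c(66000, 66000), captured = 2)
  fp2 <- data.frame(accession = "p2", a_min = 22.34, a_max = 22.34)
  cov0 <- coverage_ratio(m0, fp2, 70, "S1")
  expect_equal(unname(cov0["lower"]), 8 * 22.34 / (pi * 70^2))
  expect_error(coverage_ratio(m0, fp2, 70, "S2"), "incomplete-input")
  expect_error(coverage_ratio(m, fp[0, ], 70, "S1"), "incomplete-input")
})

test_that("coordinate footprints bracket the equal-volume sphere estimate", {
  # icosahedral-ish cloud scaled to the volume of a 66 kDa sphere
  set.seed(33)
  cloud <- matrix(rnorm(3 * 400), ncol = 3)
  cloud <- cloud / mean(sqrt(rowSums(cloud^2)))  # ~unit mean radius
  r_target <- protein_radius(66000)
  cloud <- cloud * r_target
  fr <- cross_section_range(coords = cloud)
  sphere <- sphere_cross_section(66000)
  expect_lt(fr$a_min, sphere * 3)
  expect_gt(fr$a_max, sphere * 0.8)
  expect_lte(fr$a_min, fr$a_max)
})
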