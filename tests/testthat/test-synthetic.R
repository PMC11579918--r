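test_that("noise-free flat bilayer puts every phosphate exactly on its leaflet", {
  sp <- bilayer_spec(bulk_thickness = 38.1, z_noise_sigma = 0,
                     xy_jitter_sigma = 0, n_frames = 1,
                     n_lipids_per_leaflet = 50, box_edge = 80, seed = 1)
  sys <- generate_bilayer(sp)$ensemble
  z <- frame_coords(sys)[, 3]
  upper <- z[z > 0]
  lower <- z[z < 0]
  expect_equal(unique(upper), 19.05)
  expect_equal(unique(lower), -19.05)
})

test_that("the thinning funnel follows its radial profile exactly", {
  sp <- bilayer_spec(bulk_thickness = 38.1, window_thickness = 20.1,
                     protein_radius = 10, n_protein_beads = 20,
                     decay_width = 25, z_noise_sigma = 0,
                     xy_jitter_sigma = 0, deep_phosphate_fraction = 0,
                     n_frames = 1, n_lipids_per_leaflet = 100, seed = 4)
  # at the protein surface the planted local thickness equals the window value
  expect_equal(bilayer_thickness_at(sp, 10), 20.1)
  expect_equal(bilayer_thickness_at(sp, 10 + sqrt(2 * log(2)) * 25),
               20.1 + (38.1 - 20.1) / 2)  # half decay at sqrt(2 ln 2) widths
  # far away it reverts to bulk
  expect_equal(bilayer_thickness_at(sp, 1e4), 38.1)

  sys <- generate_bilayer(sp)$ensemble
  tb <- subset(as_tibble(sys), role == "lipid_phosphate")
  rho <- sqrt(tb$x^2 + tb$y^2)
  expect_equal(abs(tb$z), bilayer_thickness_at(sp, rho) / 2, tolerance = 1e-12)
})

test_that("flat generation reduces to the special case of the funnel", {
  sp_flat <- bilayer_spec(protein_radius = 0, z_noise_sigma = 0,
                          xy_jitter_sigma = 0, n_frames = 1,
                          n_lipids_per_leaflet = 30, box_edge = 60, seed = 6)
  expect_equal(bilayer_thickness_at(sp_flat, c(0, 5, 70)),
               rep(sp_flat$bulk_thickness, 3))
})

test_that("generation is bitwise reproducible from the seed", {
  sp <- bilayer_spec(n_frames = 3, n_lipids_per_leaflet = 40,
                     protein_radius = 8, n_protein_beads = 15,
                     window_thickness = 25, box_edge = 70, seed = 77)
  g1 <- generate_bilayer(sp)
  g2 <- generate_bilayer(sp)
  expect_identical(g1$ensemble$coords, g2$ensemble$coords)
  expect_identical(g1$ensemble$topology, g2$ensemble$topology)
  sp2 <- bilayer_spec(n_frames = 3, n_lipids_per_leaflet = 40,
                      protein_radius = 8, n_protein_beads = 15,
                      window_thickness = 25, box_edge = 70, seed = 78)
  expect_false(identical(generate_bilayer(sp2)$ensemble$coords,
                         g1$ensemble$coords))
})

test_that("generator does not disturb the global RNG stream", {
  set.seed(123)
  a <- stats::rnorm(1)
  set.seed(123)
  invisible(generate_bilayer(bilayer_spec(n_frames = 1,
                                          n_lipids_per_leaflet = 20,
                                          box_edge = 50, seed = 9)))
  b <- stats::rnorm(1)
  expect_identical(a, b)
})

test_that("leaflets are symmetric within counting noise in flat regions", {
  sp <- bilayer_spec(n_frames = 20, n_lipids_per_leaflet = 200,
                     z_noise_sigma = 1, seed = 11)
  sys <- generate_bilayer(sp)$ensemble
  z <- as.vector(sys$coords[, seq_len(400), 3])
  up <- z[z > 0]
  dn <- z[z < 0]
  n <- length(up)
  expect_lt(abs(mean(up) + mean(dn)), 2 * 3 * 1 / sqrt(n))
})

test_that("species counts follow largest-remainder apportionment", {
  ratios <- er_lipid_composition()
  counts <- apportion_counts(200, ratios)
  expect_equal(sum(counts), 200L)
  quota <- 200 * ratios / sum(ratios)
  expect_true(all(abs(counts - quota) < 1))  # within one lipid of quota
  # degenerate and simple cases
  expect_equal(unname(apportion_counts(7, c(a = 1, b = 1))), c(4L, 3L))
  expect_equal(sum(apportion_counts(0, ratios)), 0L)

  truth <- generate_bilayer(bilayer_spec(n_lipids_per_leaflet = 200,
                                         n_frames = 1, seed = 1))$truth
  expect_equal(sum(truth$species_counts_per_leaflet), 200L)
  sys <- generate_bilayer(bilayer_spec(n_lipids_per_leaflet = 200,
                                       n_frames = 1, seed = 1))$ensemble
  realized <- table(sys$topology$resname[sys$topology$role == "lipid_phosphate"])
  expect_equal(sort(as.integer(realized), decreasing = TRUE),
               sort(as.integer(2 * truth$species_counts_per_leaflet),
                    decreasing = TRUE))
})

test_that("truth sidecar round-trips through its text serialization", {
  truth <- generate_bilayer(bilayer_spec(n_frames = 1,
                                         n_lipids_per_leaflet = 20,
                                         box_edge = 50, seed = 3))$truth
  path <- withr::local_tempfile(fileext = ".truth.txt")
  write_synthetic_truth(truth, path)
  back <- read_synthetic_truth(path)
  expect_equal(back$bulk_thickness, truth$bulk_thickness)
  expect_equal(back$seed, truth$seed)
  expect_equal(back[["composition.DYPC"]], 42)
})

test_that("ideal helices have exact axial spacing and direction", {
  h <- generate_helix(14, direction = c(0, 0, 1))
  z <- frame_coords(h)[, 3]
  expect_equal(diff(z), rep(1.5, 13))
  expect_equal(helix_span(14), 21)

  h17 <- generate_helix(17)
  expect_equal(helix_span(17), 25.5)
  expect_equal(max(frame_coords(h17)[, 3]) - min(frame_coords(h17)[, 3]),
               16 * 1.5)

  # a tilted helix keeps its axial spacing along the requested direction
  d <- c(1, 2, 2) / 3
  ht <- generate_helix(12, direction = d)
  proj <- frame_coords(ht) %*% d
  expect_equal(as.vector(diff(proj)), rep(1.5, 11))

  expect_error(generate_helix(3), ">= 4")
  expect_error(generate_helix(10, direction = c(0, 0, 0)), "nonzero")
})

test_that("helices constructed at a known angle recover that angle", {
  # 21 residues: the first- and last-three-residue centroids share the same
  # helical phase, so the endpoint axis is exact
  a <- generate_helix(21, direction = c(0, 0, 1))
  b <- generate_helix(21, direction = c(sin(pi / 6), 0, cos(pi / 6)))
  ax_a <- helix_axis(a, c(1, 21))
  ax_b <- helix_axis(b, c(1, 21))
  expect_lt(cross_angle(ax_a, c(0, 0, 1)), 0.5)
  expect_equal(cross_angle(ax_a, ax_b), 30, tolerance = 0.01)
  # exact on the construction directions themselves
  expect_equal(cross_angle(c(0, 0, 1), c(sin(pi / 6), 0, cos(pi / 6))), 30)
})

test_that("band tables recover planted cleavage", {
  exact <- generate_band_table(c(25, 50, 75), n_replicates = 4, cv = 0,
                               seed = 5)
  expect_equal(cleavage_percent(exact$cleaved, exact$full),
               rep(c(25, 50, 75), each = 4))

  mc <- generate_band_table(50, n_replicates = 1000, cv = 0.1, seed = 8)
  expect_lt(abs(mean(cleavage_percent(mc$cleaved, mc$full)) - 50), 1)

  t1 <- generate_band_table(c(10, 90), n_replicates = 3, cv = 0.2, seed = 13)
  t2 <- generate_band_table(c(10, 90), n_replicates = 3, cv = 0.2, seed = 13)
  expect_identical(t1, t2)
  expect_error(generate_band_table(50, cv = -0.1), "cv")
  expect_error(generate_band_table(120), "\\[0, 100\\]")
})

test_that("invalid bilayer specs are rejected", {
  expect_error(bilayer_spec(window_thickness = 40, bulk_thickness = 38),
               "window_thickness")
  expect_error(bilayer_spec(window_radius = 5, protein_radius = 10),
               "window_radius")
  expect_error(bilayer_spec(n_frames = 0), "n_frames")
  expect_error(
    generate_bilayer(bilayer_spec(n_lipids_per_leaflet = 500, box_edge = 80)),
    "lattice cannot host")
})
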