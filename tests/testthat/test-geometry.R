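random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

test_that("superposition exactly undoes a rigid transformation", {
  set.seed(51)
  ref <- matrix(stats::rnorm(30), 10, 3)
  R <- random_rotation()
  t <- c(3, -7, 12)
  mobile <- ref %*% t(R) + matrix(t, 10, 3, byrow = TRUE)
  sp <- kabsch_superpose(mobile, ref)
  expect_lt(sp$rmsd, 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)

  ident <- kabsch_superpose(ref, ref)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-10)
  expect_equal(ident$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_lt(ident$rmsd, 1e-12)
})

test_that("Kabsch agrees with the quaternion-method oracle on random clouds", {
  set.seed(52)
  for (i in 1:20) {
    a <- matrix(stats::rnorm(30), 10, 3)
    b <- a + matrix(stats::rnorm(30, sd = 0.3), 10, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd,
                 quaternion_superpose_rmsd(a, b), tolerance = 1e-8)
  }
})

test_that("degenerate selections are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 beads")
})

test_that("RMSD series is zero for a static ensemble and matches its composition oracle", {
  set.seed(53)
  nb <- 12
  base <- matrix(stats::rnorm(nb * 3, sd = 5), nb, 3)
  static <- array(rep(base, each = 4), dim = c(4, nb, 3))
  topo <- tibble::tibble(index = seq_len(nb) - 1L, name = "BB",
                         resname = "ALA", resid = seq_len(nb), chain = "A")
  sys <- md_ensemble(topo, static, box = c(50, 50, 50))
  expect_equal(rmsd_series(sys)$rmsd, rep(0, 4), tolerance = 1e-12)

  # moving ensemble: rmsd_series == per-frame kabsch + explicit formula
  coords <- array(stats::rnorm(5 * nb * 3, sd = 4), dim = c(5, nb, 3))
  sys2 <- md_ensemble(topo, coords, box = c(50, 50, 50))
  series <- rmsd_series(sys2, superpose = TRUE)
  expect_equal(series$rmsd[1], 0, tolerance = 1e-10)
  ref <- frame_coords(sys2, 1)
  manual <- vapply(1:5, function(f) {
    kabsch_superpose(frame_coords(sys2, f), ref)$rmsd
  }, numeric(1))
  expect_equal(series$rmsd, manual, tolerance = 1e-12)

  # without superposition the explicit formula applies directly
  raw <- rmsd_series(sys2, superpose = FALSE)
  manual_raw <- vapply(1:5, function(f) {
    sqrt(mean(rowSums((frame_coords(sys2, f) - ref)^2)))
  }, numeric(1))
  expect_equal(raw$rmsd, manual_raw, tolerance = 1e-12)
})

test_that("excluding residues changes RMSD only when those residues moved", {
  nb <- 10
  base <- cbind(seq_len(nb), (seq_len(nb) * 3) %% 7, (seq_len(nb) * 5) %% 11)
  moved <- base
  moved[5:6, ] <- moved[5:6, ] + 10  # only residues 5-6 move
  coords <- array(0, dim = c(2, nb, 3))
  coords[1, , ] <- base
  coords[2, , ] <- moved
  topo <- tibble::tibble(index = seq_len(nb) - 1L, name = "BB",
                         resname = "ALA", resid = seq_len(nb), chain = "A")
  sys <- md_ensemble(topo, coords, box = c(60, 60, 60))
  all_sel <- select_beads(sys, role = "protein_backbone")
  excl <- select_beads(sys, role = "protein_backbone",
                       exclude_resid = c(5, 6))
  with_all <- rmsd_series(sys, selection = all_sel, superpose = FALSE)
  without <- rmsd_series(sys, selection = excl, superpose = FALSE)
  expect_gt(with_all$rmsd[2], 0)
  expect_equal(without$rmsd[2], 0, tolerance = 1e-12)
})

test_that("RMSF matches the sigma*sqrt(3) closed form under isotropic jitter", {
  set.seed(54)
  nf <- 1e4; nb <- 10; sigma <- 0.8
  base <- matrix(stats::rnorm(nb * 3, sd = 5), nb, 3)
  coords <- array(rep(base, each = nf), dim = c(nf, nb, 3)) +
    array(stats::rnorm(nf * nb * 3, sd = sigma), dim = c(nf, nb, 3))
  topo <- tibble::tibble(index = seq_len(nb) - 1L, name = "BB",
                         resname = "ALA", resid = seq_len(nb), chain = "A")
  sys <- md_ensemble(topo, coords, box = c(60, 60, 60))
  prof <- rmsf_profile(sys, superpose_to_mean = FALSE)
  expect_equal(mean(prof$rmsf), sigma * sqrt(3),
               tolerance = 0.02)
})

test_that("RMSF is zero for static structures and invariant to global shifts", {
  nb <- 8
  set.seed(58)
  base <- matrix(stats::rnorm(nb * 3, sd = 4), nb, 3)
  static <- array(rep(base, each = 3), dim = c(3, nb, 3))
  topo <- tibble::tibble(index = seq_len(nb) - 1L, name = "BB",
                         resname = "ALA", resid = seq_len(nb), chain = "A")
  sys <- md_ensemble(topo, static, box = c(100, 100, 100))
  expect_equal(rmsf_profile(sys)$rmsf, rep(0, nb), tolerance = 1e-10)
  expect_error(rmsf_profile(md_ensemble(topo, static[1, , , drop = FALSE],
                                        box = c(100, 100, 100))),
               "2 frames")

  # per-frame global translation is removed by superposition to the mean
  set.seed(55)
  wob <- static
  for (f in 1:3) wob[f, , ] <- base + stats::rnorm(1, sd = 3)
  sys_w <- md_ensemble(topo, wob, box = c(100, 100, 100))
  expect_equal(rmsf_profile(sys_w, superpose_to_mean = TRUE)$rmsf,
               rep(0, nb), tolerance = 1e-8)

  # two identical replicates have zero across-replicate spread
  two <- rmsf_profile(list(sys_w, sys_w))
  expect_equal(two$replicate_sd, rep(0, nb), tolerance = 1e-12)
})

test_that("helix axes follow construction and flip with the residue range", {
  h <- generate_helix(21, direction = c(0, 0, 1))
  ax <- helix_axis(h, c(1, 21))
  expect_lt(cross_angle(ax, c(0, 0, 1)), 0.5)
  rev_ax <- helix_axis(h, c(21, 1))
  expect_equal(rev_ax$vector, -ax$vector, tolerance = 1e-12)
  expect_error(helix_axis(h, c(1, 4), n_end = 3), "at least 6")
})

test_that("endpoint centroids with n_end = 3 beat single-residue endpoints on noisy helices", {
  set.seed(56)
  errs <- replicate(40, {
    h <- generate_helix(21, direction = c(0, 0, 1))
    h$coords[1, , ] <- h$coords[1, , ] + stats::rnorm(21 * 3, sd = 0.5)
    c(cross_angle(helix_axis(h, c(1, 21), n_end = 1), c(0, 0, 1)),
      cross_angle(helix_axis(h, c(1, 21), n_end = 3), c(0, 0, 1)))
  })
  expect_gt(mean(errs[1, ]), mean(errs[2, ]))
})

test_that("cross angles respect construction, folding and rigid rotation", {
  expect_equal(cross_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(cross_angle(c(0, 0, 1), c(0, 1, 0)), 90)
  expect_equal(cross_angle(c(0, 0, 1), c(0, 0, -1)), 180)
  expect_equal(cross_angle(c(0, 0, 1), c(0, 0, -1), fold_to_90 = TRUE), 0)
  expect_error(cross_angle(c(0, 0, 0), c(0, 0, 1)), "zero")

  # orthogonal constructed helices
  a <- generate_helix(21, direction = c(0, 0, 1))
  b <- generate_helix(21, direction = c(1, 0, 0))
  ang <- cross_angle(helix_axis(a, c(1, 21)), helix_axis(b, c(1, 21)))
  expect_equal(ang, 90, tolerance = 0.5 / 90)

  # invariance under a common rigid rotation
  set.seed(57)
  v1 <- c(0.2, -0.5, 1); v2 <- c(1, 0.3, -0.2)
  base_ang <- cross_angle(v1, v2)
  for (i in 1:5) {
    R <- random_rotation()
    expect_equal(cross_angle(as.vector(R %*% v1), as.vector(R %*% v2)),
                 base_ang, tolerance = 1e-6 / base_ang)
  }
})

test_that("per-frame cross-angle series summarizes frames", {
  a <- generate_helix(21, direction = c(0, 0, 1))
  b <- generate_helix(21, direction = c(sin(pi / 4), 0, cos(pi / 4)),
                      origin = c(20, 0, 0))
  combined_topo <- dplyr::bind_rows(
    a$topology,
    dplyr::mutate(b$topology, index = index + 21L,
                  resid = resid + 100L, chain = "B"))
  coords <- array(0, dim = c(2, 42, 3))
  for (f in 1:2) {
    coords[f, 1:21, ] <- a$coords[1, , ]
    coords[f, 22:42, ] <- b$coords[1, , ]
  }
  sys <- md_ensemble(combined_topo, coords, box = c(200, 200, 200))
  ser <- cross_angle_series(sys, c(1, 21), c(101, 121))
  expect_equal(nrow(ser), 2L)
  expect_equal(ser$angle, rep(45, 2), tolerance = 0.01)
  expect_equal(attr(ser, "sd"), 0)
})

test_that("helix span arithmetic", {
  expect_equal(helix_span(14), 21)
  expect_equal(helix_span(17), 25.5)
  expect_equal(helix_span(1), 1.5)
  expect_equal(helix_span(10, rise_per_residue = 1.2), 12)
})
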