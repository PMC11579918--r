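two_bead_window_system <- function(d1, d2) {
  # protein bead at origin; two phosphates at lateral distances d1 and d2
  xyz <- rbind(c(0, 0, 0), c(d1, 0, 0), c(d2, 0, 0))
  topo <- tibble::tibble(index = 0:2, name = c("BB", "PO4", "PO4"),
                         resname = c("ALA", "POPC", "POPC"),
                         resid = 1:3, chain = c("P", "M", "M"))
  md_ensemble(topo, xyz, box = rep(50, 3))
}

test_that("window membership respects the distance boundary", {
  sys <- two_bead_window_system(5.9, 6.1)
  sel <- tm_window_selection(sys, 0L, c(1L, 2L), cutoff = 6)
  expect_equal(sel$frames[[1]], 1L)  # 5.9 in, 6.1 out
  on_edge <- two_bead_window_system(6.0, 8.0)
  sel2 <- tm_window_selection(on_edge, 0L, c(1L, 2L), cutoff = 6)
  expect_equal(sel2$frames[[1]], 1L)  # exactly at the cutoff is included
  expect_error(tm_window_selection(sys, 0L, 1:2, cutoff = 0), "cutoff")
  expect_error(tm_window_selection(sys, integer(0), 1:2), "protein")
})

test_that("larger cutoffs select supersets and match the brute-force oracle", {
  sp <- bilayer_spec(bulk_thickness = 38.1, window_thickness = 22,
                     protein_radius = 10, n_protein_beads = 40,
                     n_lipids_per_leaflet = 220, n_frames = 3, seed = 17)
  sys <- generate_bilayer(sp)$ensemble
  prot <- select_beads(sys, role = "protein_backbone")
  po4 <- select_beads(sys, role = "lipid_phosphate")
  sel6 <- tm_window_selection(sys, prot, po4, cutoff = 6)
  sel8 <- tm_window_selection(sys, prot, po4, cutoff = 8)
  for (f in seq_len(n_frames(sys))) {
    expect_true(all(sel6$frames[[f]] %in% sel8$frames[[f]]))
    expect_identical(sel6$frames[[f]],
                     brute_force_window(sys, prot, po4, 6, f))
    expect_identical(sel8$frames[[f]],
                     brute_force_window(sys, prot, po4, 8, f))
  }
})

test_that("double-Gaussian fits recover constructed leaflet peaks", {
  prof <- gaussian_mixture_profile(means = c(-19.05, 19.05),
                                   sigmas = c(1, 1), amplitudes = c(1, 1))
  fit <- fit_leaflet_gaussians(prof, 2)
  expect_true(fit$converged)
  expect_equal(sort(fit$components$mean), c(-19.05, 19.05),
               tolerance = 0.01 / 19.05)
  expect_gt(fit$r_squared, 0.999)
  expect_equal(thickness_from_fit(fit), 38.1, tolerance = 1e-3)
})

test_that("triple fits handle a mid-plane component that double fits absorb", {
  # well-separated leaflets with a weak mid component: both readings agree
  wide <- gaussian_mixture_profile(means = c(-19.05, 0, 19.05),
                                   sigmas = c(1, 3, 1),
                                   amplitudes = c(1, 0.1, 1))
  fit3w <- fit_leaflet_gaussians(wide, 3)
  expect_true(fit3w$converged)
  expect_equal(range(fit3w$components$mean), c(-19.05, 19.05),
               tolerance = 0.05 / 19.05)
  expect_equal(thickness_from_fit(fit3w), 38.1, tolerance = 0.05 / 38.1)

  # window-like geometry where the mid population overlaps the leaflets:
  # the triple fit recovers the planted separation, the double fit is pulled
  # inward by the mid-plane density
  prof <- gaussian_mixture_profile(means = c(-10.05, 0, 10.05),
                                   sigmas = c(2, 4, 2),
                                   amplitudes = c(1, 0.25, 1))
  fit3 <- fit_leaflet_gaussians(prof, 3)
  expect_true(fit3$converged)
  expect_equal(thickness_from_fit(fit3), 20.1, tolerance = 0.05 / 20.1)

  fit2 <- fit_leaflet_gaussians(prof, 2)
  sep2 <- thickness_from_fit(fit2)
  expect_lt(sep2, 20.1 - 0.05)
  expect_gt(abs(sep2 - 20.1), abs(thickness_from_fit(fit3) - 20.1))
})

test_that("triple fits report an explicit null mid component when the core is empty", {
  prof <- gaussian_mixture_profile(means = c(-15, 15), sigmas = c(1.2, 1.2),
                                   amplitudes = c(1, 1))
  fit <- fit_leaflet_gaussians(prof, 3)
  expect_true(fit$converged)
  expect_equal(nrow(fit$components), 3L)
  expect_equal(thickness_from_fit(fit), 30, tolerance = 1e-3)
  expect_lt(min(fit$components$amplitude), 0.01 * max(fit$components$amplitude))
})

test_that("degenerate profiles fail initialization loudly", {
  flat <- gaussian_mixture_profile(means = 0, sigmas = 1, amplitudes = 0)
  expect_error(fit_leaflet_gaussians(flat, 2), "nonzero bins")
  one_peak <- gaussian_mixture_profile(means = 0, sigmas = 2, amplitudes = 1)
  expect_error(fit_leaflet_gaussians(one_peak, 2), "peaks")
})

test_that("thickness reads the outermost means and is shift invariant", {
  prof <- gaussian_mixture_profile(means = c(-10.05, 0, 10.05),
                                   sigmas = c(1, 2, 1),
                                   amplitudes = c(1, 0.15, 1))
  fit <- fit_leaflet_gaussians(prof, 3)
  expect_equal(thickness_from_fit(fit), 20.1, tolerance = 0.05 / 20.1)

  shifted <- gaussian_mixture_profile(means = c(-10.05, 0, 10.05) + 5,
                                      sigmas = c(1, 2, 1),
                                      amplitudes = c(1, 0.15, 1),
                                      z = seq(-25, 35, by = 1))
  fit_s <- fit_leaflet_gaussians(shifted, 3)
  expect_equal(thickness_from_fit(fit_s), thickness_from_fit(fit),
               tolerance = 1e-6)
  # amplitude scaling leaves the thickness unchanged
  scaled <- gaussian_mixture_profile(means = c(-10.05, 0, 10.05),
                                     sigmas = c(1, 2, 1),
                                     amplitudes = 7 * c(1, 0.15, 1))
  expect_equal(thickness_from_fit(fit_leaflet_gaussians(scaled, 3)),
               thickness_from_fit(fit), tolerance = 1e-6)

  unconv <- memthin:::new_gaussian_fit(NULL, 3, converged = FALSE)
  expect_error(thickness_from_fit(unconv), "unconverged")
})

test_that("bulk pipeline recovers the planted thickness across replicates", {
  reps <- lapply(1:3, function(r) {
    generate_bilayer(bilayer_spec(bulk_thickness = 38.1, z_noise_sigma = 1,
                                  n_lipids_per_leaflet = 200, n_frames = 50,
                                  seed = 100 + r))$ensemble
  })
  res <- thickness_pipeline(reps, region = "bulk")
  expect_s3_class(res, "thickness_result")
  expect_equal(res$method, "double")
  expect_equal(res$mean, 38.1, tolerance = 0.3 / 38.1)
  expect_gt(res$sem, 0)
  expect_equal(res$n_replicates, 3L)
  expect_equal(glance(res)$mean, res$mean)
  expect_equal(nrow(tidy(res)), 3L)
})

test_that("a single replicate reports SEM 0 with a warning", {
  one <- generate_bilayer(bilayer_spec(n_frames = 30,
                                       n_lipids_per_leaflet = 100,
                                       seed = 41))$ensemble
  expect_warning(res <- thickness_pipeline(one, region = "bulk"),
                 "SEM reported as 0")
  expect_equal(res$sem, 0)
  expect_equal(res$n_replicates, 1L)
})

test_that("relative thinning reproduces the headline arithmetic", {
  expect_equal(round(relative_thinning(38.1, 20.1)), 47)
  expect_equal(relative_thinning(38.1, 20.1), 47.2441, tolerance = 1e-5)
  expect_equal(relative_thinning(38.1, 23.1), 39.3701, tolerance = 1e-5)
  expect_equal(relative_thinning(30, 30), 0)
  expect_warning(neg <- relative_thinning(20, 25), "negative")
  expect_lt(neg, 0)
  expect_error(relative_thinning(0, 10), "bulk")
  # complement identity: planting w = b (1 - p/100) recovers p exactly
  for (p in c(10, 40, 47.2, 80)) {
    expect_equal(relative_thinning(38.1, 38.1 * (1 - p / 100)), p)
  }
})

test_that("thickness differences propagate SEMs in quadrature", {
  d <- thickness_difference(23.1, 20.1, sem_a = 0.16, sem_b = 0.54)
  expect_equal(d$difference, 3, tolerance = 1e-12)
  expect_equal(d$propagated_error, sqrt(0.16^2 + 0.54^2), tolerance = 1e-12)
  expect_equal(round(d$propagated_error, 3), 0.563)
  same <- thickness_difference(21.7, 21.7)
  expect_equal(same$difference, 0)
})
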