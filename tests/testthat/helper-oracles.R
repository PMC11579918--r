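# Independent oracles used across the suite. These deliberately use different
# algorithms from the package implementation.

# Horn's quaternion method for optimal rigid superposition: the rotation is
# recovered from the dominant eigenvector of the 4x4 key matrix, entirely
# independent of the SVD route used by kabsch_superpose().
quaternion_superpose_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  M <- t(P) %*% Q
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lambda) / nrow(P)
  sqrt(max(msd, 0))
}

# brute-force O(N * M) double loop for the proximity window
brute_force_window <- function(system, protein_idx, lipid_idx, cutoff,
                               frame) {
  P <- frame_coords(system, frame)[as.integer(protein_idx) + 1L, , drop = FALSE]
  L <- frame_coords(system, frame)[as.integer(lipid_idx) + 1L, , drop = FALSE]
  keep <- logical(nrow(L))
  for (i in seq_len(nrow(L))) {
    best <- Inf
    for (j in seq_len(nrow(P))) {
      d <- sqrt(sum((L[i, ] - P[j, ])^2))
      if (d < best) best <- d
    }
    keep[i] <- best <= cutoff
  }
  as.integer(lipid_idx)[keep]
}

# construct a density-profile-like data frame from an exact Gaussian mixture
gaussian_mixture_profile <- function(means, sigmas, amplitudes,
                                     z = seq(-30, 30, by = 1)) {
  y <- rep(0, length(z))
  for (k in seq_along(means)) {
    y <- y + amplitudes[k] * exp(-(z - means[k])^2 / (2 * sigmas[k]^2))
  }
  structure(tibble::tibble(z = z, density = y),
            selection_descriptor = "constructed mixture",
            class = c("density_profile", "tbl_df", "tbl", "data.frame"))
}

# small hand-built ensemble: beads at given coordinates, all one role source
toy_ensemble <- function(xyz, names = "PO4", resnames = "POPC", box = 100) {
  n <- nrow(xyz)
  topo <- tibble::tibble(
    index = seq_len(n) - 1L,
    name = rep_len(names, n),
    resname = rep_len(resnames, n),
    resid = seq_len(n),
    chain = "A"
  )
  md_ensemble(topo, xyz, box = rep(box, 3), source_format = "synthetic")
}
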