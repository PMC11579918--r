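#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Computes the proper rotation (det = +1) and translation minimizing the
#' RMSD between the selected beads of a mobile and a reference frame, via
#' SVD of the covariance of the centered coordinate sets.
#'
#' @param mobile,reference `beads x 3` coordinate matrices, or
#'   [md_ensemble()] objects (their first frame is used).
#' @param selection Optional `bead_selection`/0-based indices applied to both.
#' @return List with `rotation` (3x3), `translation` (length 3; the
#'   superposed mobile is `mobile %*% t(rotation) + translation`), and `rmsd`
#'   (angstrom, over the selection after superposition).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  M <- coords_matrix(mobile, selection)
  R0 <- coords_matrix(reference, selection)
  if (nrow(M) != nrow(R0)) stop("selections differ in size")
  if (nrow(M) < 3) stop("need at least 3 beads for superposition")
  cm <- colMeans(M)
  cr <- colMeans(R0)
  Mc <- sweep(M, 2, cm)
  Rc <- sweep(R0, 2, cr)
  if (collinear(Mc) || collinear(Rc)) {
    stop("degenerate (collinear) selection; superposition is ill-defined")
  }
  H <- t(Mc) %*% Rc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  rot <- sv$v %*% D %*% t(sv$u)
  trans <- cr - as.vector(rot %*% cm)
  fitted <- Mc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - Rc)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

coords_matrix <- function(x, selection = NULL, frame = 1L) {
  m <- if (inherits(x, "md_ensemble")) frame_coords(x, frame) else as.matrix(x)
  if (!is.null(selection)) {
    idx <- as.integer(selection) + 1L
    if (length(idx) == 0L) stop("empty selection")
    m <- m[idx, , drop = FALSE]
  }
  m
}

collinear <- function(centered, tol = 1e-10) {
  s <- svd(centered, nu = 0, nv = 0)$d
  sum(s > tol * max(s, tol)) < 2
}

#' Per-frame RMSD from a reference frame
#'
#' Root mean squared deviation of the selected beads from a reference frame,
#' after (by default) rigid superposition on the same selection.
#'
#' @param ensemble An [md_ensemble()].
#' @param reference_frame Frame number used as the reference (default 1), or
#'   a `beads x 3` matrix of reference coordinates for the full topology.
#' @param selection `bead_selection`/0-based indices; default all beads.
#' @param superpose Superpose each frame before measuring (default `TRUE`).
#' @return A tibble with `frame`, `time` and `rmsd` (angstrom).
#' @export
rmsd_series <- function(ensemble, reference_frame = 1L, selection = NULL,
                        superpose = TRUE) {
  stopifnot(inherits(ensemble, "md_ensemble"))
  ref <- if (is.matrix(reference_frame)) {
    reference_frame
  } else {
    frame_coords(ensemble, reference_frame)
  }
  idx <- if (is.null(selection)) seq_len(n_beads(ensemble)) else as.integer(selection) + 1L
  if (length(idx) == 0L) stop("empty selection")
  refsel <- ref[idx, , drop = FALSE]
  nf <- n_frames(ensemble)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    m <- frame_coords(ensemble, f)[idx, , drop = FALSE]
    if (superpose) {
      sp <- kabsch_superpose(m, refsel)
      out[f] <- sp$rmsd
    } else {
      out[f] <- sqrt(mean(rowSums((m - refsel)^2)))
    }
  }
  tibble::tibble(frame = seq_len(nf), time = ensemble$time, rmsd = out)
}

#' Per-bead RMSF profile, optionally averaged over replicates
#'
#' Root mean squared fluctuation about the mean structure,
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)`, after (by default)
#' superposing every frame onto the ensemble-mean structure of the selection
#' (two refinement passes: superpose to the raw mean, recompute the mean,
#' superpose again). With replicate ensembles the profile is the across-
#' replicate mean and `replicate_sd` the across-replicate standard deviation.
#'
#' @param ensemble An [md_ensemble()] (>= 2 frames), or a list of replicate
#'   ensembles.
#' @param selection `bead_selection`/0-based indices; default all beads.
#' @param superpose_to_mean Superpose frames to the mean structure first
#'   (default `TRUE`). Disable to measure raw fluctuations (e.g. against the
#'   `sigma * sqrt(3)` closed form for isotropic jitter).
#' @return An `rmsf_profile` tibble with `bead` (0-based index within the
#'   system), `rmsf` (angstrom) and, with replicates, `replicate_sd`.
#' @export
rmsf_profile <- function(ensemble, selection = NULL,
                         superpose_to_mean = TRUE) {
  if (inherits(ensemble, "md_ensemble")) {
    prof <- rmsf_single(ensemble, selection, superpose_to_mean)
    prof$replicate_sd <- rep(NA_real_, nrow(prof))
    return(prof)
  }
  stopifnot(is.list(ensemble), length(ensemble) >= 1)
  profs <- lapply(ensemble, rmsf_single, selection = selection,
                  superpose_to_mean = superpose_to_mean)
  mat <- do.call(cbind, lapply(profs, function(p) p$rmsf))
  out <- profs[[1]]
  out$rmsf <- rowMeans(mat)
  out$replicate_sd <- apply(mat, 1, stats::sd)
  out
}

rmsf_single <- function(ensemble, selection, superpose_to_mean) {
  stopifnot(inherits(ensemble, "md_ensemble"))
  if (n_frames(ensemble) < 2) stop("RMSF needs at least 2 frames")
  idx <- if (is.null(selection)) seq_len(n_beads(ensemble)) else as.integer(selection) + 1L
  if (length(idx) == 0L) stop("empty selection")
  nf <- n_frames(ensemble)
  stack <- ensemble$coords[, idx, , drop = FALSE]
  if (superpose_to_mean) {
    for (pass in 1:2) {
      mean_xyz <- apply(stack, c(2, 3), mean)
      for (f in seq_len(nf)) {
        m <- matrix(stack[f, , ], ncol = 3)
        sp <- kabsch_superpose(m, mean_xyz)
        stack[f, , ] <- sweep(m %*% t(sp$rotation), 2, sp$translation, `+`)
      }
    }
  }
  mean_xyz <- apply(stack, c(2, 3), mean)
  dev2 <- sweep(stack, c(2, 3), mean_xyz)^2
  rmsf <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames & axes, x3 axes
  desc <- attr(selection, "descriptor") %||% "all"
  out <- tibble::tibble(bead = idx - 1L, rmsf = rmsf)
  structure(out, selection_descriptor = desc,
            class = c("rmsf_profile", class(out)))
}

#' Helix axis from endpoint residue centroids
#'
#' The axis vector runs from the centroid of the backbone beads of the first
#' `n_end` residues to the centroid of the last `n_end` residues of the
#' range, oriented in sequence order.
#'
#' @param system An [md_ensemble()].
#' @param residue_range `c(first, last)` residue ids (file numbering,
#'   inclusive). `first > last` reverses the orientation.
#' @param frame Frame number (default 1).
#' @param n_end Number of endpoint residues per centroid (default 3).
#' @param backbone_roles Roles counted as backbone.
#' @return A `helix_axis`: list with `start_centroid`, `end_centroid`,
#'   `vector` (all angstrom).
#' @export
helix_axis <- function(system, residue_range, frame = 1L, n_end = 3L,
                       backbone_roles = "protein_backbone") {
  stopifnot(inherits(system, "md_ensemble"), length(residue_range) == 2)
  resids <- seq(residue_range[1], residue_range[2])
  if (length(resids) < 2 * n_end) {
    stop("residue range must contain at least ", 2 * n_end, " residues")
  }
  topo <- system$topology
  bb <- topo$role %in% backbone_roles
  centroid_of <- function(ids) {
    rows <- which(bb & topo$resid %in% ids)
    if (length(rows) == 0L) stop("no backbone beads for residues ",
                                 paste(range(ids), collapse = "-"))
    colMeans(frame_coords(system, frame)[rows, , drop = FALSE])
  }
  start_c <- centroid_of(resids[seq_len(n_end)])
  end_c <- centroid_of(resids[seq(length(resids) - n_end + 1L, length(resids))])
  v <- end_c - start_c
  if (sqrt(sum(v^2)) < 1e-12) stop("degenerate helix axis (zero vector)")
  structure(list(start_centroid = start_c, end_centroid = end_c, vector = v),
            class = "helix_axis")
}

#' Axial span of an ideal helix
#'
#' `n_residues * rise_per_residue`: the membrane thickness an ideal
#' transmembrane helix of that length matches (1.5 A rise per residue for a
#' canonical alpha-helix; a 14-residue hydrophobic stretch spans ~21 A).
#'
#' @param n_residues Number of residues (>= 1).
#' @param rise_per_residue Axial rise per residue, angstrom (default 1.5).
#' @return Span in angstrom.
#' @export
helix_span <- function(n_residues, rise_per_residue = 1.5) {
  stopifnot(n_residues >= 1)
  n_residues * rise_per_residue
}

#' Crossing angle between two helix axes
#'
#' `arccos` of the dot product of the unit axis vectors, in degrees within
#' `[0, 180]`; optionally folded to `[0, 90]` (so antiparallel reads 0).
#'
#' @param a,b `helix_axis` objects or bare 3-vectors.
#' @param fold_to_90 Fold to `[0, 90]` (default `FALSE`).
#' @return Angle in degrees.
#' @export
cross_angle <- function(a, b, fold_to_90 = FALSE) {
  va <- if (inherits(a, "helix_axis")) a$vector else as.numeric(a)
  vb <- if (inherits(b, "helix_axis")) b$vector else as.numeric(b)
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na < 1e-12 || nb < 1e-12) stop("zero-length axis vector")
  cosang <- sum(va * vb) / (na * nb)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (fold_to_90 && ang > 90) ang <- 180 - ang
  ang
}

#' Per-frame crossing-angle series between two helices
#'
#' @param system An [md_ensemble()].
#' @param range_a,range_b Residue ranges of the two helices
#'   (see [helix_axis()]).
#' @param n_end Endpoint residues per centroid.
#' @param fold_to_90 Fold angles to `[0, 90]`.
#' @return An `angle_series` tibble with `frame`, `time`, `angle` (degrees),
#'   plus `mean`/`sd` attributes.
#' @export
cross_angle_series <- function(system, range_a, range_b, n_end = 3L,
                               fold_to_90 = FALSE) {
  nf <- n_frames(system)
  ang <- vapply(seq_len(nf), function(f) {
    cross_angle(helix_axis(system, range_a, frame = f, n_end = n_end),
                helix_axis(system, range_b, frame = f, n_end = n_end),
                fold_to_90 = fold_to_90)
  }, numeric(1))
  out <- tibble::tibble(frame = seq_len(nf), time = system$time, angle = ang)
  structure(out, mean = mean(ang), sd = stats::sd(ang),
            class = c("angle_series", class(out)))
}
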