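#' ER membrane lipid composition
#'
#' Ten-species endoplasmic-reticulum model-membrane composition
#' (DYPC:YOPC:POPI:PYPI:DYPE:YOPE:ERGO:YOPA:YOPS:POPS at
#' 42:28:21:14:10:10:7:6:6:6), used as the default composition of the
#' synthetic bilayer generator. `popc_composition()` gives the single-species
#' control membrane.
#'
#' @return Named numeric vector of ratios (not normalized).
#' @export
er_lipid_composition <- function() {
  c(DYPC = 42, YOPC = 28, POPI = 21, PYPI = 14, DYPE = 10,
    YOPE = 10, ERGO = 7, YOPA = 6, YOPS = 6, POPS = 6)
}

#' @rdname er_lipid_composition
#' @export
popc_composition <- function() c(POPC = 1)

#' Specification of a synthetic bilayer system
#'
#' Describes a planar two-leaflet bilayer with optional protein-proximal
#' thinning: away from the protein the phosphate leaflets sit at
#' `+/- bulk_thickness/2`; within the deformation funnel the local thickness
#' decays smoothly to `window_thickness` at the protein surface,
#' `T(rho) = Tw + (Tb - Tw) * (1 - exp(-max(0, rho - protein_radius)^2 /
#' (2 * decay_width^2)))` with `rho` the radial distance from the box-center
#' axis. Vertical Gaussian noise of `z_noise_sigma` and lateral jitter of
#' `xy_jitter_sigma` are drawn independently per frame.
#'
#' @param bulk_thickness Bulk leaflet peak separation, angstrom.
#' @param window_thickness Thickness at the protein surface, angstrom
#'   (`0 < window_thickness <= bulk_thickness`).
#' @param window_radius Radius of the region tagged as the TM window
#'   (>= `protein_radius`); deep mid-plane phosphates are only planted here.
#' @param decay_width Radial decay length of the thinning funnel, angstrom.
#' @param n_lipids_per_leaflet Lipids (one PO4 bead each) per leaflet.
#' @param area_per_lipid Lattice area per lipid, square angstrom.
#' @param z_noise_sigma,xy_jitter_sigma Per-frame Gaussian noise, angstrom.
#' @param n_frames Number of frames (>= 1).
#' @param protein_radius,protein_half_height,n_protein_beads Geometry of the
#'   embedded protein cylinder (`protein_radius = 0` or
#'   `n_protein_beads = 0` means no protein). The default half height,
#'   `window_thickness / 2 + 5`, makes the cylinder span the local membrane
#'   like a transmembrane protein, whatever the planted thickness.
#' @param deep_phosphate_fraction Fraction of window lipids whose phosphate
#'   dwells near the mid-plane (emulating headgroups coordinated deep inside
#'   the TM window); only active when a protein is present.
#' @param water_slab Add water beads above and below the membrane.
#' @param water_density Water bead number density, beads per cubic angstrom.
#' @param composition Named ratios of lipid species; apportioned to realized
#'   counts by largest remainder.
#' @param box_edge Lateral box edge, angstrom (box is `box_edge^2 x box_z`).
#' @param box_z Box height, angstrom.
#' @param ar1_phi Optional AR(1) coefficient in `[0, 1)` for temporally
#'   correlated z-noise (0 = white noise).
#' @param seed Integer seed; everything the generator draws derives from it.
#' @return A `bilayer_spec` (named list).
#' @export
bilayer_spec <- function(bulk_thickness = 38.1,
                         window_thickness = bulk_thickness,
                         window_radius = 16,
                         decay_width = 25,
                         n_lipids_per_leaflet = 200,
                         area_per_lipid = 64,
                         z_noise_sigma = 1,
                         xy_jitter_sigma = 1,
                         n_frames = 100,
                         protein_radius = 0,
                         protein_half_height = NULL,
                         n_protein_beads = 0,
                         deep_phosphate_fraction = 0.05,
                         water_slab = FALSE,
                         water_density = 0.004,
                         composition = er_lipid_composition(),
                         box_edge = 150,
                         box_z = 150,
                         ar1_phi = 0,
                         seed = 1L) {
  spec <- list(bulk_thickness = bulk_thickness,
               window_thickness = window_thickness,
               window_radius = window_radius, decay_width = decay_width,
               n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
               area_per_lipid = area_per_lipid,
               z_noise_sigma = z_noise_sigma,
               xy_jitter_sigma = xy_jitter_sigma,
               n_frames = as.integer(n_frames),
               protein_radius = protein_radius,
               protein_half_height = protein_half_height %||%
                 (window_thickness / 2 + 5),
               n_protein_beads = as.integer(n_protein_beads),
               deep_phosphate_fraction = deep_phosphate_fraction,
               water_slab = isTRUE(water_slab),
               water_density = water_density,
               composition = composition,
               box_edge = box_edge, box_z = box_z,
               ar1_phi = ar1_phi,
               seed = as.integer(seed))
  if (!(spec$window_thickness > 0 && spec$window_thickness <= spec$bulk_thickness)) {
    stop("need 0 < window_thickness <= bulk_thickness")
  }
  if (spec$window_radius < spec$protein_radius) {
    stop("window_radius must be >= protein_radius")
  }
  if (spec$n_frames < 1L) stop("n_frames must be >= 1")
  if (spec$z_noise_sigma < 0 || spec$xy_jitter_sigma < 0) {
    stop("noise sigmas must be >= 0")
  }
  if (spec$ar1_phi < 0 || spec$ar1_phi >= 1) stop("ar1_phi must be in [0, 1)")
  if (is.null(names(spec$composition)) || any(spec$composition < 0)) {
    stop("composition must be a named vector of non-negative ratios")
  }
  class(spec) <- "bilayer_spec"
  spec
}

#' Local planted thickness of a bilayer spec
#'
#' Evaluates the radial thinning-funnel profile `T(rho)` of a
#' [bilayer_spec()] at radial distance(s) `rho` from the protein axis.
#'
#' @param spec A `bilayer_spec`.
#' @param rho Radial distance(s) from the box-center axis, angstrom.
#' @return Planted local thickness, angstrom.
#' @export
bilayer_thickness_at <- function(spec, rho) {
  d <- pmax(0, rho - spec$protein_radius)
  spec$window_thickness + (spec$bulk_thickness - spec$window_thickness) *
    (1 - exp(-d^2 / (2 * spec$decay_width^2)))
}

#' Largest-remainder apportionment of composition ratios
#'
#' @param n Total count to apportion.
#' @param ratios Named non-negative ratios.
#' @return Named integer vector summing to `n`.
#' @export
apportion_counts <- function(n, ratios) {
  stopifnot(n >= 0, all(ratios >= 0), sum(ratios) > 0)
  quota <- n * ratios / sum(ratios)
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- quota - counts
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  stats::setNames(as.integer(counts), names(ratios))
}

# evaluate code under a temporary RNG seed, restoring global RNG state after
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic bilayer ensemble with planted ground truth
#'
#' Places one PO4 bead per lipid on a jittered square lattice per leaflet at
#' `z = +/- T(rho)/2` plus Gaussian noise (see [bilayer_spec()] for the
#' funnel `T(rho)`), an optional protein cylinder of backbone beads on the
#' box-center axis, optional deep mid-plane phosphates inside the window
#' region, and an optional water phase outside the membrane slab.
#' Coordinates are centered: the membrane mid-plane is `z = 0` and the box
#' spans `[-edge/2, edge/2]` in x and y. Fully reproducible from `spec$seed`.
#'
#' @param spec A [bilayer_spec()].
#' @return A list with elements `ensemble` (an [md_ensemble()]) and `truth`
#'   (a `synthetic_truth` carrying the spec plus realized per-species counts).
#' @export
generate_bilayer <- function(spec) {
  stopifnot(inherits(spec, "bilayer_spec"))
  with_local_seed(spec$seed, {
    s <- sqrt(spec$area_per_lipid)
    nx <- floor(spec$box_edge / s)
    if (nx < 1) stop("box too small for one lipid at this area per lipid")
    centers <- (seq_len(nx) - 0.5) * s - spec$box_edge / 2
    sites <- as.matrix(expand.grid(x = centers, y = centers))
    rho_site <- sqrt(rowSums(sites^2))
    eligible <- which(rho_site >= spec$protein_radius)
    n <- spec$n_lipids_per_leaflet
    if (length(eligible) < n) {
      stop("lattice cannot host ", n, " lipids per leaflet at ",
           spec$area_per_lipid, " A^2 within a ", spec$box_edge,
           " A box (", length(eligible), " eligible sites)")
    }

    species_counts <- apportion_counts(n, spec$composition)
    leaflet_sites <- list()
    leaflet_species <- list()
    for (leaflet in 1:2) {
      pick <- sample(eligible, n)
      leaflet_sites[[leaflet]] <- sites[pick, , drop = FALSE]
      leaflet_species[[leaflet]] <- sample(rep(names(species_counts),
                                               species_counts))
    }

    # fixed identity of deep-dwelling window phosphates (upper leaflet list,
    # then lower), only when a protein is present
    deep <- list(integer(0), integer(0))
    if (spec$protein_radius > 0 && spec$deep_phosphate_fraction > 0) {
      for (leaflet in 1:2) {
        rho_l <- sqrt(rowSums(leaflet_sites[[leaflet]]^2))
        in_window <- which(rho_l <= spec$window_radius)
        n_deep <- round(spec$deep_phosphate_fraction * length(in_window))
        if (n_deep > 0) {
          deep[[leaflet]] <- sort(sample(in_window, n_deep))
        }
      }
    }

    n_prot <- if (spec$protein_radius > 0) spec$n_protein_beads else 0L
    prot_xyz <- NULL
    if (n_prot > 0) {
      k <- seq_len(n_prot)
      theta <- k * 2.399963  # golden angle, radians
      zf <- if (n_prot == 1L) 0 else (k - 1) / (n_prot - 1) * 2 - 1
      prot_xyz <- cbind(spec$protein_radius * cos(theta),
                        spec$protein_radius * sin(theta),
                        zf * spec$protein_half_height)
    }

    n_water <- 0L
    if (spec$water_slab) {
      slab_margin <- 5
      z_lo <- spec$bulk_thickness / 2 + slab_margin
      vol <- spec$box_edge^2 * max(0, spec$box_z / 2 - z_lo) * 2
      n_water <- as.integer(round(spec$water_density * vol))
    }

    topo <- build_bilayer_topology(leaflet_species, n_prot, n_water)
    nb <- nrow(topo)
    coords <- array(0, dim = c(spec$n_frames, nb, 3))
    z_prev <- list(NULL, NULL)

    for (f in seq_len(spec$n_frames)) {
      xyz <- matrix(0, nb, 3)
      at <- 1L
      for (leaflet in 1:2) {
        sgn <- if (leaflet == 1) 1 else -1
        base <- leaflet_sites[[leaflet]]
        jitter <- matrix(stats::rnorm(2 * n, 0, spec$xy_jitter_sigma), n, 2)
        xy <- base + jitter
        rho <- sqrt(rowSums(xy^2))
        innov <- stats::rnorm(n, 0, spec$z_noise_sigma)
        if (spec$ar1_phi > 0 && !is.null(z_prev[[leaflet]])) {
          noise <- spec$ar1_phi * z_prev[[leaflet]] +
            sqrt(1 - spec$ar1_phi^2) * innov
        } else {
          noise <- innov
        }
        z_prev[[leaflet]] <- noise
        z <- sgn * bilayer_thickness_at(spec, rho) / 2 + noise
        d <- deep[[leaflet]]
        if (length(d) > 0) z[d] <- stats::rnorm(length(d), 0, max(spec$z_noise_sigma, 1))
        xyz[at:(at + n - 1L), ] <- cbind(xy, z)
        at <- at + n
      }
      if (n_prot > 0) {
        xyz[at:(at + n_prot - 1L), ] <- prot_xyz
        at <- at + n_prot
      }
      if (n_water > 0) {
        z_lo <- spec$bulk_thickness / 2 + 5
        half <- n_water %/% 2L
        n_up <- half + n_water %% 2L
        wz <- c(stats::runif(n_up, z_lo, spec$box_z / 2),
                stats::runif(half, -spec$box_z / 2, -z_lo))
        wx <- stats::runif(n_water, -spec$box_edge / 2, spec$box_edge / 2)
        wy <- stats::runif(n_water, -spec$box_edge / 2, spec$box_edge / 2)
        xyz[at:(at + n_water - 1L), ] <- cbind(wx, wy, wz)
      }
      coords[f, , ] <- xyz
    }

    ensemble <- md_ensemble(topo, coords,
                            box = c(spec$box_edge, spec$box_edge, spec$box_z),
                            time = as.numeric(seq_len(spec$n_frames) - 1L),
                            source_format = "synthetic")
    truth <- structure(
      c(unclass(spec)[setdiff(names(spec), "composition")],
        list(composition = spec$composition,
             species_counts_per_leaflet = species_counts,
             n_deep_phosphates = lengths(deep),
             n_water_beads = n_water)),
      class = "synthetic_truth")
    list(ensemble = ensemble, truth = truth)
  })
}

build_bilayer_topology <- function(leaflet_species, n_prot, n_water) {
  species <- c(leaflet_species[[1]], leaflet_species[[2]])
  n2 <- length(species)
  topo <- tibble::tibble(
    index = seq_len(n2) - 1L,
    name = "PO4", resname = species, resid = seq_len(n2), chain = "M"
  )
  next_resid <- n2
  next_index <- n2
  if (n_prot > 0) {
    topo <- dplyr::bind_rows(topo, tibble::tibble(
      index = next_index + seq_len(n_prot) - 1L,
      name = "BB", resname = "ALA",
      resid = next_resid + seq_len(n_prot), chain = "P"))
    next_index <- next_index + n_prot
    next_resid <- next_resid + n_prot
  }
  if (n_water > 0) {
    topo <- dplyr::bind_rows(topo, tibble::tibble(
      index = next_index + seq_len(n_water) - 1L,
      name = "W", resname = "W",
      resid = next_resid + seq_len(n_water), chain = "W"))
  }
  topo
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> planted bulk ", x$bulk_thickness, " A, window ",
      x$window_thickness, " A, sigma_z ", x$z_noise_sigma, " A, ",
      x$n_frames, " frame(s), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write / read a planted-truth sidecar file
#'
#' Serializes a `synthetic_truth` as plain `key: value` text next to a
#' generated ensemble so analyses can be checked against the planted
#' parameters later.
#'
#' @param truth A `synthetic_truth` from [generate_bilayer()].
#' @param path Output path (conventionally `<ensemble>.truth.txt`).
#' @return `path` invisibly; for the reader, a named list.
#' @export
write_synthetic_truth <- function(truth, path) {
  flat <- unlist(unclass(truth))
  writeLines(paste0(names(flat), ": ",
                    vapply(flat, format, character(1), digits = 17)), path)
  invisible(path)
}

#' @rdname write_synthetic_truth
#' @export
read_synthetic_truth <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- regmatches(lines, regexec("^([^:]+): (.*)$", lines))
  out <- lapply(kv, function(g) {
    v <- suppressWarnings(as.numeric(g[3]))
    if (is.na(v) && !identical(g[3], "NA")) g[3] else v
  })
  stats::setNames(out, vapply(kv, `[`, character(1), 2))
}

#' Generate an ideal helix ensemble
#'
#' One backbone bead per residue on an ideal alpha-helix (radius 2.3 A,
#' 100 degrees of twist per residue) whose axis points along `direction`.
#' The axial extent between beads `i` and `j` is exactly `(j - i) * rise`.
#'
#' @param n_residues Number of residues (>= 4, so axis endpoints have three
#'   residues each).
#' @param direction Axis direction (any nonzero 3-vector; normalized).
#' @param rise_per_residue Axial rise per residue, angstrom.
#' @param origin Position of the first residue's axial point.
#' @param radius Helix radius, angstrom.
#' @return An [md_ensemble()] with one frame.
#' @export
generate_helix <- function(n_residues, direction = c(0, 0, 1),
                           rise_per_residue = 1.5, origin = c(0, 0, 0),
                           radius = 2.3) {
  if (n_residues < 4) stop("n_residues must be >= 4")
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("direction must be a nonzero vector")
  u <- direction / nrm
  i <- seq_len(n_residues)
  theta <- (i - 1) * 100 * pi / 180
  local <- cbind(radius * cos(theta), radius * sin(theta),
                 (i - 1) * rise_per_residue)
  R <- rotation_to(c(0, 0, 1), u)
  xyz <- local %*% t(R) + matrix(origin, n_residues, 3, byrow = TRUE)
  span <- max(abs(xyz)) + 3 * radius + 10
  topo <- tibble::tibble(index = i - 1L, name = "BB", resname = "ALA",
                         resid = i, chain = "A")
  md_ensemble(topo, xyz, box = rep(2 * span, 3), source_format = "synthetic")
}

# proper rotation taking unit vector a onto unit vector b (Rodrigues)
rotation_to <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (sum(v^2) < 1e-24) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a
    ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Generate a replicate band-intensity table with planted cleavage
#'
#' Emulates densitometry of cleaved and full-length bands: for each point the
#' noise-free intensities are `p` and `100 - p` (arbitrary units) and both are
#' multiplied by independent lognormal noise with unit mean and coefficient of
#' variation `cv`, so the expected recovered cleavage percentage equals the
#' planted value.
#'
#' @param true_cleavage Numeric vector of planted cleavage percentages in
#'   `[0, 100]`, one per point.
#' @param n_replicates Replicates per point.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param n_length Optional integer labels per point (defaults to
#'   `seq_along(true_cleavage)`).
#' @param strain Strain label for the table.
#' @param seed Integer seed.
#' @return A tibble with columns `construct`, `n_length`, `strain`,
#'   `replicate`, `cleaved`, `full`.
#' @export
generate_band_table <- function(true_cleavage, n_replicates = 3, cv = 0.1,
                                n_length = seq_along(true_cleavage),
                                strain = "synthetic", seed = 1L) {
  if (cv < 0) stop("cv must be >= 0")
  if (any(true_cleavage < 0 | true_cleavage > 100)) {
    stop("true_cleavage must be within [0, 100]")
  }
  if (length(n_length) != length(true_cleavage)) {
    stop("n_length must match true_cleavage in length")
  }
  with_local_seed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- -sdlog^2 / 2
    rows <- purrr::map2_dfr(true_cleavage, n_length, function(p, nl) {
      noise_c <- if (cv > 0) stats::rlnorm(n_replicates, meanlog, sdlog) else rep(1, n_replicates)
      noise_f <- if (cv > 0) stats::rlnorm(n_replicates, meanlog, sdlog) else rep(1, n_replicates)
      tibble::tibble(
        construct = paste0("N", nl),
        n_length = as.integer(nl),
        strain = strain,
        replicate = seq_len(n_replicates),
        cleaved = p * noise_c,
        full = (100 - p) * noise_f
      )
    })
    rows
  })
}
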