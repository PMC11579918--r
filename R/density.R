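#' Number-density profile along the membrane normal
#'
#' Histograms the z-coordinates of the selected beads per frame, divides by
#' the bin volume (`box_x * box_y * bin_width`, per frame), and averages over
#' frames. The membrane normal is the z-axis by convention. For dynamic
#' selections (e.g. a per-frame TM-window selection) pass a `frame_selection`
#' from [tm_window_selection()].
#'
#' @param system An [md_ensemble()].
#' @param selection A `bead_selection`, integer vector of 0-based indices, or
#'   a `frame_selection` (list of per-frame index vectors).
#' @param bin_width Bin width in angstrom (> 0); default 1.
#' @param z_range Optional `c(lo, hi)` range in angstrom; beads outside are
#'   ignored. Defaults to the symmetric range covering the selection over all
#'   frames, expanded to a whole number of bins.
#' @param stride Analyze every `stride`-th frame (default 1 = all frames).
#' @return A `density_profile`: a tibble with columns `z` (bin midpoint, A)
#'   and `density` (beads per cubic angstrom), with attributes `bin_edges`,
#'   `n_frames` and `selection_descriptor`.
#' @examples
#' sys <- generate_bilayer(bilayer_spec(n_frames = 2, n_lipids_per_leaflet = 50,
#'                                      box_edge = 80))$ensemble
#' po4 <- select_beads(sys, role = "lipid_phosphate")
#' prof <- density_profile(sys, po4)
#' @export
density_profile <- function(system, selection, bin_width = 1,
                            z_range = NULL, stride = 1L) {
  stopifnot(inherits(system, "md_ensemble"))
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (bin_width >= min(system$box[, 3])) {
    stop("bin_width must be smaller than the box height")
  }
  frames_used <- seq(1L, n_frames(system), by = stride)
  per_frame <- selection_per_frame(selection, n_frames(system))
  if (all(lengths(per_frame[frames_used]) == 0L)) stop("empty selection")

  z_all <- unlist(lapply(frames_used, function(f) {
    idx <- per_frame[[f]]
    if (length(idx) == 0L) numeric(0) else system$coords[f, idx + 1L, 3]
  }))
  if (is.null(z_range)) {
    z_range <- range(z_all)
    pad <- bin_width / 2
    z_range <- c(z_range[1] - pad, z_range[2] + pad)
  }
  nbins <- max(1L, ceiling((z_range[2] - z_range[1]) / bin_width - 1e-9))
  edges <- z_range[1] + bin_width * (0:nbins)

  dens <- numeric(nbins)
  for (f in frames_used) {
    idx <- per_frame[[f]]
    if (length(idx) == 0L) next
    z <- system$coords[f, idx + 1L, 3]
    z <- z[z >= edges[1] & z <= edges[nbins + 1]]
    h <- counts_in_bins(z, edges)
    vol <- system$box[f, 1] * system$box[f, 2] * bin_width
    dens <- dens + h / vol
  }
  dens <- dens / length(frames_used)

  desc <- if (!is.null(attr(selection, "descriptor"))) {
    attr(selection, "descriptor")
  } else "indices"
  out <- tibble::tibble(z = (edges[-1] + edges[-(nbins + 1)]) / 2,
                        density = dens)
  structure(out, bin_edges = edges, n_frames = length(frames_used),
            selection_descriptor = desc,
            class = c("density_profile", class(out)))
}

# left-closed bins, with the final right edge closed so nothing on the
# boundary is dropped
counts_in_bins <- function(z, edges) {
  n <- length(edges) - 1L
  bin <- findInterval(z, edges, rightmost.closed = TRUE, left.open = FALSE)
  bin <- bin[bin >= 1L & bin <= n]
  tabulate(bin, nbins = n)
}

selection_per_frame <- function(selection, nf) {
  if (inherits(selection, "frame_selection")) {
    if (length(selection$frames) != nf) {
      stop("frame_selection covers ", length(selection$frames),
           " frames, system has ", nf)
    }
    selection$frames
  } else {
    rep(list(as.integer(selection)), nf)
  }
}

#' Export a density profile as TSV or xmgrace .xvg
#'
#' @param profile A `density_profile`.
#' @param path Output path.
#' @param format `"tsv"` (two columns with header) or `"xvg"`.
#' @return `path`, invisibly.
#' @export
write_density_profile <- function(profile, path, format = c("tsv", "xvg")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(data.frame(z = profile$z, density = profile$density),
                       path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    hdr <- c("@    title \"Number density profile\"",
             "@    xaxis  label \"z (\\cE\\C)\"",
             "@    yaxis  label \"density (beads/\\cE\\C\\S3\\N)\"",
             "@TYPE xy")
    body <- sprintf("%12.5f %14.8e", profile$z, profile$density)
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Frame-averaged volumetric number-density map
#'
#' Bins selected beads on a regular 3-D grid covering the box, averages the
#' per-frame counts, and converts to number density (beads per cubic
#' angstrom). Optional Gaussian smoothing is applied as a separable periodic
#' convolution with a sum-normalized kernel, so the total integral is
#' preserved exactly up to floating-point error.
#'
#' @param system An [md_ensemble()].
#' @param selection A `bead_selection` or integer indices (0-based).
#' @param spacing Grid spacing in angstrom (> 0, at most half the box).
#' @param smoothing_sigma Gaussian smoothing width in angstrom (0 = none).
#' @return A `density_map`: list with `origin` (grid corner, A), `spacing`,
#'   `density` (3-D array, beads/A^3), `n_frames`.
#' @export
volumetric_map <- function(system, selection, spacing = 2,
                           smoothing_sigma = 0) {
  stopifnot(inherits(system, "md_ensemble"))
  if (spacing <= 0) stop("spacing must be > 0")
  box <- system$box[1, ]
  if (spacing > min(box) / 2) stop("spacing larger than half the box")
  idx <- as.integer(selection) + 1L
  if (length(idx) == 0L) stop("empty selection")

  dims <- pmax(1L, as.integer(ceiling(box / spacing)))
  # grid anchored at the minimal coordinate corner so it always covers the box
  lo <- apply(system$coords[, idx, , drop = FALSE], 3, min)
  origin <- pmin(lo, -box / 2)
  counts <- array(0, dim = dims)
  nf <- n_frames(system)
  for (f in seq_len(nf)) {
    xyz <- matrix(system$coords[f, idx, ], ncol = 3)
    cell <- sweep(xyz, 2, origin)
    ijk <- pmin(floor(sweep(cell, 2, rep(spacing, 3), `/`)),
                matrix(dims - 1L, nrow(cell), 3, byrow = TRUE))
    ijk[ijk < 0] <- 0L
    lin <- ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3]) + 1L
    tab <- tabulate(lin, nbins = prod(dims))
    counts <- counts + array(tab, dim = dims)
  }
  density <- counts / nf / spacing^3
  if (smoothing_sigma > 0) {
    density <- gaussian_smooth_periodic(density, smoothing_sigma / spacing)
  }
  structure(list(origin = origin, spacing = spacing, density = density,
                 n_frames = nf),
            class = "density_map")
}

# separable periodic Gaussian convolution; kernel normalized to sum 1
gaussian_smooth_periodic <- function(arr, sigma_cells) {
  half <- max(1L, ceiling(3 * sigma_cells))
  k <- stats::dnorm(seq(-half, half), sd = sigma_cells)
  k <- k / sum(k)
  d <- dim(arr)
  conv1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (j in seq_along(k)) {
      shift <- j - half - 1L
      out <- out + k[j] * v[((seq_len(n) - 1L + shift) %% n) + 1L]
    }
    out
  }
  for (axis in 1:3) {
    arr <- apply(arr, setdiff(1:3, axis), conv1)
    # apply() puts the processed axis first; restore order
    arr <- aperm(arr, order(c(axis, setdiff(1:3, axis))))
  }
  array(arr, dim = d)
}

#' @export
print.density_map <- function(x, ...) {
  cat("<density_map> ", paste(dim(x$density), collapse = " x "),
      " voxels, spacing ", x$spacing, " A, ", x$n_frames, " frame(s)\n",
      sep = "")
  invisible(x)
}

#' Write a density map in OpenDX grid format
#'
#' @param map A `density_map` from [volumetric_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_map_dx <- function(map, path) {
  d <- dim(map$density)
  n <- prod(d)
  hdr <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", map$origin[1], map$origin[2], map$origin[3]),
    sprintf("delta %g 0 0", map$spacing),
    sprintf("delta 0 %g 0", map$spacing),
    sprintf("delta 0 0 %g", map$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n)
  )
  # dx order: z fastest
  vals <- map$density[cbind(rep(1:d[1], each = d[2] * d[3]),
                            rep(rep(1:d[2], each = d[3]), d[1]),
                            rep(1:d[3], d[1] * d[2]))]
  rows <- split(vals, ceiling(seq_along(vals) / 3))
  body <- vapply(rows, function(r) paste(sprintf("%.8e", r), collapse = " "),
                 character(1))
  writeLines(c(hdr, body,
               'attribute "dep" string "positions"',
               'object "density" class field'), path)
  invisible(path)
}

#' Total integral of a density map
#'
#' `sum(density) * spacing^3`; equals the mean selected-bead count per frame
#' before smoothing, and is preserved by smoothing.
#'
#' @param map A `density_map`.
#' @return Numeric scalar (beads).
#' @export
map_integral <- function(map) sum(map$density) * map$spacing^3
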