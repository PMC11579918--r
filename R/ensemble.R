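#' Construct a labeled coordinate ensemble
#'
#' An `md_ensemble` bundles a topology (one row per bead, with a functional
#' `role` assigned from bead and residue names) and a stack of coordinate
#' frames. All coordinates, box vectors and derived quantities are in
#' angstrom; times are in picoseconds. Only orthorhombic boxes are supported.
#'
#' @param topology A data frame with columns `index` (0-based, unique),
#'   `name`, `resname`, `resid`, `chain` and optionally `role`. If `role` is
#'   absent it is assigned with [assign_roles()].
#' @param coords A numeric array of dimension `frames x beads x 3` (angstrom),
#'   or a single `beads x 3` matrix for a one-frame ensemble.
#' @param box A numeric matrix `frames x 3` of orthorhombic box edges
#'   (angstrom), or a length-3 vector recycled across frames.
#' @param time Numeric vector of frame times in ps (default `0, 1, 2, ...`).
#' @param source_format One of `"gro"`, `"pdb"`, `"synthetic"`.
#' @param convention Naming convention table passed to [assign_roles()].
#'
#' @return An object of class `md_ensemble` with elements `topology`
#'   (a tibble), `coords`, `box`, `time` and `source_format`.
#' @seealso [read_coordinates()], [as_tibble.md_ensemble()]
#' @export
md_ensemble <- function(topology, coords, box, time = NULL,
                        source_format = c("synthetic", "gro", "pdb"),
                        convention = default_naming_convention()) {
  source_format <- match.arg(source_format)
  topology <- tibble::as_tibble(topology)
  required <- c("name", "resname", "resid", "chain")
  missing_cols <- setdiff(required, names(topology))
  if (length(missing_cols) > 0) {
    stop("topology is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"index" %in% names(topology)) {
    topology$index <- seq_len(nrow(topology)) - 1L
  }
  if (anyDuplicated(topology$index)) {
    stop("topology bead indices must be unique")
  }
  if (!"role" %in% names(topology)) {
    topology$role <- assign_roles(topology, convention = convention)
  }
  topology$role <- check_roles(topology$role)

  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("coords must be a frames x beads x 3 array")
  }
  n_frames <- dim(coords)[1]
  if (n_frames < 1L) stop("an ensemble needs at least one frame")
  if (dim(coords)[2] != nrow(topology)) {
    stop("coordinate bead count (", dim(coords)[2],
         ") does not match topology (", nrow(topology), " beads)")
  }
  if (is.null(dim(box))) box <- matrix(box, nrow = n_frames, ncol = 3, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) == 1L && n_frames > 1L) {
    box <- box[rep(1L, n_frames), , drop = FALSE]
  }
  if (nrow(box) != n_frames || ncol(box) != 3L) {
    stop("box must be a frames x 3 matrix of orthorhombic edges")
  }
  if (any(!is.finite(box)) || any(box <= 0)) {
    stop("box components must be finite and > 0 (orthorhombic boxes only)")
  }
  if (is.null(time)) time <- as.numeric(seq_len(n_frames) - 1L)
  if (length(time) != n_frames) stop("time must have one entry per frame")

  structure(
    list(topology = topology, coords = coords, box = box,
         time = as.numeric(time), source_format = source_format),
    class = "md_ensemble"
  )
}

bead_roles <- c("protein_backbone", "protein_other", "lipid_phosphate",
                "water", "other")

check_roles <- function(role) {
  role <- as.character(role)
  bad <- setdiff(unique(role), bead_roles)
  if (length(bad) > 0) {
    stop("unknown bead role(s): ", paste(bad, collapse = ", "))
  }
  if (anyNA(role)) stop("every bead must have a role")
  role
}

#' Default bead/atom naming convention
#'
#' Maps bead or atom names (plus residue names) to functional roles. The
#' defaults cover Martini coarse-grained beads (`BB` backbone, `PO4`
#' phosphate, `W` water) and all-atom PDB names (`CA` backbone, `P` phosphate
#' on a lipid residue, `SOL`/`HOH`/`TIP3` water). Rules are applied top to
#' bottom; the first match wins and unmatched beads in amino-acid residues
#' become `protein_other`, anything else `other`.
#'
#' @return A tibble with columns `field` (`"name"` or `"resname"`), `pattern`
#'   (exact, case-sensitive match) and `role`.
#' @export
default_naming_convention <- function() {
  tibble::tribble(
    ~field,     ~pattern, ~role,
    "name",     "PO4",    "lipid_phosphate",
    "name",     "BB",     "protein_backbone",
    "name",     "CA",     "protein_backbone",
    "name",     "W",      "water",
    "name",     "WN",     "water",
    "resname",  "W",      "water",
    "resname",  "SOL",    "water",
    "resname",  "HOH",    "water",
    "resname",  "TIP3",   "water",
    "resname",  "ION",    "other"
  )
}

amino_acid_resnames <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP"
)

lipid_resnames <- c(
  "POPC", "POPE", "POPS", "POPI", "POPA", "DOPC", "DPPC", "DYPC", "YOPC",
  "PYPI", "DYPE", "YOPE", "ERGO", "YOPA", "YOPS", "CHOL"
)

#' Assign a functional role to every bead
#'
#' Role assignment is total and a pure function of `(name, resname)` under the
#' active convention: every bead receives exactly one of `protein_backbone`,
#' `protein_other`, `lipid_phosphate`, `water`, `other`.
#'
#' @param topology Data frame with `name` and `resname` columns.
#' @param convention Convention table as from [default_naming_convention()].
#' @return Character vector of roles, one per bead.
#' @export
assign_roles <- function(topology, convention = default_naming_convention()) {
  name <- as.character(topology$name)
  resname <- as.character(topology$resname)
  role <- rep(NA_character_, length(name))

  for (i in seq_len(nrow(convention))) {
    rule <- convention[i, ]
    hit <- if (rule$field == "name") name == rule$pattern else resname == rule$pattern
    # "P" atom names only mean phosphate on a lipid residue
    if (rule$field == "name" && rule$pattern == "CA") {
      hit <- hit & resname %in% amino_acid_resnames
    }
    role[is.na(role) & hit] <- rule$role
  }
  # all-atom lipid phosphorus
  role[is.na(role) & name == "P" & resname %in% lipid_resnames] <- "lipid_phosphate"
  role[is.na(role) & resname %in% amino_acid_resnames] <- "protein_other"
  role[is.na(role)] <- "other"
  role
}

#' @export
print.md_ensemble <- function(x, ...) {
  cat("<md_ensemble> ", n_frames(x), " frame(s), ", n_beads(x), " beads (",
      x$source_format, ")\n", sep = "")
  counts <- table(factor(x$topology$role, levels = bead_roles))
  cat("  roles:", paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  cat("  box (frame 1):", paste(sprintf("%.2f", x$box[1, ]), collapse = " x "),
      "Å\n")
  invisible(x)
}

#' Number of frames / beads in an ensemble
#' @param x An `md_ensemble`.
#' @return Integer scalar.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname n_frames
#' @export
n_beads <- function(x) dim(x$coords)[2]

#' Long tidy view of an ensemble
#'
#' Returns one row per bead per frame with topology columns, frame number
#' (1-based), time (ps) and `x`, `y`, `z` coordinates in angstrom.
#'
#' @param x An `md_ensemble`.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom tibble as_tibble
#' @export
as_tibble.md_ensemble <- function(x, ...) {
  nf <- n_frames(x)
  nb <- n_beads(x)
  top <- x$topology[rep(seq_len(nb), times = nf), ]
  top$frame <- rep(seq_len(nf), each = nb)
  top$time <- rep(x$time, each = nb)
  top$x <- as.vector(t(x$coords[, , 1]))
  top$y <- as.vector(t(x$coords[, , 2]))
  top$z <- as.vector(t(x$coords[, , 3]))
  tibble::as_tibble(top)
}

#' Extract one frame's coordinates
#' @param x An `md_ensemble`.
#' @param i Frame number (1-based).
#' @return A `beads x 3` numeric matrix (angstrom).
#' @export
frame_coords <- function(x, i = 1L) {
  stopifnot(i >= 1L, i <= n_frames(x))
  matrix(x$coords[i, , ], ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
}
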