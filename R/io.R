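#' Read a multi-frame coordinate file into an ensemble
#'
#' Reads GROMACS GRO files (fixed width, nm; concatenated blocks are treated
#' as frames) and PDB files (multi-`MODEL`; `CRYST1` provides the box). All
#' coordinates are converted to angstrom on input. Bead roles are assigned
#' from the naming convention; topology is taken from the first frame and all
#' later frames must have the same bead count.
#'
#' @param path Path to a `.gro` or `.pdb` file.
#' @param dialect `"gro"`, `"pdb"`, or `"auto"` (detect from extension, then
#'   content).
#' @param convention Naming convention table, see [default_naming_convention()].
#' @return An [md_ensemble()].
#' @export
read_coordinates <- function(path, dialect = c("auto", "gro", "pdb"),
                             convention = default_naming_convention()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("gro", "pdb")) {
      ext
    } else {
      first <- readLines(path, n = 20L, warn = FALSE)
      if (any(grepl("^(ATOM  |HETATM|MODEL |CRYST1)", first))) "pdb" else "gro"
    }
  }
  switch(dialect,
         gro = read_gro(path, convention),
         pdb = read_pdb(path, convention))
}

parse_fixed_num <- function(line, from, to, what, line_no) {
  s <- substr(line, from, to)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) {
    stop("malformed ", what, " field at line ", line_no, ": '", s, "'")
  }
  v
}

read_gro <- function(path, convention = default_naming_convention()) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  frames <- list()
  topo <- NULL
  frame_no <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame_no <- frame_no + 1L
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || natoms < 1L) {
      stop("malformed atom-count line at line ", i + 1L)
    }
    if (i + 1L + natoms + 1L > length(lines)) {
      stop("truncated GRO frame ", frame_no, " (expected ", natoms, " atoms)")
    }
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    line_nos <- (i + 2L):(i + 1L + natoms)
    xyz <- matrix(0, natoms, 3)
    for (k in seq_len(natoms)) {
      ln <- atom_lines[k]
      if (nchar(ln) < 44L) stop("malformed GRO atom line at line ", line_nos[k])
      xyz[k, 1] <- parse_fixed_num(ln, 21, 28, "x-coordinate", line_nos[k])
      xyz[k, 2] <- parse_fixed_num(ln, 29, 36, "y-coordinate", line_nos[k])
      xyz[k, 3] <- parse_fixed_num(ln, 37, 44, "z-coordinate", line_nos[k])
    }
    if (frame_no == 1L) {
      topo <- tibble::tibble(
        index = seq_len(natoms) - 1L,
        name = trimws(substr(atom_lines, 11, 15)),
        resname = trimws(substr(atom_lines, 6, 10)),
        resid = as.integer(trimws(substr(atom_lines, 1, 5))),
        chain = "A"
      )
    } else if (natoms != nrow(topo)) {
      stop("inconsistent bead count in frame ", frame_no, ": got ", natoms,
           ", expected ", nrow(topo))
    }
    box_fields <- scan(text = lines[i + 1L + natoms + 1L], quiet = TRUE)
    if (length(box_fields) < 3L) {
      stop("malformed box line at line ", i + 1L + natoms + 1L)
    }
    if (length(box_fields) > 3L && any(abs(box_fields[-(1:3)]) > 1e-9)) {
      stop("triclinic box in frame ", frame_no,
           "; only orthorhombic boxes are supported")
    }
    time <- NA_real_
    tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    if (length(tm) == 2L) time <- as.numeric(tm[2])
    frames[[frame_no]] <- list(xyz = xyz * 10, box = box_fields[1:3] * 10,
                               time = time)
    i <- i + 1L + natoms + 2L
  }
  if (frame_no == 0L) stop("no frames found in ", path)
  assemble_frames(topo, frames, "gro", convention)
}

assemble_frames <- function(topo, frames, source_format, convention) {
  nf <- length(frames)
  nb <- nrow(topo)
  coords <- array(0, dim = c(nf, nb, 3))
  box <- matrix(0, nf, 3)
  time <- vapply(frames, function(f) f$time, numeric(1))
  if (anyNA(time)) time <- as.numeric(seq_len(nf) - 1L)
  for (f in seq_len(nf)) {
    coords[f, , ] <- frames[[f]]$xyz
    box[f, ] <- frames[[f]]$box
  }
  md_ensemble(topo, coords, box, time = time, source_format = source_format,
              convention = convention)
}

read_pdb <- function(path, convention = default_naming_convention()) {
  lines <- readLines(path, warn = FALSE)
  box <- NULL
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (length(cryst) > 0) {
    f <- cryst[1]
    abc <- c(parse_fixed_num(f, 7, 15, "box a", 0),
             parse_fixed_num(f, 16, 24, "box b", 0),
             parse_fixed_num(f, 25, 33, "box c", 0))
    angles <- c(parse_fixed_num(f, 34, 40, "alpha", 0),
                parse_fixed_num(f, 41, 47, "beta", 0),
                parse_fixed_num(f, 48, 54, "gamma", 0))
    if (any(abs(angles - 90) > 1e-3)) {
      stop("triclinic CRYST1 record; only orthorhombic boxes are supported")
    }
    box <- abc
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  is_model <- grepl("^MODEL", lines)
  is_end <- grepl("^ENDMDL", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # frame id per atom line: cumulative MODEL count (0 -> single implicit frame)
  model_id <- cumsum(is_model)
  frame_of_atom <- model_id[is_atom]
  if (max(frame_of_atom) == 0L) frame_of_atom <- frame_of_atom + 1L
  atom_lines <- lines[is_atom]
  atom_line_nos <- which(is_atom)

  split_idx <- split(seq_along(atom_lines), frame_of_atom)
  frames <- vector("list", length(split_idx))
  topo <- NULL
  for (f in seq_along(split_idx)) {
    idx <- split_idx[[f]]
    ln <- atom_lines[idx]
    nos <- atom_line_nos[idx]
    natoms <- length(ln)
    xyz <- matrix(0, natoms, 3)
    for (k in seq_len(natoms)) {
      if (nchar(ln[k]) < 54L) stop("malformed PDB atom line at line ", nos[k])
      xyz[k, 1] <- parse_fixed_num(ln[k], 31, 38, "x-coordinate", nos[k])
      xyz[k, 2] <- parse_fixed_num(ln[k], 39, 46, "y-coordinate", nos[k])
      xyz[k, 3] <- parse_fixed_num(ln[k], 47, 54, "z-coordinate", nos[k])
    }
    if (f == 1L) {
      chain <- trimws(substr(ln, 22, 22))
      chain[!nzchar(chain)] <- "A"
      topo <- tibble::tibble(
        index = seq_len(natoms) - 1L,
        name = trimws(substr(ln, 13, 16)),
        resname = trimws(substr(ln, 18, 21)),
        resid = as.integer(trimws(substr(ln, 23, 26))),
        chain = chain
      )
    } else if (natoms != nrow(topo)) {
      stop("inconsistent bead count in frame ", f, ": got ", natoms,
           ", expected ", nrow(topo))
    }
    fbox <- box
    if (is.null(fbox)) {
      fbox <- pmax(apply(xyz, 2, max) - apply(xyz, 2, min), 1)
    }
    frames[[f]] <- list(xyz = xyz, box = fbox, time = NA_real_)
  }
  if (is.null(box)) {
    warning("no CRYST1 record; using the coordinate bounding box as box")
  }
  assemble_frames(topo, frames, "pdb", convention)
}

#' Write an ensemble to GRO or PDB
#'
#' GRO is written fixed-width in nm (0.001 nm precision); PDB in angstrom
#' (0.001 A precision) with one `MODEL` block per frame and a `CRYST1` box
#' record. PDB serials above 99999 and residue ids above 9999 wrap around,
#' so bead counts survive a round trip regardless of system size.
#'
#' @param system An [md_ensemble()].
#' @param path Output file path.
#' @param dialect `"gro"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(system, path, dialect = c("gro", "pdb")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(system, "md_ensemble"))
  if (dialect == "gro" && (is.null(system$box) || any(!is.finite(system$box)))) {
    stop("GRO output requires a box")
  }
  lines <- if (dialect == "gro") format_gro(system) else format_pdb(system)
  writeLines(lines, path)
  invisible(path)
}

format_gro <- function(system) {
  nf <- n_frames(system)
  topo <- system$topology
  out <- character(0)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(system, f) / 10  # Å -> nm
    atoms <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     topo$resid %% 100000L, substr(topo$resname, 1, 5),
                     substr(topo$name, 1, 5), (seq_len(nrow(topo))) %% 100000L,
                     xyz[, 1], xyz[, 2], xyz[, 3])
    out <- c(out,
             sprintf("memthin ensemble, t= %.3f", system$time[f]),
             sprintf("%5d", nrow(topo)),
             atoms,
             sprintf("%10.5f%10.5f%10.5f", system$box[f, 1] / 10,
                     system$box[f, 2] / 10, system$box[f, 3] / 10))
  }
  out
}

format_pdb <- function(system) {
  nf <- n_frames(system)
  topo <- system$topology
  serial <- ((seq_len(nrow(topo)) - 1L) %% 99999L) + 1L
  resid <- ((topo$resid - 1L) %% 9999L) + 1L
  chain <- substr(ifelse(nzchar(topo$chain), topo$chain, "A"), 1, 1)
  name4 <- ifelse(nchar(topo$name) <= 3L,
                  sprintf(" %-3s", topo$name), substr(topo$name, 1, 4))
  out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                 system$box[1, 1], system$box[1, 2], system$box[1, 3],
                 90, 90, 90)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(system, f)
    atoms <- sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                     serial, name4, substr(topo$resname, 1, 4), chain, resid,
                     xyz[, 1], xyz[, 2], xyz[, 3], 1, 0)
    out <- c(out, sprintf("MODEL     %4d", f), atoms, "ENDMDL")
  }
  c(out, "END")
}
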