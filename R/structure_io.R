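#' Molecular frame objects
#'
#' A `mem_frame` holds one snapshot of a molecular system: an atom table and
#' the periodic box.  All coordinates are in nanometres; PDB input (in
#' Angstroms) is converted at the boundary.  Boxes are orthorhombic only.
#'
#' @param atoms data.frame with columns `serial`, `atom_name`, `res_name`,
#'   `res_id`, `x`, `y`, `z` and optionally `element` (inferred from
#'   `atom_name` when absent).
#' @param box numeric length-3, box edge lengths (Lx, Ly, Lz) in nm.
#' @param label optional frame label (e.g. a time stamp).
#' @return An object of class `mem_frame`.
#' @export
mem_frame <- function(atoms, box, label = "") {
  required <- c("serial", "atom_name", "res_name", "res_id", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop_mem("atom table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (!is.numeric(box) || length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop_mem("box must be three positive finite edge lengths (nm)")
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(pos)))
    stop_mem("non-finite atom position(s)")
  if (anyDuplicated(atoms$serial))
    stop_mem("duplicate atom serial(s) within frame")
  if (is.null(atoms$element))
    atoms$element <- infer_element(atoms$atom_name)
  structure(list(atoms = atoms, box = as.numeric(box), label = label),
            class = "mem_frame")
}

#' @export
print.mem_frame <- function(x, ...) {
  cat(sprintf("<mem_frame> %d atoms, %d residues, box %.3f x %.3f x %.3f nm\n",
              nrow(x$atoms), length(unique(residue_key(x$atoms))),
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Trajectory container
#'
#' An ordered list of frames sharing atom count and identity (names and
#' residue numbering); the box may vary per frame.
#'
#' @param frames list of `mem_frame` objects.
#' @return An object of class `mem_trajectory`.
#' @export
mem_trajectory <- function(frames) {
  if (!length(frames)) stop_mem("a trajectory needs at least one frame")
  ref <- frames[[1]]$atoms
  for (i in seq_along(frames)[-1]) {
    a <- frames[[i]]$atoms
    if (nrow(a) != nrow(ref))
      stop_mem("atom count mismatch at frame %d (0-based): %d vs %d",
               i - 1L, nrow(a), nrow(ref))
    if (!identical(a$atom_name, ref$atom_name) ||
        !identical(a$res_id, ref$res_id))
      stop_mem("atom identity mismatch at frame %d (0-based)", i - 1L)
  }
  structure(list(frames = frames), class = "mem_trajectory")
}

#' @export
print.mem_trajectory <- function(x, ...) {
  cat(sprintf("<mem_trajectory> %d frames, %d atoms each\n",
              length(x$frames), nrow(x$frames[[1]]$atoms)))
  invisible(x)
}

#' @export
length.mem_trajectory <- function(x) length(x$frames)

#' Infer chemical elements from atom names
#'
#' GRO files carry no element field.  The element is taken as the first
#' alphabetic character of the atom name after stripping any leading digits
#' (PDB-style names such as "1H5'" resolve to H; lipid names such as "C1A"
#' to C, "P" to P).  Single-letter pseudo-elements used by the synthetic
#' bead lipids (Q, G, R, E, D) resolve to themselves.
#'
#' @param atom_name character vector of atom names.
#' @return Character vector of element symbols.
#' @export
infer_element <- function(atom_name) {
  nm <- sub("^[0-9]+", "", trimws(atom_name))
  el <- toupper(substr(nm, 1, 1))
  if (any(el == ""))
    stop_mem("cannot infer element from atom name '%s'",
             atom_name[which(el == "")[1]])
  el
}

#' Read a coordinate file
#'
#' Parses a single-frame GRO or PDB file into a [mem_frame].  PDB
#' coordinates (Angstrom) are converted to nm.  The box is read from the
#' GRO box line or the PDB CRYST1 record; a missing box is an error, and
#' triclinic boxes are rejected.
#'
#' @param path file path.
#' @param format `"gro"` or `"pdb"`; default guessed from the extension.
#' @return A [mem_frame].
#' @export
read_structure <- function(path, format = guess_format(path)) {
  traj <- read_trajectory(path, format)
  traj$frames[[1]]
}

#' Read a multi-frame coordinate file
#'
#' Concatenated GRO frames or a multi-MODEL PDB become a [mem_trajectory].
#' Frames must share atom count and ordering; a mismatch is an error naming
#' the (0-based) frame index.
#'
#' @inheritParams read_structure
#' @return A [mem_trajectory].
#' @export
read_trajectory <- function(path, format = guess_format(path)) {
  if (!file.exists(path)) stop_mem("file not found: %s", path)
  format <- match.arg(format, c("gro", "pdb"))
  lines <- readLines(path, warn = FALSE)
  frames <- switch(format,
                   gro = parse_gro_frames(lines, path),
                   pdb = parse_pdb_frames(lines, path))
  mem_trajectory(frames)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gro", "pdb")) ext
  else stop_mem("cannot guess format from extension '%s'; pass format=", ext)
}

parse_gro_frames <- function(lines, path) {
  frames <- list()
  pos <- 1L
  n_total <- length(lines)
  while (pos <= n_total && any(nzchar(trimws(lines[pos:n_total])))) {
    title <- lines[pos]
    natoms <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(natoms))
      stop_mem("%s line %d: expected atom count, got '%s'",
               path, pos + 1L, lines[pos + 1L])
    atom_lines <- lines[(pos + 2L):(pos + 1L + natoms)]
    if (length(atom_lines) < natoms || any(is.na(atom_lines)))
      stop_mem("%s: truncated frame starting line %d", path, pos)
    box_line <- lines[pos + 2L + natoms]
    if (is.na(box_line) || !nzchar(trimws(box_line)))
      stop_mem("%s: no box line for frame starting line %d", path, pos)
    atoms <- parse_gro_atoms(atom_lines, path, pos + 1L)
    box <- parse_gro_box(box_line, path, pos + 2L + natoms)
    frames[[length(frames) + 1L]] <-
      mem_frame(atoms, box, label = trimws(title))
    pos <- pos + 3L + natoms
    while (pos <= n_total && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (!length(frames)) stop_mem("%s: no frames found", path)
  frames
}

parse_gro_atoms <- function(atom_lines, path, offset) {
  res_id <- suppressWarnings(as.integer(substr(atom_lines, 1, 5)))
  res_name <- trimws(substr(atom_lines, 6, 10))
  atom_name <- trimws(substr(atom_lines, 11, 15))
  serial <- suppressWarnings(as.integer(substr(atom_lines, 16, 20)))
  x <- suppressWarnings(as.numeric(substr(atom_lines, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 37, 44)))
  bad <- which(is.na(res_id) | is.na(x) | is.na(y) | is.na(z) |
                 !nzchar(atom_name))
  if (length(bad))
    stop_mem("%s line %d: malformed GRO atom line", path, offset + bad[1])
  data.frame(serial = serial, atom_name = atom_name, res_name = res_name,
             res_id = res_id, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

parse_gro_box <- function(box_line, path, lineno) {
  vals <- suppressWarnings(as.numeric(strsplit(trimws(box_line), "\\s+")[[1]]))
  if (any(is.na(vals)) || !(length(vals) %in% c(3L, 9L)))
    stop_mem("%s line %d: malformed box line", path, lineno)
  if (length(vals) == 9L && any(abs(vals[4:9]) > 1e-9))
    stop_mem("%s line %d: triclinic box not supported", path, lineno)
  vals[1:3]
}

parse_pdb_frames <- function(lines, path) {
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cryst))
    stop_mem("%s: no box (CRYST1 record absent)", path)
  a <- as.numeric(substr(cryst[1], 7, 15))
  b <- as.numeric(substr(cryst[1], 16, 24))
  c3 <- as.numeric(substr(cryst[1], 25, 33))
  ang <- c(as.numeric(substr(cryst[1], 34, 40)),
           as.numeric(substr(cryst[1], 41, 47)),
           as.numeric(substr(cryst[1], 48, 54)))
  if (any(is.na(c(a, b, c3, ang))))
    stop_mem("%s: malformed CRYST1 record", path)
  if (any(abs(ang - 90) > 1e-3))
    stop_mem("%s: triclinic box (angles %s) not supported", path,
             paste(ang, collapse = ", "))
  box <- c(a, b, c3) / 10  # Angstrom -> nm

  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {
    blocks <- list(which(is_atom))
    labels <- ""
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) < length(model_starts))
      model_ends <- c(model_ends, length(lines))
    blocks <- lapply(seq_along(model_starts), function(i) {
      idx <- seq(model_starts[i], model_ends[i])
      idx[is_atom[idx]]
    })
    labels <- trimws(substr(lines[model_starts], 7, 20))
  }
  frames <- lapply(seq_along(blocks), function(i) {
    idx <- blocks[[i]]
    if (!length(idx)) stop_mem("%s: MODEL %d contains no atoms", path, i)
    al <- lines[idx]
    serial <- suppressWarnings(as.integer(substr(al, 7, 11)))
    atom_name <- trimws(substr(al, 13, 16))
    res_name <- trimws(substr(al, 18, 21))
    res_id <- suppressWarnings(as.integer(substr(al, 23, 26)))
    x <- suppressWarnings(as.numeric(substr(al, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(al, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(al, 47, 54)))
    elem <- trimws(substr(al, 77, 78))
    bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(res_id))
    if (length(bad))
      stop_mem("%s line %d: malformed PDB atom record", path, idx[bad[1]])
    atoms <- data.frame(serial = serial, atom_name = atom_name,
                        res_name = res_name, res_id = res_id,
                        x = x / 10, y = y / 10, z = z / 10,
                        stringsAsFactors = FALSE)
    atoms$element <- ifelse(nzchar(elem), toupper(elem),
                            infer_element(atom_name))
    mem_frame(atoms, box, label = labels[min(i, length(labels))])
  })
  frames
}

#' Write a coordinate file
#'
#' Writes a [mem_frame] as GRO (positions fixed to 3 decimals, nm) or PDB
#' (Angstrom, CRYST1 box).  The output is re-readable by [read_structure];
#' round-trip agreement is within the format precision (1e-3 nm for GRO).
#'
#' @param frame a [mem_frame].
#' @param path output file path.
#' @param format `"gro"` or `"pdb"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_structure <- function(frame, path, format = guess_format(path)) {
  if (!inherits(frame, "mem_frame")) stop_mem("frame must be a mem_frame")
  if (!nrow(frame$atoms)) stop_mem("refusing to write an empty frame")
  format <- match.arg(format, c("gro", "pdb"))
  a <- frame$atoms
  lines <- if (format == "gro") {
    c(if (nzchar(frame$label)) frame$label else "memdefect frame",
      sprintf("%5d", nrow(a)),
      sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
              a$res_id %% 100000L, substr(a$res_name, 1, 5),
              substr(a$atom_name, 1, 5), a$serial %% 100000L,
              a$x, a$y, a$z),
      sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2], frame$box[3]))
  } else {
    c(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
              frame$box[1] * 10, frame$box[2] * 10, frame$box[3] * 10,
              90, 90, 90),
      sprintf("ATOM  %5d %-4s %-4s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
              a$serial %% 100000L, substr(a$atom_name, 1, 4),
              substr(a$res_name, 1, 4), a$res_id %% 10000L,
              a$x * 10, a$y * 10, a$z * 10, substr(a$element, 1, 2)),
      "END")
  }
  ok <- tryCatch(suppressWarnings({ writeLines(lines, path); TRUE }),
                 error = function(e) FALSE)
  if (!ok) stop_mem("cannot write to '%s'", path)
  invisible(path)
}
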