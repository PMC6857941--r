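# Fixed-column PDB / PDBQT reading and writing for receptors and multi-MODEL
# ligand pose files. AutoDock PDBQT atom types (A, OA, NA, HD, SA, ...) are
# mapped to elements; plain PDB falls back to columns 77-78, then to the atom
# name. Alternate locations other than '' / 'A' are dropped with a warning.

# AutoDock atom type -> element. 'A' is aromatic carbon.
.AUTODOCK_ELEMENTS <- c(
  A = "C", C = "C", N = "N", NA. = "N", NS = "N", OA = "O", OS = "O",
  O = "O", H = "H", HD = "H", HS = "H", S = "S", SA = "S", P = "P",
  F = "F", CL = "CL", BR = "BR", I = "I", MG = "MG", ZN = "ZN",
  MN = "MN", CA. = "CA", FE = "FE"
)

.autodock_element <- function(type) {
  key <- toupper(type)
  key[key == "NA"] <- "NA."   # avoid clash with R's NA when indexing
  key[key == "CA"] <- "CA."
  out <- .AUTODOCK_ELEMENTS[key]
  unname(out)
}

.element_from_name <- function(name) {
  # PDB atom names right-pad the element; digits may lead (e.g. "1HB1").
  stripped <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(stripped, 1, 2))
  one <- toupper(substr(stripped, 1, 1))
  ifelse(two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "MN"), two, one)
}

.parse_atom_lines <- function(lines, line_numbers, dialect) {
  n <- length(lines)
  field <- function(start, stop) {
    out <- substr(lines, start, stop)
    trimws(out)
  }
  serial <- suppressWarnings(as.integer(field(7, 11)))
  name <- field(13, 16)
  altloc <- field(17, 17)
  resname <- field(18, 20)
  chain <- field(22, 22)
  resno <- suppressWarnings(as.integer(field(23, 26)))
  insert <- field(27, 27)
  x <- suppressWarnings(as.numeric(field(31, 38)))
  y <- suppressWarnings(as.numeric(field(39, 46)))
  z <- suppressWarnings(as.numeric(field(47, 54)))

  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0L) {
    stop(sprintf("malformed coordinate field at line %d: '%s'",
                 line_numbers[bad[1]], lines[bad[1]]), call. = FALSE)
  }
  bad_serial <- which(is.na(serial))
  if (length(bad_serial) > 0L) serial[bad_serial] <- seq_len(n)[bad_serial]

  if (identical(dialect, "pdbqt")) {
    # last whitespace-separated token is the AutoDock atom type
    type <- vapply(strsplit(trimws(lines), "\\s+"), function(tok) tok[length(tok)], "")
    element <- .autodock_element(type)
    missing_el <- which(is.na(element))
    if (length(missing_el) > 0L) {
      element[missing_el] <- .element_from_name(name[missing_el])
    }
  } else {
    element <- toupper(field(77, 78))
    blank <- which(element == "" | is.na(element))
    if (length(blank) > 0L) element[blank] <- .element_from_name(name[blank])
  }

  data.frame(
    serial = serial, name = name, altloc = altloc, element = element,
    resname = resname, chain = chain, resno = resno, insert = insert,
    x = x, y = y, z = z,
    stringsAsFactors = FALSE
  )
}

.drop_altlocs <- function(atoms) {
  keep <- atoms$altloc %in% c("", "A")
  if (!all(keep)) {
    warning(sprintf("dropping %d alternate-location atoms (keeping altloc '' or 'A')",
                    sum(!keep)), call. = FALSE)
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL
  }
  atoms
}

.guess_dialect <- function(path) {
  if (grepl("\\.pdbqt$", path, ignore.case = TRUE)) "pdbqt" else "pdb"
}

#' Read a receptor structure from a PDB or PDBQT file
#'
#' Parses all `ATOM`/`HETATM` records (MODEL wrappers, if any, are ignored for
#' receptors) and indexes atoms by residue. Coordinates are in angstroms;
#' residue numbering and insertion codes follow the input file.
#'
#' @param path Path to the structure file.
#' @param dialect `"pdb"`, `"pdbqt"`, or `"auto"` (from the file extension).
#' @return An object of class `receptor`: a list with `atoms` (data frame with
#'   columns `serial`, `name`, `element`, `resname`, `chain`, `resno`,
#'   `insert`, `x`, `y`, `z`) and `residue_index`, a named list mapping
#'   `"chain/resno/insert"` keys to atom row indices.
#' @export
read_receptor <- function(path, dialect = c("auto", "pdb", "pdbqt")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") dialect <- .guess_dialect(path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  atoms <- .parse_atom_lines(lines[is_atom], which(is_atom), dialect)
  atoms <- .drop_altlocs(atoms)
  new_receptor(atoms)
}

#' @rdname read_receptor
#' @param atoms Atom table as returned by the parser.
#' @export
new_receptor <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "/")
  residue_index <- split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
  structure(list(atoms = atoms, residue_index = residue_index),
            class = "receptor")
}

#' @export
print.receptor <- function(x, ...) {
  cat(sprintf("<receptor> %d atoms, %d residues\n",
              nrow(x$atoms), length(x$residue_index)))
  invisible(x)
}

#' Read a multi-MODEL ligand pose file
#'
#' Each `MODEL`...`ENDMDL` block becomes one pose; a file without MODEL
#' records is read as a single pose. All poses must have the same atom count
#' and atom-name ordering (as AutoDock writes them).
#'
#' @param path Path to a PDB or PDBQT pose file.
#' @param dialect `"pdb"`, `"pdbqt"`, or `"auto"`.
#' @param ligand_id Identifier for the ligand; defaults to the file base name.
#' @return An object of class `pose_set`: list with `ligand_id` and `poses`,
#'   a list of `pose` objects (each with an `atoms` data frame, `pose_index`,
#'   and `bonds`, initially `NULL`).
#' @export
read_poses <- function(path, dialect = c("auto", "pdb", "pdbqt"),
                       ligand_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") dialect <- .guess_dialect(path)
  if (is.null(ligand_id)) {
    ligand_id <- sub("\\.(pdb|pdbqt)$", "", basename(path), ignore.case = TRUE)
  }
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  model_ends <- grep("^ENDMDL", lines)
  blocks <- if (length(model_starts) == 0L) {
    list(seq_along(lines))
  } else {
    if (length(model_starts) != length(model_ends)) {
      stop("unbalanced MODEL/ENDMDL records in ", path, call. = FALSE)
    }
    mapply(function(s, e) seq(s, e), model_starts, model_ends, SIMPLIFY = FALSE)
  }

  poses <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    sel <- idx[grepl("^(ATOM  |HETATM)", lines[idx])]
    if (length(sel) == 0L) {
      stop(sprintf("pose block %d contains no atoms", b), call. = FALSE)
    }
    atoms <- .parse_atom_lines(lines[sel], sel, dialect)
    atoms <- .drop_altlocs(atoms)
    poses[[b]] <- new_pose(atoms, pose_index = b)
  }

  counts <- vapply(poses, function(p) nrow(p$atoms), integer(1))
  if (length(unique(counts)) != 1L) {
    stop(sprintf("pose blocks differ in atom count: %s",
                 paste(unique(counts), collapse = ", ")), call. = FALSE)
  }
  ref_names <- poses[[1]]$atoms$name
  same <- vapply(poses, function(p) identical(p$atoms$name, ref_names), logical(1))
  if (!all(same)) {
    stop("pose blocks differ in atom ordering (atom names do not match)",
         call. = FALSE)
  }
  new_pose_set(ligand_id, poses)
}

#' Construct a pose from an atom table
#'
#' @param atoms Data frame with at least `name`, `element`, `x`, `y`, `z`.
#'   Missing bookkeeping columns (`serial`, `resname`, ...) are filled in.
#' @param pose_index Integer index of the pose within its set (>= 1).
#' @param bonds Optional two-column matrix of atom-index pairs; `NULL` means
#'   connectivity is to be inferred on demand.
#' @return An object of class `pose`.
#' @export
new_pose <- function(atoms, pose_index = 1L, bonds = NULL) {
  stopifnot(is.data.frame(atoms), pose_index >= 1)
  defaults <- list(serial = seq_len(nrow(atoms)), altloc = "",
                   resname = "LIG", chain = "A", resno = 1L, insert = "")
  for (col in names(defaults)) {
    if (is.null(atoms[[col]])) atoms[[col]] <- defaults[[col]]
  }
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates", call. = FALSE)
  }
  if (any(is.na(atoms$element) | atoms$element == "")) {
    stop("every atom needs an element symbol", call. = FALSE)
  }
  if (!is.null(bonds)) bonds <- .validate_bonds(bonds, nrow(atoms))
  structure(list(atoms = atoms, pose_index = as.integer(pose_index),
                 bonds = bonds),
            class = "pose")
}

.validate_bonds <- function(bonds, n_atoms) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (any(bonds < 1L | bonds > n_atoms)) stop("bond index out of range", call. = FALSE)
  if (any(bonds[, 1] == bonds[, 2])) stop("self-bond not allowed", call. = FALSE)
  # canonical order i < j, no duplicates
  swap <- bonds[, 1] > bonds[, 2]
  bonds[swap, ] <- bonds[swap, 2:1]
  unique(bonds)
}

#' @rdname new_pose
#' @param ligand_id Ligand identifier.
#' @param poses List of `pose` objects.
#' @export
new_pose_set <- function(ligand_id, poses) {
  idx <- vapply(poses, function(p) p$pose_index, integer(1))
  if (anyDuplicated(idx)) stop("duplicate pose_index in pose set", call. = FALSE)
  structure(list(ligand_id = ligand_id, poses = poses), class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  n_atoms <- if (length(x$poses)) nrow(x$poses[[1]]$atoms) else 0L
  cat(sprintf("<pose_set> ligand '%s': %d poses x %d atoms\n",
              x$ligand_id, length(x$poses), n_atoms))
  invisible(x)
}

.format_atom_line <- function(atoms, dialect) {
  record <- rep("ATOM  ", nrow(atoms))
  base <- sprintf("%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f",
                  record, atoms$serial,
                  formatC(atoms$name, width = 4, flag = "-"),
                  atoms$altloc, atoms$resname, atoms$chain, atoms$resno,
                  atoms$insert, atoms$x, atoms$y, atoms$z)
  if (identical(dialect, "pdbqt")) {
    type <- .element_to_autodock(atoms$element)
    paste0(base, sprintf("  %4.2f  %4.2f    %+.3f %-2s", 1, 0, 0, type))
  } else {
    paste0(base, sprintf("%6.2f%6.2f          %2s", 1, 0, atoms$element))
  }
}

.element_to_autodock <- function(element) {
  map <- c(C = "C", N = "N", O = "OA", H = "HD", S = "SA", P = "P",
           F = "F", CL = "Cl", BR = "Br", I = "I")
  out <- map[toupper(element)]
  out[is.na(out)] <- element[is.na(out)]
  unname(out)
}

#' Write a receptor or pose set to a PDB/PDBQT file
#'
#' Coordinates are written at PDB precision (three decimals). Pose sets are
#' wrapped in `MODEL`/`ENDMDL` blocks in pose order. A `header` comment line
#' (written as `REMARK`) can record provenance such as a seed.
#'
#' @param x A `receptor` or `pose_set`.
#' @param path Output path.
#' @param dialect `"pdb"` or `"pdbqt"`.
#' @param header Optional character vector of remark lines.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, dialect = c("pdb", "pdbqt"), header = NULL) {
  dialect <- match.arg(dialect)
  out <- character(0)
  if (!is.null(header)) out <- sprintf("REMARK   1 %s", header)
  if (inherits(x, "receptor")) {
    out <- c(out, .format_atom_line(x$atoms, dialect), "END")
  } else if (inherits(x, "pose_set")) {
    for (p in x$poses) {
      out <- c(out,
               sprintf("MODEL %8d", p$pose_index),
               .format_atom_line(p$atoms, dialect),
               "ENDMDL")
    }
    out <- c(out, "END")
  } else {
    stop("write_structure handles 'receptor' and 'pose_set' objects", call. = FALSE)
  }
  writeLines(out, path)
  invisible(path)
}
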