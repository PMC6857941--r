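# Geometric post-processing of docking poses: covalent connectivity by the
# covalent-radius rule, hydroxyl-group detection, the glycosidic C-O midpoint
# of UDP-glucuronic acid, and the two distance-threshold classifiers
# (hydroxyl orientation of the substrate; correct coenzyme binding mode).

# Covalent radii in angstroms (Cordero et al. consensus values).
.COVALENT_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  SI = 1.11, P = 1.07, S = 1.05, CL = 1.02, BR = 1.20, I = 1.39,
  SE = 1.20, ZN = 1.22, MG = 1.41, FE = 1.32, MN = 1.39, CA = 1.76
)

#' Default hydroxyl-orientation cutoff
#'
#' The classification cutoff is the sum of a hydrogen-bond distance and the
#' positional error of the docking program: 3.2 + 0.6 = 3.8 angstroms.
#'
#' @param hbond_distance Hydrogen-bond donor-acceptor distance, angstroms.
#' @param docking_error Positional uncertainty of docked poses, angstroms.
#' @return The cutoff in angstroms (3.8 by default).
#' @export
default_orientation_cutoff <- function(hbond_distance = 3.2, docking_error = 0.6) {
  hbond_distance + docking_error
}

.coords <- function(pose) as.matrix(pose$atoms[, c("x", "y", "z")])

#' Infer covalent connectivity from interatomic distances
#'
#' Two atoms are bonded when their distance does not exceed
#' `scale * (r_i + r_j)` with covalent radii `r`. Explicit bond records
#' already attached to the pose take precedence and are returned unchanged.
#'
#' @param pose A `pose` object.
#' @param scale Multiplier on the covalent-radius sum (default 1.2).
#' @return Two-column integer matrix of bonded atom-index pairs (i < j).
#' @export
infer_connectivity <- function(pose, scale = 1.2) {
  if (!is.null(pose$bonds)) return(pose$bonds)
  el <- toupper(pose$atoms$element)
  unknown <- setdiff(unique(el), names(.COVALENT_RADII))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  radii <- .COVALENT_RADII[el]
  xyz <- .coords(pose)
  d <- as.matrix(stats::dist(xyz))
  cutoff <- scale * outer(radii, radii, "+")
  adj <- d <= cutoff & upper.tri(d) & d > 0.01
  which(adj, arr.ind = TRUE, useNames = FALSE)
}

#' Attach connectivity to a pose
#'
#' @inheritParams infer_connectivity
#' @return The pose with its `bonds` field populated.
#' @export
ensure_bonds <- function(pose, scale = 1.2) {
  if (is.null(pose$bonds)) pose$bonds <- infer_connectivity(pose, scale)
  pose
}

.neighbor_list <- function(pose) {
  bonds <- infer_connectivity(pose)
  n <- nrow(pose$atoms)
  nb <- vector("list", n)
  if (length(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

#' Find hydroxyl oxygens in a pose
#'
#' A hydroxyl oxygen is an oxygen bonded to exactly one carbon and one
#' hydrogen and nothing else (hydroxyl, phenol, enol and the O-H oxygen of a
#' carboxylic acid all qualify; carbonyl, ether and ester oxygens do not).
#' When the pose carries no hydrogens at all, the criterion degrades to an
#' oxygen whose single neighbor is a carbon.
#'
#' @param pose A `pose` object (connectivity is inferred if absent).
#' @return Integer vector of atom indices; may be empty.
#' @export
find_hydroxyl_oxygens <- function(pose) {
  el <- toupper(pose$atoms$element)
  nb <- .neighbor_list(pose)
  has_hydrogens <- any(el == "H")
  ox <- which(el == "O")
  keep <- vapply(ox, function(i) {
    nel <- el[nb[[i]]]
    n_c <- sum(nel == "C")
    n_h <- sum(nel == "H")
    n_other <- length(nel) - n_c - n_h
    if (has_hydrogens) {
      n_c == 1L && n_h == 1L && n_other == 0L
    } else {
      n_c == 1L && n_h == 0L && n_other == 0L
    }
  }, logical(1))
  ox[keep]
}

#' Locate the glycosidic C-O bond midpoint of a UDPGA pose
#'
#' Identifies the bridging oxygen between glucuronic acid and the UDP
#' pyrophosphate: an oxygen bonded to both a phosphorus and a carbon, where
#' that carbon (the anomeric carbon of glucuronate) carries a further oxygen
#' neighbor (its ring oxygen). Returns the bond's two atoms and their
#' midpoint, the reference point of the hydroxyl-orientation criterion.
#'
#' @param udpga_pose A `pose` of the coenzyme.
#' @return An object of class `glycosidic_reference`: list with
#'   `carbon_index`, `oxygen_index`, and `midpoint` (length-3 numeric,
#'   angstroms).
#' @export
locate_glycosidic_midpoint <- function(udpga_pose) {
  el <- toupper(udpga_pose$atoms$element)
  nb <- .neighbor_list(udpga_pose)
  xyz <- .coords(udpga_pose)

  candidates <- list()
  for (i in which(el == "O")) {
    nbr <- nb[[i]]
    has_p <- any(el[nbr] == "P")
    carbons <- nbr[el[nbr] == "C"]
    if (!has_p || length(carbons) != 1L) next
    c_idx <- carbons[1]
    # the anomeric carbon must carry another oxygen (the pyranose ring O)
    other_ox <- setdiff(nb[[c_idx]][el[nb[[c_idx]]] == "O"], i)
    if (length(other_ox) >= 1L) {
      candidates[[length(candidates) + 1L]] <- c(oxygen = i, carbon = c_idx)
    }
  }
  if (length(candidates) != 1L) {
    stop(sprintf(
      "expected exactly 1 glycosidic bridging oxygen, found %d",
      length(candidates)), call. = FALSE)
  }
  o_idx <- candidates[[1]][["oxygen"]]
  c_idx <- candidates[[1]][["carbon"]]
  structure(list(
    carbon_index = c_idx,
    oxygen_index = o_idx,
    midpoint = as.numeric((xyz[o_idx, ] + xyz[c_idx, ]) / 2)
  ), class = "glycosidic_reference")
}

#' Minimum hydroxyl-oxygen distance to the glycosidic midpoint
#'
#' @param substrate_pose A `pose` with at least one hydroxyl oxygen.
#' @param reference A `glycosidic_reference`.
#' @return Distance in angstroms (minimum over hydroxyl oxygens).
#' @export
hydroxyl_min_distance <- function(substrate_pose, reference) {
  ox <- find_hydroxyl_oxygens(substrate_pose)
  if (length(ox) == 0L) {
    stop("substrate has no conjugatable hydroxyl", call. = FALSE)
  }
  xyz <- .coords(substrate_pose)[ox, , drop = FALSE]
  diffs <- sweep(xyz, 2, reference$midpoint)
  min(sqrt(rowSums(diffs^2)))
}

#' Classify the hydroxyl orientation of a substrate pose
#'
#' A pose is oriented (catalytically productive) when at least one hydroxyl
#' oxygen of the substrate lies within `cutoff` of the glycosidic C-O bond
#' midpoint of the coenzyme. The oxygen, not its hydrogen, is the distance
#' atom, and the boundary is inclusive.
#'
#' @inheritParams hydroxyl_min_distance
#' @param cutoff Distance threshold in angstroms (default
#'   [default_orientation_cutoff()], 3.8).
#' @return Logical scalar.
#' @export
classify_hydroxyl_orientation <- function(substrate_pose, reference,
                                          cutoff = default_orientation_cutoff()) {
  stopifnot(cutoff > 0, all(is.finite(reference$midpoint)))
  hydroxyl_min_distance(substrate_pose, reference) <= cutoff
}

#' Count oriented poses in a pose set
#'
#' Applies [classify_hydroxyl_orientation()] to every pose and tallies the
#' oriented-pose count `S_DH` against the total `S_DT`.
#'
#' @param pose_set A `pose_set` of substrate poses.
#' @param reference A `glycosidic_reference`.
#' @param cutoff Distance threshold in angstroms.
#' @return List with `S_DH`, `S_DT`, and `per_pose`, a data frame with
#'   columns `pose_index`, `min_hydroxyl_distance_A`, `oriented` (0/1).
#' @export
count_orientations <- function(pose_set, reference,
                               cutoff = default_orientation_cutoff()) {
  if (length(pose_set$poses) == 0L) stop("empty pose set", call. = FALSE)
  dists <- vapply(pose_set$poses,
                  function(p) hydroxyl_min_distance(p, reference), numeric(1))
  oriented <- dists <= cutoff
  per_pose <- data.frame(
    pose_index = vapply(pose_set$poses, function(p) p$pose_index, integer(1)),
    min_hydroxyl_distance_A = dists,
    oriented = as.integer(oriented)
  )
  list(S_DH = sum(oriented), S_DT = length(dists), per_pose = per_pose)
}

#' Binding-site specification for the coenzyme pocket
#'
#' The UDPGA pocket of UGT1A1 comprises S38, H173, G308, L355, S375, H376 and
#' G377. A pose binds "correctly" when it contacts at least `min_contacts` of
#' the listed residues within `contact_cutoff` (heavy atoms only). The quorum
#' default of 5 tolerates site mutations such as H376R.
#'
#' @param residues Data frame with columns `resno` (integer) and `expected`
#'   (three-letter residue name); defaults to the UGT1A1 coenzyme site.
#' @param contact_cutoff Heavy-atom contact distance, angstroms (default 3.8).
#' @param min_contacts Minimum number of contacted residues (default 5).
#' @return An object of class `binding_site_spec`.
#' @export
binding_site_spec <- function(residues = udpga_site_residues(),
                              contact_cutoff = 3.8, min_contacts = 5L) {
  stopifnot(is.data.frame(residues), nrow(residues) >= 1,
            contact_cutoff > 0,
            min_contacts >= 1, min_contacts <= nrow(residues))
  structure(list(residues = residues,
                 contact_cutoff = contact_cutoff,
                 min_contacts = as.integer(min_contacts)),
            class = "binding_site_spec")
}

#' @rdname binding_site_spec
#' @export
udpga_site_residues <- function() {
  data.frame(
    resno = c(38L, 173L, 308L, 355L, 375L, 376L, 377L),
    expected = c("SER", "HIS", "GLY", "LEU", "SER", "HIS", "GLY"),
    stringsAsFactors = FALSE
  )
}

#' Classify the coenzyme binding mode of a UDPGA pose
#'
#' A site residue is contacted when the minimum heavy-atom distance between
#' the pose and that residue is within the contact cutoff; the pose is in the
#' correct binding mode when at least `min_contacts` residues are contacted.
#' Residue-name mismatches (e.g. a mutated site residue) warn but still
#' count; a residue number absent from the receptor is an error.
#'
#' @param udpga_pose A `pose` of the coenzyme.
#' @param receptor A `receptor`.
#' @param site A `binding_site_spec`.
#' @return List with `is_correct` (logical), `contacted` (data frame of
#'   contacted residues with their minimum distances), and `n_contacted`.
#' @export
classify_udpga_binding <- function(udpga_pose, receptor,
                                   site = binding_site_spec()) {
  heavy_pose <- toupper(udpga_pose$atoms$element) != "H"
  pose_xyz <- .coords(udpga_pose)[heavy_pose, , drop = FALSE]
  rec_el <- toupper(receptor$atoms$element)

  res <- site$residues
  min_dist <- numeric(nrow(res))
  for (k in seq_len(nrow(res))) {
    rows <- which(receptor$atoms$resno == res$resno[k])
    if (length(rows) == 0L) {
      stop("binding-site residue ", res$resno[k], " absent from receptor",
           call. = FALSE)
    }
    seen <- unique(receptor$atoms$resname[rows])
    if (!res$expected[k] %in% seen) {
      warning(sprintf("residue %d is %s, expected %s (mutated site?)",
                      res$resno[k], paste(seen, collapse = "/"),
                      res$expected[k]), call. = FALSE)
    }
    rows <- rows[rec_el[rows] != "H"]
    if (length(rows) == 0L) { min_dist[k] <- Inf; next }
    rxyz <- as.matrix(receptor$atoms[rows, c("x", "y", "z")])
    # min over all pose-residue heavy-atom pairs
    d2 <- outer(rowSums(pose_xyz^2), rowSums(rxyz^2), "+") -
      2 * pose_xyz %*% t(rxyz)
    min_dist[k] <- sqrt(max(0, min(d2)))
  }
  contacted <- min_dist <= site$contact_cutoff
  list(
    is_correct = sum(contacted) >= site$min_contacts,
    contacted = data.frame(resno = res$resno[contacted],
                           expected = res$expected[contacted],
                           min_distance_A = min_dist[contacted]),
    n_contacted = sum(contacted)
  )
}

#' Apply a rigid motion to a structure
#'
#' Utility for invariance checks: rotates then translates all atom
#' coordinates of a `pose`, `pose_set`, `receptor`, or
#' `glycosidic_reference`.
#'
#' @param x The object to transform.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric vector.
#' @return The transformed object.
#' @export
transform_rigid <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  move <- function(atoms) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rotation)
    xyz <- sweep(xyz, 2, translation, "+")
    atoms[, c("x", "y", "z")] <- xyz
    atoms
  }
  if (inherits(x, "pose")) {
    x$atoms <- move(x$atoms)
  } else if (inherits(x, "pose_set")) {
    x$poses <- lapply(x$poses, transform_rigid, rotation = rotation,
                      translation = translation)
  } else if (inherits(x, "receptor")) {
    x$atoms <- move(x$atoms)
  } else if (inherits(x, "glycosidic_reference")) {
    x$midpoint <- as.numeric(rotation %*% x$midpoint + translation)
  } else {
    stop("cannot transform object of class ", class(x)[1], call. = FALSE)
  }
  x
}
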