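# Synthetic fixtures with known ground truth: (a) docking-pose sets whose
# hydroxyl-orientation labels are planted by construction, plus a matching
# UDPGA-like coenzyme pose and a receptor stub carrying the seven
# coenzyme-site residues; (b) variant panels whose capacities follow the
# sigmoid model with chosen constants plus truncated Gaussian noise.
#
# Substrate templates place the reference hydroxyl oxygen at the local
# origin with every other atom in the +x half-space. A pose planted at
# distance d is positioned with +x mapped to the outward radial direction
# from the glycosidic midpoint, so d is exactly the minimum hydroxyl-oxygen
# distance -- the planted label cannot be flipped by another atom of the
# molecule.

.template_atoms <- function(template) {
  a <- function(name, element, x, y, z) {
    data.frame(name = name, element = element, x = x, y = y, z = z,
               stringsAsFactors = FALSE)
  }
  phenol_core <- rbind(
    a("O1", "O", 0.000, 0.000, 0),
    a("HO1", "H", 0.250, 0.930, 0),
    a("C1", "C", 1.360, 0.000, 0),
    a("C2", "C", 2.055, 1.204, 0),
    a("C3", "C", 3.445, 1.204, 0),
    a("C4", "C", 4.140, 0.000, 0),
    a("C5", "C", 3.445, -1.204, 0),
    a("C6", "C", 2.055, -1.204, 0),
    a("H2", "H", 1.515, 2.139, 0),
    a("H3", "H", 3.985, 2.139, 0),
    a("H5", "H", 3.985, -2.139, 0),
    a("H6", "H", 1.515, -2.139, 0)
  )
  switch(template,
    "aap-like" = rbind(
      phenol_core,
      a("N1", "N", 5.540, 0.000, 0),
      a("HN1", "H", 5.890, 0.950, 0),
      a("C7", "C", 6.709, -0.675, 0),
      a("O2", "O", 6.709, -1.905, 0),
      a("C8", "C", 8.017, 0.080, 0),
      a("H81", "H", 8.527, 0.880, 0.300),
      a("H82", "H", 8.527, -0.670, 0.400),
      a("H83", "H", 8.527, 0.080, -0.850)
    ),
    "e2-like" = rbind(
      phenol_core,
      a("C7", "C", 5.680, 0.000, 0.000),
      a("C8", "C", 6.860, 0.000, 0.990),
      a("O17", "O", 8.060, 0.000, 0.140),
      a("HO17", "H", 8.660, 0.750, 0.140)
    ),
    "diol-like" = rbind(
      a("O1", "O", 0.000, 0.000, 0.000),
      a("HO1", "H", 0.250, 0.930, 0.000),
      a("C1", "C", 1.420, 0.000, 0.000),
      a("C2", "C", 2.600, 0.000, 0.990),
      a("O2", "O", 3.700, 0.000, 0.090),
      a("HO2", "H", 4.300, 0.750, 0.090)
    ),
    "carboxyl-like" = rbind(
      a("O1", "O", 0.000, 0.000, 0.000),
      a("HO1", "H", 0.250, 0.930, 0.000),
      a("C1", "C", 1.360, 0.000, 0.000),
      a("O2", "O", 1.960, -1.070, 0.000),
      a("C2", "C", 2.360, 1.140, 0.000),
      a("H21", "H", 3.260, 1.540, 0.300),
      a("H22", "H", 1.760, 1.880, 0.400),
      a("H23", "H", 2.760, 1.140, -0.900)
    ),
    stop("unknown substrate template: ", template, call. = FALSE)
  )
}

# Minimal UDP-glucuronic-acid stub: anomeric carbon C1 and the bridging
# oxygen O1 define the glycosidic bond with midpoint exactly at the origin;
# C1 carries the pyranose ring oxygen, O1 the pyrophosphate phosphorus.
.udpga_stub <- function() {
  data.frame(
    name = c("C1", "O1", "O5", "C5R", "C2", "P1", "O1P", "O2P", "O3P"),
    element = c("C", "O", "O", "C", "C", "P", "O", "O", "O"),
    x = c(0.70, -0.70, 1.40, 2.80, 1.25, -1.90, -2.90, -1.60, -3.00),
    y = c(0.00, 0.00, 1.20, 1.30, -1.35, 0.90, 0.20, 2.40, 1.40),
    z = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.60, 0.00, -0.90),
    stringsAsFactors = FALSE
  )
}

# Receptor stub: the seven coenzyme-site residues of UGT1A1, each a short
# atom chain pointing outward from the coenzyme so that its innermost atom
# sits `anchor_distance` from the nearest coenzyme heavy atom.
.receptor_stub <- function(udpga_atoms, anchor_distance = 3.0) {
  res <- data.frame(
    resno = c(38L, 173L, 308L, 355L, 375L, 376L, 377L),
    resname = c("SER", "HIS", "GLY", "LEU", "SER", "HIS", "GLY"),
    stringsAsFactors = FALSE
  )
  backbone <- list(
    SER = data.frame(name = c("N", "CA", "C", "O", "CB", "OG"),
                     element = c("N", "C", "C", "O", "C", "O")),
    HIS = data.frame(name = c("N", "CA", "C", "O", "CB"),
                     element = c("N", "C", "C", "O", "C")),
    GLY = data.frame(name = c("N", "CA", "C", "O"),
                     element = c("N", "C", "C", "O")),
    LEU = data.frame(name = c("N", "CA", "C", "O", "CB"),
                     element = c("N", "C", "C", "O", "C"))
  )
  heavy <- udpga_atoms[toupper(udpga_atoms$element) != "H", ]
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  out <- list()
  serial <- 0L
  for (k in seq_len(nrow(res))) {
    theta <- 2 * pi * (k - 1) / nrow(res)
    u <- c(cos(theta), sin(theta), 0.15 * ((-1)^k))
    u <- u / sqrt(sum(u^2))
    v <- c(-sin(theta), cos(theta), 0)
    # coenzyme atom sticking furthest out along u anchors the contact
    proj <- xyz %*% u
    anchor <- xyz[which.max(proj), ] + anchor_distance * u
    tmpl <- backbone[[res$resname[k]]]
    offsets_along <- c(N = 0, CA = 1.46, C = 2.99, O = 4.22)
    for (j in seq_len(nrow(tmpl))) {
      nm <- tmpl$name[j]
      pos <- if (nm %in% names(offsets_along)) {
        anchor + offsets_along[[nm]] * u
      } else if (nm == "CB") {
        anchor + 1.46 * u + 1.53 * v
      } else {  # OG
        anchor + 1.46 * u + 2.95 * v
      }
      serial <- serial + 1L
      out[[serial]] <- data.frame(
        serial = serial, name = nm, altloc = "", element = tmpl$element[j],
        resname = res$resname[k], chain = "A", resno = res$resno[k],
        insert = "", x = pos[1], y = pos[2], z = pos[3],
        stringsAsFactors = FALSE
      )
    }
  }
  new_receptor(do.call(rbind, out))
}

#' Specification of a synthetic pose fixture
#'
#' @param n_poses Number of substrate poses (the docking-run count; the
#'   conventional protocol uses 100 runs per pair).
#' @param frac_oriented Fraction of poses planted inside the cutoff;
#'   `round(n_poses * frac_oriented)` poses are oriented.
#' @param cutoff Classification cutoff in angstroms.
#' @param inside_range,outside_range Distance ranges (angstroms) the planted
#'   hydroxyl-midpoint distances are drawn from; must sit strictly below and
#'   above the cutoff respectively.
#' @param substrate_template One of `"aap-like"`, `"e2-like"`,
#'   `"diol-like"`, `"carboxyl-like"`.
#' @param seed Integer seed; identical specs give byte-identical files.
#' @return A list of class `pose_fixture_spec`.
#' @export
pose_fixture_spec <- function(n_poses = 100L, frac_oriented = 0.3,
                              cutoff = default_orientation_cutoff(),
                              inside_range = c(2.2, 3.6),
                              outside_range = c(4.2, 7.5),
                              substrate_template = "aap-like",
                              seed = 1L) {
  stopifnot(n_poses >= 1, frac_oriented >= 0, frac_oriented <= 1)
  if (inside_range[1] > inside_range[2] || outside_range[1] > outside_range[2]) {
    stop("degenerate distance range", call. = FALSE)
  }
  if (inside_range[2] > cutoff || outside_range[1] <= cutoff) {
    stop("distance ranges cross the cutoff: inside must stay <= cutoff, outside > cutoff",
         call. = FALSE)
  }
  structure(list(n_poses = as.integer(n_poses), frac_oriented = frac_oriented,
                 cutoff = cutoff, inside_range = inside_range,
                 outside_range = outside_range,
                 substrate_template = substrate_template,
                 seed = as.integer(seed)),
            class = "pose_fixture_spec")
}

.random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# rotation mapping +x to u, with spin angle phi about u
.frame_rotation <- function(u, phi) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  cbind(u, cos(phi) * v + sin(phi) * w, -sin(phi) * v + cos(phi) * w)
}

#' Generate a pose fixture with planted orientation labels
#'
#' Writes a receptor stub (PDB) with the seven coenzyme-site residues, a
#' single-model coenzyme pose file (PDBQT) whose glycosidic C-O midpoint is
#' at the origin, a multi-MODEL substrate pose file (PDBQT), and a label
#' table recording each pose's planted hydroxyl-midpoint distance and
#' orientation label.
#'
#' @param spec A [pose_fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `paths` (named: `receptor`, `udpga`, `substrate`,
#'   `labels`) and `labels`, the label data frame (`pose_index`,
#'   `planted_distance_A`, `oriented`).
#' @export
generate_pose_fixture <- function(spec, dir = tempfile("pose_fixture_")) {
  stopifnot(inherits(spec, "pose_fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  n_inside <- round(spec$n_poses * spec$frac_oriented)
  inside <- rep(FALSE, spec$n_poses)
  if (n_inside > 0) inside[sample.int(spec$n_poses, n_inside)] <- TRUE
  d <- ifelse(inside,
              stats::runif(spec$n_poses, spec$inside_range[1], spec$inside_range[2]),
              stats::runif(spec$n_poses, spec$outside_range[1], spec$outside_range[2]))

  tmpl <- .template_atoms(spec$substrate_template)
  local_xyz <- as.matrix(tmpl[, c("x", "y", "z")])
  poses <- vector("list", spec$n_poses)
  for (i in seq_len(spec$n_poses)) {
    u <- .random_unit_vector()
    rot <- .frame_rotation(u, stats::runif(1, 0, 2 * pi))
    xyz <- local_xyz %*% t(rot)
    xyz <- sweep(xyz, 2, d[i] * u, "+")
    atoms <- tmpl
    atoms[, c("x", "y", "z")] <- xyz
    poses[[i]] <- new_pose(atoms, pose_index = i)
  }
  substrate_set <- new_pose_set(spec$substrate_template, poses)

  udpga_atoms <- .udpga_stub()
  udpga_set <- new_pose_set("udpga", list(new_pose(udpga_atoms, pose_index = 1L)))
  receptor <- .receptor_stub(udpga_atoms)

  paths <- list(
    receptor = file.path(dir, "receptor.pdb"),
    udpga = file.path(dir, "udpga_poses.pdbqt"),
    substrate = file.path(dir, "substrate_poses.pdbqt"),
    labels = file.path(dir, "labels.csv")
  )
  hdr <- sprintf("synthetic fixture, seed %d", spec$seed)
  write_structure(receptor, paths$receptor, dialect = "pdb", header = hdr)
  write_structure(udpga_set, paths$udpga, dialect = "pdbqt", header = hdr)
  write_structure(substrate_set, paths$substrate, dialect = "pdbqt", header = hdr)

  labels <- data.frame(
    pose_index = seq_len(spec$n_poses),
    planted_distance_A = d,
    oriented = as.integer(inside)
  )
  .write_csv_with_header(labels, paths$labels, seed = spec$seed,
                         extra = sprintf("# cutoff: %g", spec$cutoff))
  list(paths = paths, labels = labels, spec = spec)
}

#' Specification of a synthetic variant panel
#'
#' Emulates the data-generating process the capacity model assumes: each
#' variant's capacity is `sigma * kappa * sigmoid(f)^beta + epsilon` plus
#' Gaussian noise truncated at zero, where `f` is its oriented-pose
#' fraction.
#'
#' @param n_variants Number of mutant variants (wild-type is added on top).
#' @param S_DT Total docking runs per variant (default 100).
#' @param true_params Generating [model_params()]; `beta` sets the wild-type
#'   oriented count `S_DH(wild) = round(S_DT / beta)`.
#' @param fraction_grid Oriented-pose fractions of the mutants; default an
#'   even grid on [0.05, 0.95].
#' @param noise_sd Capacity noise standard deviation; `NULL` defaults to 5%
#'   of the wild-type capacity (matching reported in vitro assay
#'   variability of roughly 10% CV).
#' @param nd_threshold Capacities below this are reported not-detected.
#' @param genotypes Promoter genotype per variant, recycled.
#' @param n_zero_binding Number of variants (taken from the end of the grid)
#'   given `udpga_correct_count = 0`, i.e. a disrupted coenzyme site.
#' @param binomial Draw `S_DH` binomially around `fraction * S_DT` instead
#'   of deterministically rounding.
#' @param seed Integer seed.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(n_variants = 20L, S_DT = 100L,
                       true_params = model_params(sigma = 50, gamma = 8,
                                                  mu = 0.4, epsilon = 0,
                                                  beta = 2.5),
                       fraction_grid = NULL, noise_sd = NULL,
                       nd_threshold = 0, genotypes = "wild/wild",
                       n_zero_binding = 0L, binomial = FALSE, seed = 1L) {
  stopifnot(n_variants >= 1, S_DT >= 1, is.null(noise_sd) || noise_sd >= 0,
            nd_threshold >= 0, n_zero_binding >= 0,
            n_zero_binding <= n_variants)
  if (is.null(fraction_grid)) {
    fraction_grid <- seq(0.05, 0.95, length.out = n_variants)
  }
  stopifnot(all(fraction_grid >= 0 & fraction_grid <= 1))
  structure(list(n_variants = as.integer(n_variants), S_DT = as.integer(S_DT),
                 true_params = true_params, fraction_grid = fraction_grid,
                 noise_sd = noise_sd, nd_threshold = nd_threshold,
                 genotypes = genotypes,
                 n_zero_binding = as.integer(n_zero_binding),
                 binomial = isTRUE(binomial), seed = as.integer(seed)),
            class = "panel_spec")
}

#' Generate a variant panel with known model constants
#'
#' @param spec A [panel_spec()].
#' @param dir Optional directory; when given, the docking-summary and
#'   capacity CSVs the pipeline reads are written there.
#' @return List with `panel` (a `capacity_panel`), `summaries` and
#'   `capacities` (the CSV-dialect data frames), and `truth` (the generating
#'   constants and per-variant noiseless capacities).
#' @export
generate_variant_panel <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  p <- spec$true_params

  S_DH_wild <- round(spec$S_DT / p$beta)
  if (S_DH_wild < 1) stop("beta too large: wild-type would have no oriented poses",
                          call. = FALSE)
  beta_real <- spec$S_DT / S_DH_wild
  f_wild <- S_DH_wild / spec$S_DT
  wild_true <- p$sigma * sigmoid_term(f_wild, p$gamma, p$mu)^beta_real + p$epsilon
  noise_sd <- if (is.null(spec$noise_sd)) 0.05 * wild_true else spec$noise_sd

  n <- spec$n_variants
  genotypes <- rep_len(spec$genotypes, n)
  kap <- kappa(genotypes, "printed")
  fractions <- spec$fraction_grid
  S_DH <- if (spec$binomial) {
    stats::rbinom(n, spec$S_DT, fractions)
  } else {
    round(fractions * spec$S_DT)
  }
  f_real <- S_DH / spec$S_DT
  v_true <- p$sigma * kap * sigmoid_term(f_real, p$gamma, p$mu)^beta_real +
    p$epsilon
  v_obs <- pmax(0, v_true + stats::rnorm(n, 0, noise_sd))
  wild_obs <- pmax(0, wild_true + stats::rnorm(1, 0, noise_sd))

  correct_counts <- sample(80:100, n, replace = TRUE)
  if (spec$n_zero_binding > 0) {
    zero_idx <- seq(n - spec$n_zero_binding + 1L, n)
    correct_counts[zero_idx] <- 0L
  }
  nd <- v_obs < spec$nd_threshold

  variants <- sprintf("V%02d", seq_len(n))
  ligand <- "synthetic"
  summaries <- data.frame(
    variant = c("wild", variants), ligand = ligand,
    S_DT = spec$S_DT, S_DH = c(S_DH_wild, S_DH),
    udpga_correct_count = c(sample(80:100, 1), correct_counts),
    stringsAsFactors = FALSE
  )
  capacities <- data.frame(
    variant = c("wild", variants),
    genotype = c("wild/wild", genotypes),
    V_c = c(wild_obs, ifelse(nd, NA_real_, v_obs)),
    nd = c(FALSE, nd),
    stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_summary_csv(summaries, file.path(dir, "docking_summaries.csv"),
                      seed = spec$seed)
    write_capacity_csv(capacities, file.path(dir, "capacities.csv"),
                       seed = spec$seed)
  }
  panel <- capacity_panel(summaries, capacities, ligand = ligand,
                          wild_name = "wild")
  list(panel = panel, summaries = summaries, capacities = capacities,
       truth = list(params = p, beta_realized = beta_real,
                    noise_sd = noise_sd, wild_capacity = wild_true,
                    fractions = f_real, capacities_noiseless = v_true))
}
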