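test_that("covalent-radius rule finds bonds at standard lengths only", {
  oh <- new_pose(make_atoms(list("O1", "O", 0, 0, 0),
                            list("H1", "H", 0, 0, 0.97)))
  expect_equal(infer_connectivity(oh), matrix(c(1L, 2L), ncol = 2))

  cc <- new_pose(make_atoms(list("C1", "C", 0, 0, 0),
                            list("C2", "C", 3, 0, 0)))
  expect_equal(nrow(infer_connectivity(cc)), 0)

  water <- new_pose(make_atoms(list("O", "O", 0, 0, 0),
                               list("H1", "H", 0.96, 0, 0),
                               list("H2", "H", -0.24, 0.93, 0)))
  expect_equal(nrow(infer_connectivity(water)), 2)

  bad <- new_pose(make_atoms(list("X1", "XX", 0, 0, 0),
                             list("C1", "C", 1.5, 0, 0)))
  expect_error(infer_connectivity(bad), "XX")
})

test_that("explicit bond records override inference", {
  atoms <- make_atoms(list("C1", "C", 0, 0, 0), list("C2", "C", 1.5, 0, 0),
                      list("C3", "C", 3.0, 0, 0))
  explicit <- matrix(c(1L, 3L), ncol = 2)
  p <- new_pose(atoms, bonds = explicit)
  expect_equal(infer_connectivity(p), explicit)
})

test_that("hydroxyl detection matches brute-force neighbor enumeration", {
  for (template in c("aap-like", "e2-like", "diol-like", "carboxyl-like")) {
    atoms <- ugtcap:::.template_atoms(template)
    pose <- new_pose(atoms)
    expect_equal(find_hydroxyl_oxygens(pose), oracle_hydroxyls(atoms),
                 info = template)
  }
  # sanity on the expected counts: one phenolic OH in the acetaminophen-like
  # molecule (its amide O must not count), two in the estradiol-like one
  expect_length(find_hydroxyl_oxygens(new_pose(ugtcap:::.template_atoms("aap-like"))), 1)
  expect_length(find_hydroxyl_oxygens(new_pose(ugtcap:::.template_atoms("e2-like"))), 2)
})

test_that("ether oxygens never qualify as hydroxyls", {
  # dimethyl-ether-like: O bonded to two carbons
  ether <- new_pose(make_atoms(list("C1", "C", -1.42, 0, 0),
                               list("O1", "O", 0, 0, 0),
                               list("C2", "C", 1.42, 0, 0),
                               list("H1", "H", -1.9, 0.9, 0)))
  expect_length(find_hydroxyl_oxygens(ether), 0)
})

test_that("hydrogen-free poses fall back to the heavy-atom hydroxyl rule", {
  # phenol with hydrogens stripped: the O has one C neighbor and qualifies
  atoms <- ugtcap:::.template_atoms("aap-like")
  heavy <- atoms[toupper(atoms$element) != "H", ]
  found <- find_hydroxyl_oxygens(new_pose(heavy))
  expect_equal(found, oracle_hydroxyls(heavy))
  # without hydrogens the amide O also matches the degraded criterion
  expect_length(found, 2)
})

test_that("glycosidic midpoint is the mean of the bridging C-O bond", {
  toy <- new_pose(make_atoms(list("C1", "C", 0, 0, 0),
                             list("O1", "O", 1, 0, 0),
                             list("P1", "P", 2, 0, 0),
                             list("O5", "O", -0.7, 1.2, 0)))
  ref <- locate_glycosidic_midpoint(toy)
  expect_equal(ref$midpoint, c(0.5, 0, 0))
  expect_equal(toy$atoms$name[ref$oxygen_index], "O1")
  expect_equal(toy$atoms$name[ref$carbon_index], "C1")

  no_p <- new_pose(make_atoms(list("C1", "C", 0, 0, 0),
                              list("O1", "O", 1, 0, 0),
                              list("O5", "O", -0.7, 1.2, 0)))
  expect_error(locate_glycosidic_midpoint(no_p), "0")

  two <- new_pose(rbind(toy$atoms,
                        within(toy$atoms, x <- x + 10)))
  expect_error(locate_glycosidic_midpoint(two), "2")
})

test_that("orientation classification uses the oxygen with inclusive cutoff", {
  methanol_at <- function(d) {
    new_pose(make_atoms(list("O1", "O", d, 0, 0),
                        list("C1", "C", d + 1.42, 0, 0),
                        list("HO1", "H", d + 0.25, 0.93, 0)))
  }
  ref <- midpoint_reference(c(0, 0, 0))
  expect_true(classify_hydroxyl_orientation(methanol_at(3.70), ref, cutoff = 3.8))
  expect_false(classify_hydroxyl_orientation(methanol_at(3.90), ref, cutoff = 3.8))
  expect_true(classify_hydroxyl_orientation(methanol_at(3.80), ref, cutoff = 3.8))

  no_oh <- new_pose(make_atoms(list("C1", "C", 0, 0, 0),
                               list("C2", "C", 1.5, 0, 0)))
  expect_error(classify_hydroxyl_orientation(no_oh, ref),
               "no conjugatable hydroxyl")
})

test_that("count_orientations equals the planted labels and brute force", {
  dir <- withr::local_tempdir()
  fx <- generate_pose_fixture(
    pose_fixture_spec(n_poses = 100, frac_oriented = 0.3, seed = 11), dir)
  poses <- read_poses(fx$paths$substrate)
  ref <- locate_glycosidic_midpoint(read_poses(fx$paths$udpga)$poses[[1]])
  counts <- count_orientations(poses, ref, cutoff = 3.8)
  expect_equal(counts$S_DT, 100)
  expect_equal(counts$S_DH, 30)
  expect_equal(counts$per_pose$oriented, fx$labels$oriented)
  # independent brute-force distances
  brute <- vapply(poses$poses, function(p) {
    oracle_min_hydroxyl_dist(p$atoms, ref$midpoint)
  }, numeric(1))
  expect_equal(counts$per_pose$min_hydroxyl_distance_A, brute, tolerance = 1e-9)
  expect_equal(counts$per_pose$oriented, as.integer(brute <= 3.8))
})

test_that("degenerate orientation fractions count correctly", {
  dir <- withr::local_tempdir()
  fx0 <- generate_pose_fixture(
    pose_fixture_spec(n_poses = 8, frac_oriented = 0, seed = 12), dir)
  poses <- read_poses(fx0$paths$substrate)
  ref <- locate_glycosidic_midpoint(
    read_poses(fx0$paths$udpga)$poses[[1]])
  c0 <- count_orientations(poses, ref)
  expect_equal(c0$S_DH, 0)
  expect_equal(c0$S_DT, 8)

  fx1 <- generate_pose_fixture(
    pose_fixture_spec(n_poses = 1, frac_oriented = 1, seed = 13),
    withr::local_tempdir())
  p1 <- read_poses(fx1$paths$substrate)
  c1 <- count_orientations(p1, ref)
  expect_equal(c(c1$S_DH, c1$S_DT), c(1, 1))
})

test_that("oriented count is monotone non-decreasing in the cutoff", {
  fx <- generate_pose_fixture(
    pose_fixture_spec(n_poses = 40, frac_oriented = 0.5, seed = 14),
    withr::local_tempdir())
  poses <- read_poses(fx$paths$substrate)
  ref <- locate_glycosidic_midpoint(read_poses(fx$paths$udpga)$poses[[1]])
  counts <- vapply(seq(1, 9, by = 0.5), function(cut) {
    count_orientations(poses, ref, cutoff = cut)$S_DH
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("classification is invariant under rigid motion", {
  fx <- generate_pose_fixture(
    pose_fixture_spec(n_poses = 25, frac_oriented = 0.4, seed = 15,
                      substrate_template = "e2-like"),
    withr::local_tempdir())
  poses <- read_poses(fx$paths$substrate)
  udpga <- read_poses(fx$paths$udpga)$poses[[1]]
  rec <- read_receptor(fx$paths$receptor)
  ref <- locate_glycosidic_midpoint(udpga)
  rot <- oracle_rotation()
  shift <- c(12.3, -4.5, 7.8)

  before <- count_orientations(poses, ref)
  after <- count_orientations(
    transform_rigid(poses, rot, shift),
    transform_rigid(ref, rot, shift))
  expect_equal(after$per_pose$oriented, before$per_pose$oriented)
  expect_equal(after$per_pose$min_hydroxyl_distance_A,
               before$per_pose$min_hydroxyl_distance_A, tolerance = 1e-6)

  cb_before <- classify_udpga_binding(udpga, rec)
  cb_after <- classify_udpga_binding(transform_rigid(udpga, rot, shift),
                                     transform_rigid(rec, rot, shift))
  expect_equal(cb_after$is_correct, cb_before$is_correct)
  expect_equal(cb_after$n_contacted, cb_before$n_contacted)
})

test_that("coenzyme binding-mode quorum counts contacted residues", {
  fx <- generate_pose_fixture(pose_fixture_spec(n_poses = 1, seed = 16),
                              withr::local_tempdir())
  rec <- read_receptor(fx$paths$receptor)
  udpga <- read_poses(fx$paths$udpga)$poses[[1]]

  near <- classify_udpga_binding(udpga, rec)
  expect_true(near$is_correct)
  expect_equal(near$n_contacted, 7)

  far <- classify_udpga_binding(transform_rigid(udpga, translation = c(60, 0, 0)),
                                rec)
  expect_false(far$is_correct)
  expect_equal(far$n_contacted, 0)
})

test_that("partial contact below the quorum is not the correct mode", {
  # seven single-residue stubs: four within 3 A of the ligand carbon,
  # three at 6 A
  resnos <- udpga_site_residues()$resno
  d <- c(3, 3, 3, 3, 6, 6, 6)
  atoms <- do.call(rbind, lapply(seq_along(resnos), function(k) {
    data.frame(serial = k, name = "CA", altloc = "", element = "C",
               resname = udpga_site_residues()$expected[k], chain = "A",
               resno = resnos[k], insert = "",
               x = d[k] * cos(2 * pi * k / 7), y = d[k] * sin(2 * pi * k / 7),
               z = 0, stringsAsFactors = FALSE)
  }))
  rec <- new_receptor(atoms)
  lig <- new_pose(make_atoms(list("C1", "C", 0, 0, 0)))
  res <- classify_udpga_binding(lig, rec,
                                binding_site_spec(contact_cutoff = 3.8,
                                                  min_contacts = 5))
  expect_false(res$is_correct)
  expect_equal(res$n_contacted, 4)
})

test_that("site residue errors and mutation warnings behave as specified", {
  atoms <- data.frame(serial = 1, name = "CA", altloc = "", element = "C",
                      resname = "ARG", chain = "A", resno = 376L, insert = "",
                      x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  rec <- new_receptor(atoms)
  lig <- new_pose(make_atoms(list("C1", "C", 1, 0, 0)))
  spec_376 <- binding_site_spec(
    residues = data.frame(resno = 376L, expected = "HIS"),
    min_contacts = 1)
  # H376R-style mutation: warns, still counts the contact
  expect_warning(res <- classify_udpga_binding(lig, rec, spec_376), "376")
  expect_true(res$is_correct)

  spec_38 <- binding_site_spec(
    residues = data.frame(resno = 38L, expected = "SER"), min_contacts = 1)
  expect_error(classify_udpga_binding(lig, rec, spec_38), "38")
})
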