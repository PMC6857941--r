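#!/usr/bin/env Rscript
# Step 2: classify the docking poses of step 1.
#
# Locates the glycosidic C-O bond midpoint of the coenzyme pose, measures
# every substrate pose's minimum hydroxyl-oxygen distance to it, applies
# the 3.8 A orientation criterion (3.2 A H-bond + 0.6 A docking error),
# checks the coenzyme's own binding mode against the seven pocket residues,
# and compares the result with the fixture's planted labels.

suppressMessages(library(ugtcap))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 20260925L

poses <- read_poses("results/pose_fixture/substrate_poses.pdbqt")
udpga <- read_poses("results/pose_fixture/udpga_poses.pdbqt")$poses[[1]]
receptor <- read_receptor("results/pose_fixture/receptor.pdb")
labels <- utils::read.csv("results/pose_fixture/labels.csv",
                          comment.char = "#")

ref <- locate_glycosidic_midpoint(udpga)
cat(sprintf("glycosidic midpoint: (%.3f, %.3f, %.3f) A\n",
            ref$midpoint[1], ref$midpoint[2], ref$midpoint[3]))

binding <- classify_udpga_binding(udpga, receptor)
cat(sprintf("coenzyme binding mode: %s (%d of 7 site residues contacted)\n",
            if (binding$is_correct) "correct" else "incorrect",
            binding$n_contacted))

counts <- count_orientations(poses, ref)
cat(sprintf("hydroxyl orientations: S_DH = %d of S_DT = %d poses\n",
            counts$S_DH, counts$S_DT))
agree <- mean(counts$per_pose$oriented == labels$oriented)
cat(sprintf("agreement with planted labels: %.1f%%\n", 100 * agree))

write_classification_csv(counts, poses$ligand_id,
                         "results/pose_classification.csv", seed = seed)
cat("wrote results/pose_classification.csv\n")
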