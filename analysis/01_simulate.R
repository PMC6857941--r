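#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs.
#
# Two kinds of ground-truth data stand in for the docking campaign this
# pipeline post-processes: (a) a pose fixture — 100 docked substrate
# conformations around a coenzyme whose glycosidic C-O midpoint is known,
# with the oriented/non-oriented label of every pose planted by
# construction; (b) a 20-variant panel whose in vitro capacities follow the
# sigmoid capacity model (sigma 50, gamma 8, mu 0.4, beta 2.5) with 5%
# assay noise.

suppressMessages(library(ugtcap))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 20260925L

dir.create("results", showWarnings = FALSE)

fx <- generate_pose_fixture(
  pose_fixture_spec(n_poses = 100, frac_oriented = 0.3,
                    substrate_template = "aap-like", seed = seed),
  dir = "results/pose_fixture")
cat(sprintf("pose fixture: %d poses, %d planted oriented -> %s\n",
            nrow(fx$labels), sum(fx$labels$oriented),
            dirname(fx$paths$substrate)))

gen <- generate_variant_panel(
  panel_spec(n_variants = 20, S_DT = 100, seed = seed),
  dir = "results/panel")
cat(sprintf("variant panel: wild + %d mutants, noise sd %.3g (capacity units)\n",
            nrow(gen$panel$members), gen$truth$noise_sd))
cat(sprintf("  generating constants: sigma=%g gamma=%g mu=%g beta=%g\n",
            gen$truth$params$sigma, gen$truth$params$gamma,
            gen$truth$params$mu, gen$truth$beta_realized))
cat("wrote results/pose_fixture/ and results/panel/\n")
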