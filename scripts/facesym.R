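#!/usr/bin/env Rscript

# Thin command-line wrapper over the facesym package.
#
#   Rscript scripts/facesym.R simulate --out DIR [--m 1000] [--seed 1]
#       write a synthetic cohort: PLY meshes, landmark files, cohort CSV
#   Rscript scripts/facesym.R study --out DIR [--seed 1] [--reps 200]
#       run the full pipeline end-to-end and write every tabular artifact

suppressPackageStartupMessages(library(facesym))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) == 0) stop("usage: facesym.R <simulate|study> --out DIR ...")
cmd <- args[1]
get_arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
out_dir <- get_arg("--out", "facesym_out")
seed <- as.integer(get_arg("--seed", "1"))
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

if (cmd == "simulate") {
  m <- as.integer(get_arg("--m", "1000"))
  sim <- simulate_faces(face_sim_config(M = m, seed = seed))
  mesh_dir <- file.path(out_dir, "meshes")
  dir.create(mesh_dir, showWarnings = FALSE)
  for (f in sim$faces) {
    write_face(f, file.path(mesh_dir, paste0(f$subject_id, ".ply")),
               file.path(mesh_dir, paste0(f$subject_id, ".landmarks.txt")))
  }
  write_face(sim$template, file.path(out_dir, "template.ply"),
             file.path(out_dir, "template.landmarks.txt"))
  utils::write.csv(sim$cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(list(M = m, seed = seed, n = nrow(sim$cohort)),
                       file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  message("Wrote ", nrow(sim$cohort), " faces to ", out_dir)
} else if (cmd == "study") {
  reps <- as.integer(get_arg("--reps", "200"))
  study <- run_study(face_cfg = face_sim_config(seed = seed),
                     lasso_reps = reps, out_dir = out_dir)
  print(study)
  message("Artifacts in ", out_dir)
} else {
  stop("unknown subcommand '", cmd, "' (expected simulate or study)")
}
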