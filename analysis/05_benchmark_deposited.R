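#!/usr/bin/env Rscript
# Optional benchmark against a deposited patient cohort (requires a download;
# it cannot run offline). Given the RDS list of marked point patterns
# (spatstat ppp format, marks Phenotype and Tissue.Category, coordinates in
# micrometers) and an outcome table, this converts the record to per-patient
# CSVs and recomputes the headline cohort means: B-in-islands density,
# stromal-B FD difference, heterotypic LCs per cm^2, mean heterotypic
# LC-island distance, and overall B density.
#
# Usage:
#   Rscript analysis/05_benchmark_deposited.R <PatientPointPatterns.rds> \
#       <outcomes.csv> [out_dir]
# where outcomes.csv has columns patient_id, outcome (good/poor),
# rfs_months, event.

suppressPackageStartupMessages(library(tilspatial))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 2)
  stop("usage: Rscript analysis/05_benchmark_deposited.R <rds> <outcomes.csv> [out_dir]")
rds <- args[1]
outcomes_csv <- args[2]
out_dir <- if (length(args) >= 3) args[3] else file.path("results", "deposited")

outcomes <- read.csv(outcomes_csv)
csv_dir <- file.path(out_dir, "csv")
paths <- read_deposited_patterns(rds, csv_dir)
cat(sprintf("converted %d patterns to %s\n", length(paths), csv_dir))

bm <- benchmark_deposited(csv_dir, outcomes_csv,
                          out_dir = file.path(out_dir, "run"))
for (k in names(bm)) cat(sprintf("%-42s %.4g\n", k, bm[[k]]))
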