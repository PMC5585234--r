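#!/usr/bin/env Rscript
# Stage 2 — filter occurrences and grid them into proportional assemblages.
#
# Applies the standard reef-coral filters (depth <= 60 m, zooxanthellate
# only), bins records into 1-degree cells as count-based proportions,
# excludes single-genus cells, restricts modern and fossil matrices to
# their shared taxon pool, and pairs the modern cells with the observed
# climatology. Run stage 01 first.

library(coralclim)

world_dir <- file.path("results", "world")
out_dir <- file.path("results", "assemblages")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

modern_occ <- read_occurrences(file.path(world_dir, "modern_occurrences.csv"))
fossil_occ <- read_occurrences(file.path(world_dir, "fossil_occurrences.csv"))
field <- read_field(file.path(world_dir, "modern_field.csv"))

modern_f <- filter_records(modern_occ)
fossil_f <- filter_records(fossil_occ)
cat(sprintf("Filters: modern %d -> %d records, fossil %d -> %d.\n",
            nrow(modern_occ), nrow(modern_f),
            nrow(fossil_occ), nrow(fossil_f)))

for (rank in c("species", "genus")) {
  modern <- apply_cell_filters(build_matrix(modern_f, rank), min_genera = 2)
  fossil <- apply_cell_filters(build_matrix(fossil_f, rank), min_genera = 2)
  harm <- harmonize_taxa(modern, fossil, min_genera = 2)
  write_assemblage(harm$modern, file.path(out_dir, paste0("modern_", rank, ".csv")))
  write_assemblage(harm$fossil, file.path(out_dir, paste0("fossil_", rank, ".csv")))
  cat(sprintf(
    "%s rank: %d shared taxa; %d modern and %d fossil cells after filters.\n",
    rank, length(harm$modern$taxa), nrow(harm$modern$props),
    nrow(harm$fossil$props)))
}

# calibration table for the species rank (the primary analysis level)
modern_sp <- read_assemblage(file.path(out_dir, "modern_species.csv"))
cal <- pair_cells(modern_sp, field)
calib <- cbind(cal$cells, mean_sst = cal$mean_sst, stv = cal$stv,
               as.data.frame(cal$props))
write.csv(calib, file.path(out_dir, "calibration_species.csv"),
          row.names = FALSE)
cat(sprintf("Calibration table: %d cells, SST %.1f-%.1f C, STV %.1f-%.1f C.\n",
            nrow(cal$props), min(cal$mean_sst), max(cal$mean_sst),
            min(cal$stv), max(cal$stv)))
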