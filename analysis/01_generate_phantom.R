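#!/usr/bin/env Rscript
# Generate the default validation phantom: a desk-scale synthetic nano-CT
# bone volume with two remodeling regions separated by a wavy
# hyper-mineralized cement line, lacunae, canaliculi (crossing, looping and
# intra-region) and Gaussian image noise. Writes the volume and its ground
# truth for inspection, plus a summary table.

suppressMessages({library(optparse); library(olcn)})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L))))

ph <- default_validation_phantom(opts$seed)
tr <- ph$truth

message(sprintf("Phantom: %s voxels at %.0f nm; GV range [%g, %g]",
                paste(dim(ph$volume$data), collapse = " x "),
                ph$volume$voxel_size_nm,
                min(ph$volume$data), max(ph$volume$data)))
message(sprintf("Ground truth: %d lacunae above the 1500-voxel filter, %d below",
                sum(tr$lacuna_info$above_size_filter),
                sum(!tr$lacuna_info$above_size_filter)))
message(sprintf("Analytic 3D canal porosity young/old: %.4f / %.4f",
                tr$analytic_region_porosity[1],
                tr$analytic_region_porosity[2]))
cc <- tr$true_crossing_counts
message("Crossing canaliculi within 25 um per lacuna: ",
        paste(cc$n_within[cc$n_within > 0 | cc$lacuna_id <= 4],
              collapse = ", "))

dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)
write_volume(ph$volume, "scratch/phantom_volume.tif",
             extra_meta = list(seed = opts$seed))
write_volume(volume(tr$region_labels, ph$volume$voxel_size_nm),
             "scratch/phantom_region_labels.tif")
write_volume(volume(tr$lacuna_labels, ph$volume$voxel_size_nm),
             "scratch/phantom_lacuna_labels.tif")
summary_df <- data.frame(
  seed = opts$seed,
  n_lacunae = sum(tr$lacuna_info$above_size_filter),
  n_noise_blobs = sum(!tr$lacuna_info$above_size_filter),
  n_crossing_canaliculi = sum(cc$n_within + cc$n_beyond),
  porosity_young_3d = tr$analytic_region_porosity[1],
  porosity_old_3d = tr$analytic_region_porosity[2])
write.csv(summary_df, "results/phantom_summary.csv", row.names = FALSE)
message("Wrote scratch/phantom_*.tif and results/phantom_summary.csv")
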