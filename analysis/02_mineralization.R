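#!/usr/bin/env Rscript
# Regional degree of mineralization on the default phantom: interpolate the
# regional mask from sparse slice labels, build the low-intensity (B) and
# lacunar (C) masks, compute normalized mean gray values and rank regions
# by relative tissue age (1 = youngest).

suppressMessages({library(optparse); library(olcn)})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L))))

res <- run_pipeline(default_phantom_config(seed = opts$seed))
st <- res$region_stats

message("Regional mask: ", res$masks$provenance,
        "; gray-value check passed: ", res$gv_check$pass)
message(sprintf("Lacunar segmentation: %d lacunae (sizes %s voxels)",
                res$lacunae$n, paste(res$lacunae$sizes, collapse = ", ")))
for (i in seq_len(nrow(st)))
  message(sprintf(
    "Region %d: mineral GV %.1f, lacunar GV %.1f, normalized %.3f -> rank %d",
    st$region_id[i], st$mean_gv_mineral[i], st$mean_gv_lacunar[i],
    st$norm_mean_gv[i], st$rank[i]))
message("The lowest normalized mean GV is the youngest tissue, as mineral ",
        "density increases with local tissue age.")

dir.create("results", showWarnings = FALSE)
write.csv(cbind(seed = opts$seed, st),
          "results/mineralization_regions.csv", row.names = FALSE)
message("Wrote results/mineralization_regions.csv")
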