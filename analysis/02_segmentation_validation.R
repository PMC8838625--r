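#!/usr/bin/env Rscript
# Stage 2: validate the histogram-valley segmentation against phantom truth.
#
# A bubble phantom with pores resolved well above the blur scale is
# rendered at CT-like contrast (solid 180 / void 60) over a range of noise
# levels; the valley threshold is compared with the known mask. The
# low-contrast consensus fallback is exercised on a coarse sintered
# phantom at modes 100/140.

library(voidnet)
dir.create("results", showWarnings = FALSE)

tr <- gen_bubbles(phantom_spec("bubbles", dims = c(64, 64, 64),
                               voxel_size_um = 16, seed = 301,
                               radius_params = list(radius_um = 160,
                                                    count = 8)))
rows <- list()
for (nsd in c(0, 5, 10, 15)) {
  g <- render_grayscale(tr, solid_mode = 180, void_mode = 60,
                        noise_sd = nsd, blur_sigma_vox = if (nsd) 1 else 0,
                        seed = 302)
  seg <- histogram_valley_threshold(g)
  rows[[length(rows) + 1]] <- data.frame(
    phantom = "bubbles", contrast = "180/60", noise_sd = nsd,
    method = "valley", threshold = seg$threshold,
    misclassified_pct = 100 * mean(seg$binary$mask != tr$binary$mask))
}

trs <- gen_sintered(phantom_spec("sintered", dims = c(64, 64, 64),
                                 voxel_size_um = 16, seed = 303,
                                 blob_params = list(corr_length_vox = 8,
                                                    field = "excursion",
                                                    largest_component_only
                                                    = FALSE),
                                 target_void_fraction = 0.3))
gl <- render_grayscale(trs, solid_mode = 140, void_mode = 100,
                       noise_sd = 12, blur_sigma_vox = 0.5, seed = 304)
cs <- consensus_threshold(gl)
rows[[length(rows) + 1]] <- data.frame(
  phantom = "sintered", contrast = "140/100", noise_sd = 12,
  method = "consensus", threshold = cs$threshold,
  misclassified_pct = 100 * mean(cs$binary$mask != trs$binary$mask))

tab <- do.call(rbind, rows)
write.table(tab, "results/02_segmentation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Segmentation validation:\n")
print(tab, row.names = FALSE, digits = 4)
cat("Noise-free rendering recovers the truth mask",
    if (tab$misclassified_pct[1] == 0) "exactly" else "inexactly", "\n")
cat("Table written to results/02_segmentation.tsv\n")
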