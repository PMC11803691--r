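#!/usr/bin/env Rscript

# Compute placental volume, morphology score, maximum thickness and GLCM
# texture from the phantom masks and the fitted T2* map.

suppressPackageStartupMessages(library(placentaflow))

ind_ph <- "results/phantom"
ind_fit <- "results/relaxometry"
out <- "results/morphometrics"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fit <- read_scalar_map(file.path(ind_fit, "t2star_fit.nii.gz"))
pm <- read_mask(file.path(ind_ph, "placenta_mask.nii.gz"), fit$geometry,
                "placenta")

mm <- morphology_metrics(pm)
write_scalar_map(mm$distance_map, file.path(out, "distance_map.nii.gz"))

res <- data.frame(
  volume_mm3 = mm$volume_mm3,
  morphology_score = mm$morphology_score,
  max_thickness_mm = mm$max_thickness_mm,
  texture = placental_texture(fit, pm))
write.csv(res, file.path(out, "placenta_metrics.csv"), row.names = FALSE)
print(res)
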