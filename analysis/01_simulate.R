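#!/usr/bin/env Rscript

# Stage 1 — simulate the study cohort.
#
# Plans the synthetic claw-XRD cohort at the study's conditions (265 dogs,
# 104 with cancer, ~4 claw shavings each with occasional dropout, a 15%
# chance that a cancer patient's shaving is structurally unaffected) and
# writes the manifest plus a handful of example frames. Frames themselves
# are rendered on demand by later stages, so this stage stays light.

suppressPackageStartupMessages(library(clawxrd))

out <- "results/run"
dir.create(file.path(out, "examples"), recursive = TRUE, showWarnings = FALSE)

geom <- detector_geometry()
print(geom)

spec <- cohort_spec()  # 265 patients, prevalence 104/265, seed fixed
plan <- plan_cohort(spec, default_structures(), geom)
m <- plan$manifest

pat <- unique(m[, c("patient_id", "label")])
cat(sprintf("cohort: %d samples from %d patients (%d cancer / %d without)\n",
            nrow(m), nrow(pat), sum(pat$label == "cancer"),
            sum(pat$label == "no_cancer")))
cat(sprintf("samples per patient: %s\n",
            paste(names(table(table(m$patient_id))),
                  table(table(m$patient_id)), sep = "x", collapse = ", ")))
cat(sprintf("raw integrals span %.1f-%.1f mln counts\n",
            min(m$total_counts) / 1e6, max(m$total_counts) / 1e6))

write_manifest(m[, c("sample_id", "patient_id", "label", "batch_id", "path")],
               file.path(out, "manifest.csv"))

# example frames: one per class, plus the AgBH calibration frame of batch 1
i_nc <- which(m$label == "no_cancer")[1]
i_ca <- which(m$label == "cancer" & !m$unaffected)[1]
write_image(render_cohort_sample(plan, i_nc),
            file.path(out, "examples", "example_no_cancer.txt"))
write_image(render_cohort_sample(plan, i_ca),
            file.path(out, "examples", "example_cancer.txt"))
write_image(render_cohort_agbh(plan, "B01"),
            file.path(out, "examples", "example_agbh.txt"))
cat("wrote manifest and example frames under", out, "\n")
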