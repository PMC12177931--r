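#!/usr/bin/env Rscript
# Stage 2: generate synthetic patternoid cohorts for the three EMT
# subtypes, extract the five invasive parameters from every binary mask,
# and compare subtypes with pooled-variance t-tests. Writes per-patternoid
# metrics, a subtype summary, and replicate heatmaps.

suppressMessages(library(patternoid))
dir.create("results", showWarnings = FALSE)

n_per_subtype <- 60   # desk-scale cohort; acceptance uses 200
profs <- subtype_profiles()

all <- list()
for (pn in names(profs)) {
  co <- measure_cohort(profs[[pn]], n_per_subtype,
                       seed = 500 + match(pn, names(profs)))
  co$subtype <- pn
  all[[pn]] <- co
  cat(sprintf(
    "%-10s roots %.2f  tips %.2f  BF %.2f  max dist %.1f um  inv area %.0f um^2\n",
    pn, mean(co$roots), mean(co$tips),
    mean(co$branching_factor, na.rm = TRUE),
    mean(co$max_invasive_distance_um[co$roots > 0]),
    mean(co$invasive_area_um2)))
}
metrics <- do.call(rbind, all)
write.csv(metrics, "results/subtype_metrics.csv", row.names = FALSE)

# subtype contrasts (unpaired two-tailed equal-variance t-tests)
bf_m <- metrics$branching_factor[metrics$subtype == "M-16992"]
bf_e <- metrics$branching_factor[metrics$subtype == "E-9591"]
tt <- compare_groups(bf_m[!is.na(bf_m)], bf_e[!is.na(bf_e)])
cat(sprintf("Branching factor M vs E: t = %.2f, p = %.2g (%s)\n",
            tt$t, tt$p_value,
            ifelse(tt$significant, "significant", "n.s.")))

# replicate heatmap per subtype on a common canvas
for (pn in names(profs)) {
  masks <- lapply(1:12, function(i) {
    sim <- generate_patternoid_mask(profs[[pn]],
                                    seed = 9000 + i +
                                      1000 * match(pn, names(profs)))
    m <- sim$mask$pixels
    # center-pad to a fixed 1400x1400 canvas for alignment
    out <- matrix(FALSE, 1400, 1400)
    off <- (1400 - nrow(m)) %/% 2
    out[off + seq_len(nrow(m)), off + seq_len(ncol(m))] <- m
    out
  })
  hm <- build_heatmap(masks)
  tiff::writeTIFF(hm$counts / hm$n_replicates,
                  sprintf("results/heatmap_%s.tif", pn))
  cat(sprintf("heatmap %s: %d replicates, max overlap %d\n",
              pn, hm$n_replicates, max(hm$counts)))
}
cat("wrote results/subtype_metrics.csv and results/heatmap_*.tif\n")
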