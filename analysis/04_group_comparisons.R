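#!/usr/bin/env Rscript
# Step 4 -- Group comparisons on the synthetic cohort.
#
# Exercises the test battery the way the indices are analyzed in practice:
# repeated-measures one-way ANOVA with Scheffe post hoc on per-animal
# window-mean TOI across doses, the Friedman test with Steel-Dwass post hoc
# on the oximetry indices across doses, and the Wilcoxon signed-rank test
# between conditions. (With raw animal data unavailable, these p values
# characterize the synthetic cohort, not the published one.)

suppressPackageStartupMessages(library(cordox))

rec <- read_recordings("results/synthetic_recordings.csv")
indices <- utils::read.csv("results/oximetry_indices.csv")

# per-animal window-mean thoracic TOI across SNP doses at baseline
sub <- rec[rec$condition == "baseline" & rec$drug == "SNP", ]
key <- interaction(sub$animal_id, sub$dose_ug_kg_min)
means <- tapply(sub$toi_thoracic_pct, key, mean)
animals <- sort(unique(sub$animal_id))
doses <- sort(unique(sub$dose_ug_kg_min))
m <- matrix(means[paste(rep(animals, length(doses)),
                        rep(doses, each = length(animals)), sep = ".")],
            nrow = length(animals),
            dimnames = list(animals, paste0("dose_", doses)))
message("Thoracic TOI across SNP doses (baseline): rm-ANOVA")
print(rm_anova_oneway(m))
sp <- scheffe_posthoc(m)
message("Scheffe post hoc: ", sum(sp$significant), " of ", nrow(sp),
        " pairs significant at 0.05")
utils::write.csv(sp, "results/scheffe_thoracic_snp.csv", row.names = FALSE)

# T-SOx across SNP doses at baseline: Friedman + Steel-Dwass
idx <- indices[indices$condition == "baseline" & indices$drug == "SNP" &
                 indices$site == "thoracic" & indices$dose_ug_kg_min > 0, ]
im <- matrix(NA_real_, nrow = length(animals), ncol = 4,
             dimnames = list(animals, paste0("dose_", c(0.5, 1, 2, 5))))
for (i in seq_len(nrow(idx)))
  im[idx$animal_id[i], paste0("dose_", idx$dose_ug_kg_min[i])] <- idx$rho[i]
message("T-SOx across SNP doses (baseline): Friedman test")
print(friedman_test(im))
sd_res <- steel_dwass_posthoc(im)
message("Steel-Dwass post hoc: ", sum(sd_res$significant), " of ",
        nrow(sd_res), " pairs significant at 0.05")
utils::write.csv(sd_res, "results/steel_dwass_tsox_snp.csv", row.names = FALSE)

# cerebral TOI, baseline vs hypovolemia at dose 0 (phenylephrine arm):
# paired Wilcoxon signed-rank across animals
base0 <- rec[rec$condition == "baseline" & rec$drug == "phenylephrine" &
               rec$dose_ug_kg_min == 0, ]
hypo0 <- rec[rec$condition == "hypovolemia" & rec$drug == "phenylephrine" &
               rec$dose_ug_kg_min == 0, ]
b <- tapply(base0$toi_cerebral_pct, base0$animal_id, mean)[animals]
h <- tapply(hypo0$toi_cerebral_pct, hypo0$animal_id, mean)[animals]
message("Cerebral TOI, baseline vs hypovolemia (pre-infusion): Wilcoxon")
wt <- wilcoxon_signed_rank(b, h)
print(wt)
utils::write.csv(data.frame(test = "wilcoxon_cerebral_bleed",
                            statistic = wt$statistic, n = wt$df,
                            p_value = wt$p_value),
                 "results/wilcoxon_bleed.csv", row.names = FALSE)
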