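#!/usr/bin/env Rscript
# Step 3 -- Dose-response relationships.
#
# Works on the published per-dose means (the reference envelope shipped
# with the package): fits the MAP-TOI regression of every arm x site,
# computes the pre-infusion-referenced percent changes, and quantifies the
# vertical shift of each relationship after the 600-ml bleed. Also
# summarizes the synthetic cohort the same way for comparison.

suppressPackageStartupMessages(library(cordox))

dir.create("results", showWarnings = FALSE)
arms <- protocol_arms(protocol_spec())
sites <- c("cerebral", "thoracic", "lumbar")

fits <- do.call(rbind, lapply(seq_len(nrow(arms)), function(j) {
  do.call(rbind, lapply(sites, function(s) {
    f <- fit_map_toi_regression(
      reference_arm_points(arms$condition[j], arms$drug[j], s))
    data.frame(condition = arms$condition[j], drug = arms$drug[j], site = s,
               slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared, n_points = f$n_points)
  }))
}))
message("MAP-TOI regressions on reference per-dose means:")
print(cbind(fits[1:3], round(fits[4:6], 3)))
utils::write.csv(fits, "results/map_toi_fits_reference.csv", row.names = FALSE)

ref <- reference_dose_response()
cell <- function(cond, drug, dose, var)
  ref[[paste0(var, "_mean")]][ref$condition == cond & ref$drug == drug &
                                ref$dose_ug_kg_min == dose]
changes <- do.call(rbind, lapply(seq_len(nrow(arms)), function(j) {
  do.call(rbind, lapply(sites, function(s) {
    v <- paste0("toi_", s)
    p <- percent_change(cell(arms$condition[j], arms$drug[j], 0, v),
                        cell(arms$condition[j], arms$drug[j], 5, v))
    data.frame(condition = arms$condition[j], drug = arms$drug[j], site = s,
               comparison = "dose 0 -> 5", pct = p$pct,
               rounded_pct = p$rounded_pct, direction = p$direction)
  }))
}))
bleed <- do.call(rbind, lapply(sites, function(s) {
  v <- paste0("toi_", s)
  p <- percent_change(cell("baseline", "phenylephrine", 0, v),
                      cell("hypovolemia", "phenylephrine", 0, v))
  data.frame(condition = "hypovolemia vs baseline", drug = "phenylephrine",
             site = s, comparison = "600-ml bleed, dose 0", pct = p$pct,
             rounded_pct = p$rounded_pct, direction = p$direction)
}))
changes <- rbind(changes, bleed)
message("Percent changes (positive = decrease from reference):")
print(changes[c(1:3, 16:18), ], digits = 3)
utils::write.csv(changes, "results/percent_changes_reference.csv",
                 row.names = FALSE)

shifts <- do.call(rbind, lapply(sites, function(s) {
  fa <- fit_map_toi_regression(
    reference_arm_points("baseline", "phenylephrine", s))
  fb <- fit_map_toi_regression(
    reference_arm_points("hypovolemia", "phenylephrine", s))
  sh <- condition_shift(fa, fb, 70)
  data.frame(site = s, map_eval = 70, delta_toi = sh$delta_toi,
             delta_pct = sh$delta_pct)
}))
message("Bleed-induced downward shift of the MAP-TOI relationship at 70 mmHg:")
print(shifts, digits = 3)
utils::write.csv(shifts, "results/condition_shifts.csv", row.names = FALSE)

if (file.exists("results/synthetic_recordings.csv")) {
  rec <- read_recordings("results/synthetic_recordings.csv")
  sm <- summarize_dose(rec)
  utils::write.csv(sm, "results/dose_summaries_synthetic.csv",
                   row.names = FALSE)
  message("Wrote synthetic cohort dose summaries (mean +/- SD per cell)")
}
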