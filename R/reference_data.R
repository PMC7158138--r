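#' Reference swine dose-response envelope
#'
#' Across-animal group means and SDs of MAP and of cerebral, thoracic and
#' lumbar TOI at each dose step of the five infusion arms, from a published
#' ten-swine stepwise phenylephrine/SNP experiment under baseline,
#' hypovolemic and post-fluid-resuscitation conditions (lumbar values cover
#' the nine animals with an intact lumbar channel). These per-dose means are
#' the worked-example dataset for the MAP-TOI regressions and percent-change
#' statistics, and supply the default MAP targets of the simulator.
#'
#' @param long if `TRUE`, return tidy long format with one row per
#'   (condition, drug, dose, variable); otherwise the wide table as shipped.
#' @return data frame; wide columns are `condition`, `drug`,
#'   `dose_ug_kg_min`, then `<variable>_mean` / `<variable>_sd` for `map`
#'   (mmHg) and `toi_cerebral`, `toi_thoracic`, `toi_lumbar` (%).
#' @examples
#' head(reference_dose_response())
#' @export
reference_dose_response <- function(long = FALSE) {
  path <- system.file("extdata", "swine_dose_response.csv", package = "cordox",
                      mustWork = TRUE)
  wide <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!long) return(wide)
  vars <- c("map", "toi_cerebral", "toi_thoracic", "toi_lumbar")
  out <- do.call(rbind, lapply(vars, function(v) {
    data.frame(condition = wide$condition, drug = wide$drug,
               dose_ug_kg_min = wide$dose_ug_kg_min, variable = v,
               mean = wide[[paste0(v, "_mean")]],
               sd = wide[[paste0(v, "_sd")]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-dose (MAP mean, TOI mean) points for one arm and site
#'
#' Convenience accessor for fitting the MAP-TOI regression of one infusion
#' arm at one site from the reference envelope.
#'
#' @param condition,drug infusion arm.
#' @param site one of `"cerebral"`, `"thoracic"`, `"lumbar"`.
#' @return data frame with columns `dose_ug_kg_min`, `map`, `toi`.
#' @export
reference_arm_points <- function(condition, drug, site) {
  stopifnot(site %in% SITES)
  wide <- reference_dose_response()
  sub <- wide[wide$condition == condition & wide$drug == drug, , drop = FALSE]
  if (nrow(sub) == 0) stop("no reference arm ", condition, " / ", drug)
  sub <- sub[order(sub$dose_ug_kg_min), , drop = FALSE]
  data.frame(dose_ug_kg_min = sub$dose_ug_kg_min, map = sub$map_mean,
             toi = sub[[paste0("toi_", site, "_mean")]])
}
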