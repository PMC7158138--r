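# Dose-response aggregation: across-animal summaries, percent-change
# statistics and MAP-TOI regressions on per-dose means.

#' Across-animal dose summaries (mean +/- SD)
#'
#' Each animal contributes one value per condition x drug x dose cell --
#' the mean of its window samples -- and the summary is the across-animal
#' mean and sample SD (n - 1 denominator) of those values, for MAP and for
#' each recorded site's TOI. Cells with a single animal carry `sd = NA`
#' (flagged undefined rather than zero).
#'
#' @param ds a `cordox_recordings` table.
#' @return data frame with columns `condition`, `drug`, `dose_ug_kg_min`,
#'   `variable` (`"map"` or `"toi_<site>"`), `mean`, `sd`, `n_animals`.
#' @export
summarize_dose <- function(ds) {
  vars <- c(map = "map_mmHg",
            toi_cerebral = "toi_cerebral_pct",
            toi_thoracic = "toi_thoracic_pct",
            toi_lumbar = "toi_lumbar_pct")
  key <- interaction(ds$animal_id, ds$condition, ds$drug, ds$dose_ug_kg_min,
                     drop = TRUE)
  per_animal <- lapply(split(seq_len(nrow(ds)), key), function(idx) {
    sub <- ds[idx, , drop = FALSE]
    row <- data.frame(animal_id = sub$animal_id[1], condition = sub$condition[1],
                      drug = sub$drug[1], dose_ug_kg_min = sub$dose_ug_kg_min[1],
                      stringsAsFactors = FALSE)
    for (v in names(vars)) {
      x <- sub[[vars[[v]]]]
      row[[v]] <- if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }
    row
  })
  pa <- do.call(rbind, per_animal)
  key2 <- interaction(pa$condition, pa$drug, pa$dose_ug_kg_min, drop = TRUE)
  parts <- lapply(split(seq_len(nrow(pa)), key2), function(idx) {
    sub <- pa[idx, , drop = FALSE]
    do.call(rbind, lapply(names(vars), function(v) {
      x <- sub[[v]][!is.na(sub[[v]])]
      data.frame(condition = sub$condition[1], drug = sub$drug[1],
                 dose_ug_kg_min = sub$dose_ug_kg_min[1], variable = v,
                 mean = if (length(x)) mean(x) else NA_real_,
                 sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
                 n_animals = length(x), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, parts)
  out <- out[order(match(out$condition, unique(ds$condition)), out$drug,
                   out$dose_ug_kg_min, match(out$variable, names(vars))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent change relative to a reference value
#'
#' pct = 100 x (reference - comparator) / reference: positive for a
#' decrease from the reference (the usual pre-infusion dose-0 value of the
#' same arm, or the baseline-condition value for between-condition
#' comparisons), negative for an increase. `rounded_pct` applies
#' half-away-from-zero integer rounding ([round_half_away()]), the
#' convention under which the reference worked examples reproduce their
#' printed integers.
#'
#' @param reference reference value (> 0).
#' @param comparator comparison value.
#' @return list with `reference`, `comparator`, `pct`, `direction`
#'   (`"decrease"`/`"increase"`/`"none"`), `rounded_pct`.
#' @examples
#' percent_change(63.9, 60.8)$rounded_pct  # 5 (a 5% decrease)
#' @export
percent_change <- function(reference, comparator) {
  stopifnot(length(reference) == 1, length(comparator) == 1)
  if (!is.finite(reference) || reference <= 0)
    stop("reference must be a positive finite value")
  pct <- 100 * (reference - comparator) / reference
  list(reference = reference, comparator = comparator, pct = pct,
       direction = if (pct > 0) "decrease" else if (pct < 0) "increase" else "none",
       rounded_pct = round_half_away(pct))
}

#' Ordinary least-squares MAP-TOI regression
#'
#' Fits TOI = intercept + slope x MAP by OLS, typically to the five
#' per-dose across-animal mean points of one infusion arm at one site (the
#' dose-response relationship, not the within-window index).
#'
#' @param map,toi numeric vectors; or a data frame with `map` and `toi`
#'   columns passed as `map` (as produced by [reference_arm_points()]).
#' @return object of class `map_toi_fit`: `slope` (TOI % per mmHg),
#'   `intercept` (%), `r_squared`, `n_points`, `x_range`.
#' @examples
#' pts <- reference_arm_points("baseline", "SNP", "thoracic")
#' fit_map_toi_regression(pts)   # slope ~0.19, intercept ~34, R^2 ~0.97
#' @export
fit_map_toi_regression <- function(map, toi = NULL) {
  if (is.data.frame(map)) {
    stopifnot(all(c("map", "toi") %in% names(map)))
    toi <- map$toi; map <- map$map
  }
  stopifnot(length(map) == length(toi))
  ok <- !is.na(map) & !is.na(toi)
  map <- map[ok]; toi <- toi[ok]
  if (length(map) < 2) stop("need at least 2 points to fit")
  if (length(unique(map)) < 2) stop("degenerate fit: all MAP values equal")
  fit <- stats::lm(toi ~ map)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n_points = length(map),
                 x_range = range(map)),
            class = "map_toi_fit")
}

#' Predict TOI from a MAP-TOI fit
#' @param object a `map_toi_fit`.
#' @param newdata MAP values (mmHg).
#' @param ... unused.
#' @return predicted TOI (%).
#' @export
predict.map_toi_fit <- function(object, newdata, ...) {
  object$intercept + object$slope * newdata
}

#' @export
print.map_toi_fit <- function(x, ...) {
  cat(sprintf("MAP-TOI fit: y = %.3f x + %.1f (R^2 = %.3f, n = %d, MAP %g-%g mmHg)\n",
              x$slope, x$intercept, x$r_squared, x$n_points,
              x$x_range[1], x$x_range[2]))
  invisible(x)
}

#' Vertical shift between two dose-response relationships
#'
#' Evaluates two MAP-TOI fits at a common MAP and reports the TOI
#' difference (fit_b minus fit_a) in percentage points and as a percent of
#' fit_a's prediction -- e.g. how far the hypovolemic relationship sits
#' below the baseline one at matched pressure.
#'
#' @param fit_a,fit_b `map_toi_fit` objects (a = reference).
#' @param map_eval MAP at which to compare (mmHg); must lie inside both
#'   fits' MAP ranges unless `allow_extrapolation`.
#' @param allow_extrapolation override the range check.
#' @return list with `map_eval`, `toi_a`, `toi_b`, `delta_toi`, `delta_pct`.
#' @export
condition_shift <- function(fit_a, fit_b, map_eval,
                            allow_extrapolation = FALSE) {
  stopifnot(inherits(fit_a, "map_toi_fit"), inherits(fit_b, "map_toi_fit"))
  inside <- function(f) map_eval >= f$x_range[1] & map_eval <= f$x_range[2]
  if (!allow_extrapolation && (!inside(fit_a) || !inside(fit_b)))
    stop("map_eval ", map_eval, " outside a fit's MAP range; ",
         "set allow_extrapolation = TRUE to override")
  a <- predict(fit_a, map_eval); b <- predict(fit_b, map_eval)
  list(map_eval = map_eval, toi_a = a, toi_b = b,
       delta_toi = b - a, delta_pct = 100 * (b - a) / a)
}
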