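# Windowed oximetry indices.
#
# The autoregulation index of a dose window (COx for the cerebrum, T-SOx /
# L-SOx for the thoracic / lumbar spinal cord) is the Spearman rank
# correlation between the window's paired MAP and TOI samples. An index
# near zero indicates intact autoregulation (oxygenation decoupled from
# pressure), near +1 a pressure-passive response, and strongly negative a
# paradoxical response (oxygenation moving against pressure, attributed to
# arteriolar caliber changes shifting the arterial-to-venous volume ratio).

RESPONSE_STATES <- c("pressure_passive", "intact", "paradoxical", "undefined")

#' Spearman rank correlation with mid-rank ties
#'
#' Pearson correlation of the mid-ranks (average ranks for ties) of the two
#' vectors, computed over complete pairs. Returns `NA` (an explicit
#' undefined marker, not an error) when fewer than 3 complete pairs remain
#' or when either vector has zero variance: a constant TOI is
#' physiologically meaningful but statistically incomputable, and folding
#' it into "intact" would bias the response-pattern counts.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in [-1, 1], or `NA_real_` when undefined.
#' @examples
#' spearman_rho(1:4, c(10, 20, 30, 40))  # 1
#' spearman_rho(1:4, c(2, 1, 4, 3))      # 0.6
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(NA_real_)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  rho <- sum(dx * dy) / sqrt(sx * sy)
  max(-1, min(1, rho))
}

#' Classify a window's response state
#'
#' Threshold scheme on the oximetry index: rho > 0.36 is pressure-passive,
#' rho < -0.36 is paradoxical, anything in between is intact
#' autoregulation. The boundary values +/-0.36 fall to intact (the scheme's
#' strict inequalities leave the closed boundary to the middle state; a
#' measure-zero choice fixed for determinism). `NA` maps to `"undefined"`.
#'
#' @param rho numeric vector of correlations in [-1, 1] (NA allowed).
#' @param threshold classification threshold (default 0.36).
#' @return character vector over
#'   `c("pressure_passive", "intact", "paradoxical", "undefined")`.
#' @examples
#' classify_response(c(0.5, 0, -0.5, 0.36, NA))
#' @export
classify_response <- function(rho, threshold = 0.36) {
  stopifnot(threshold > 0)
  if (any(!is.na(rho) & abs(rho) > 1 + 1e-12))
    stop("rho outside [-1, 1]")
  out <- rep("intact", length(rho))
  out[!is.na(rho) & rho > threshold] <- "pressure_passive"
  out[!is.na(rho) & rho < -threshold] <- "paradoxical"
  out[is.na(rho)] <- "undefined"
  out
}

#' Compute oximetry indices for extracted windows
#'
#' One index per window: the Spearman correlation of the window's MAP and
#' TOI samples (complete pairs) with its three-state classification. The
#' recorded `n` is the complete-pair count actually used; windows whose
#' index is incomputable (n < 3 or zero variance) come back with state
#' `"undefined"`.
#'
#' @param windows a `cordox_windows` table from [extract_dose_windows()].
#' @param threshold classification threshold (default 0.36).
#' @return data frame of class `cordox_indices`: key columns plus `n`,
#'   `rho`, `state`, `conformant`.
#' @export
compute_oximetry_indices <- function(windows, threshold = 0.36) {
  stopifnot(inherits(windows, "cordox_windows") ||
              all(c("map_values", "toi_values") %in% names(windows)))
  n_pairs <- integer(nrow(windows))
  rho <- numeric(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    m <- windows$map_values[[i]]; t_ <- windows$toi_values[[i]]
    n_pairs[i] <- sum(!is.na(m) & !is.na(t_))
    rho[i] <- spearman_rho(m, t_)
  }
  out <- data.frame(animal_id = windows$animal_id,
                    condition = windows$condition, drug = windows$drug,
                    dose_ug_kg_min = windows$dose_ug_kg_min,
                    site = windows$site, n = n_pairs, rho = rho,
                    state = classify_response(rho, threshold),
                    conformant = windows$conformant,
                    stringsAsFactors = FALSE)
  structure(out, class = c("cordox_indices", "data.frame"))
}

#' Compute the oximetry index of a single window
#'
#' @param window one-row `cordox_windows` table, or a list with elements
#'   `map_values` and `toi_values` (key fields optional).
#' @param threshold classification threshold.
#' @return one-row data frame with `n`, `rho` and `state`.
#' @export
compute_oximetry_index <- function(window, threshold = 0.36) {
  if (is.data.frame(window)) {
    stopifnot(nrow(window) == 1)
    return(compute_oximetry_indices(window, threshold))
  }
  rho <- spearman_rho(window$map_values, window$toi_values)
  data.frame(n = sum(!is.na(window$map_values) & !is.na(window$toi_values)),
             rho = rho, state = classify_response(rho, threshold),
             stringsAsFactors = FALSE)
}

group_key <- function(df, by) {
  interaction(df[by], drop = TRUE, lex.order = TRUE)
}

#' Response-pattern counts per group
#'
#' Counts windows in each of the three response states (plus undefined,
#' kept separate and never folded into the states) per grouping cell --
#' the "pressure-passive / intact / paradoxical" tabulation.
#'
#' @param indices a `cordox_indices` table.
#' @param by grouping columns.
#' @return data frame: grouping columns, one count column per state, and
#'   `n_windows` (their sum).
#' @export
count_response_patterns <- function(indices,
                                    by = c("site", "condition", "drug",
                                           "dose_ug_kg_min")) {
  stopifnot(all(by %in% names(indices)))
  if (nrow(indices) == 0) {
    out <- indices[by]
    for (s in RESPONSE_STATES) out[[s]] <- integer(0)
    out$n_windows <- integer(0)
    return(out)
  }
  key <- group_key(indices, by)
  parts <- lapply(split(seq_len(nrow(indices)), key), function(idx) {
    sub <- indices[idx, , drop = FALSE]
    row <- sub[1, by, drop = FALSE]
    for (s in RESPONSE_STATES) row[[s]] <- sum(sub$state == s)
    row$n_windows <- nrow(sub)
    row
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Median and range of oximetry indices per group
#'
#' Median (midpoint of the two central values for even n), minimum and
#' maximum of the computable (non-undefined) indices per grouping cell.
#' Cells with no computable index are flagged `empty`.
#'
#' @param indices a `cordox_indices` table.
#' @param by grouping columns.
#' @return data frame: grouping columns, `median_rho`, `min_rho`,
#'   `max_rho`, `n_animals`, `empty`.
#' @export
summarize_indices <- function(indices,
                              by = c("site", "condition", "drug",
                                     "dose_ug_kg_min")) {
  stopifnot(all(by %in% names(indices)))
  key <- group_key(indices, by)
  parts <- lapply(split(seq_len(nrow(indices)), key), function(idx) {
    sub <- indices[idx, , drop = FALSE]
    row <- sub[1, by, drop = FALSE]
    ok <- sub$state != "undefined"
    if (!any(ok)) {
      row$median_rho <- NA_real_; row$min_rho <- NA_real_
      row$max_rho <- NA_real_; row$n_animals <- 0L; row$empty <- TRUE
    } else {
      r <- sub$rho[ok]
      row$median_rho <- stats::median(r)
      row$min_rho <- min(r); row$max_rho <- max(r)
      row$n_animals <- length(unique(sub$animal_id[ok]))
      row$empty <- FALSE
    }
    row
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Paradoxical-response tallies over stepwise infusions and animals
#'
#' A "stepwise infusion" is one condition x drug arm of one animal (five
#' arms per animal under the default protocol); an infusion counts as
#' paradoxical when any of its dose windows is classified paradoxical.
#' Tallies are reported per site over all infusions ("x of N infusions")
#' and over animals (animals with at least one paradoxical window at that
#' site).
#'
#' @param indices a `cordox_indices` table.
#' @param site site to tally.
#' @return list with `infusions_paradoxical`, `infusions_total`,
#'   `animals_paradoxical`, `animals_total`.
#' @export
paradoxical_window_tally <- function(indices, site) {
  stopifnot(site %in% SITES)
  sub <- indices[indices$site == site, , drop = FALSE]
  if (nrow(sub) == 0)
    return(list(infusions_paradoxical = 0L, infusions_total = 0L,
                animals_paradoxical = 0L, animals_total = 0L))
  arm_key <- interaction(sub$animal_id, sub$condition, sub$drug, drop = TRUE)
  arm_hit <- vapply(split(sub$state, arm_key),
                    function(s) any(s == "paradoxical"), logical(1))
  animal_hit <- vapply(split(sub$state, sub$animal_id),
                       function(s) any(s == "paradoxical"), logical(1))
  list(infusions_paradoxical = sum(arm_hit),
       infusions_total = length(arm_hit),
       animals_paradoxical = sum(animal_hit),
       animals_total = length(animal_hit))
}
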