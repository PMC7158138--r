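#' Extract per-dose analysis windows
#'
#' Splits a recording into one analysis window per animal x condition x
#' drug x dose x present site, pairing MAP with that site's TOI sample by
#' sample. The window is the unit over which an oximetry index is computed;
#' under the default protocol a conformant window holds 60 paired samples
#' (10 min at 10-s sampling). Windows with any other sample count are
#' returned flagged (`conformant = FALSE`), never truncated or padded.
#'
#' @param ds a `cordox_recordings` table (see [read_recordings()]).
#' @param spec protocol; defaults to the table's `protocol` attribute.
#' @return data frame of class `cordox_windows` with one row per window:
#'   key columns `animal_id`, `condition`, `drug`, `dose_ug_kg_min`, `site`;
#'   `n` (paired-sample count), `conformant` (logical) and list columns
#'   `map_values`, `toi_values`.
#' @export
extract_dose_windows <- function(ds, spec = attr(ds, "protocol")) {
  stopifnot(inherits(spec, "protocol_spec"))
  n_expect <- samples_per_window(spec)
  empty <- data.frame(animal_id = character(), condition = character(),
                      drug = character(), dose_ug_kg_min = numeric(),
                      site = character(), n = integer(),
                      conformant = logical(), stringsAsFactors = FALSE)
  if (nrow(ds) == 0) {
    empty$map_values <- list(); empty$toi_values <- list()
    return(structure(empty, class = c("cordox_windows", "data.frame")))
  }
  present <- sites_present(ds)
  grp <- interaction(ds$animal_id, ds$condition, ds$drug, ds$dose_ug_kg_min,
                     drop = TRUE)
  rows <- list()
  for (g in split(seq_len(nrow(ds)), grp)) {
    sub <- ds[g, , drop = FALSE]
    sub <- sub[order(sub$t_s), , drop = FALSE]
    a <- as.character(sub$animal_id[1])
    for (site in present[[a]]) {
      toi <- sub[[toi_column(site)]]
      if (length(toi) != length(sub$map_mmHg))
        stop("integrity error: MAP and TOI lengths differ within a group")
      rows[[length(rows) + 1]] <- list(
        animal_id = a, condition = sub$condition[1], drug = sub$drug[1],
        dose_ug_kg_min = sub$dose_ug_kg_min[1], site = site,
        n = nrow(sub), conformant = nrow(sub) == n_expect,
        map_values = sub$map_mmHg, toi_values = toi)
    }
  }
  out <- data.frame(
    animal_id = vapply(rows, `[[`, "", "animal_id"),
    condition = vapply(rows, `[[`, "", "condition"),
    drug = vapply(rows, `[[`, "", "drug"),
    dose_ug_kg_min = vapply(rows, `[[`, 0, "dose_ug_kg_min"),
    site = vapply(rows, `[[`, "", "site"),
    n = vapply(rows, `[[`, 0L, "n"),
    conformant = vapply(rows, `[[`, TRUE, "conformant"),
    stringsAsFactors = FALSE)
  out$map_values <- lapply(rows, `[[`, "map_values")
  out$toi_values <- lapply(rows, `[[`, "toi_values")
  # deterministic ordering: protocol order of condition/drug, then dose, site
  out <- out[order(match(out$animal_id, unique(ds$animal_id)),
                   match(out$condition, spec$conditions),
                   out$drug, out$dose_ug_kg_min,
                   match(out$site, SITES)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, protocol = spec, class = c("cordox_windows", "data.frame"))
}
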