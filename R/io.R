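# Recording I/O and validation.
#
# A recording table is tidy long format with one row per timestamp: MAP is
# shared across sites, so the three TOI channels sit in columns of the same
# row rather than being melted into site rows. An empty TOI cell is a
# missing value; a site whose TOI column is empty for *every* row of an
# animal is treated as absent for that animal (e.g. a lost lumbar channel),
# whereas sporadic missing cells within a present site are validation
# findings.

SITES <- c("cerebral", "thoracic", "lumbar")

RECORDING_COLUMNS <- c("animal_id", "condition", "drug", "dose_ug_kg_min",
                       "t_s", "map_mmHg",
                       "toi_cerebral_pct", "toi_thoracic_pct", "toi_lumbar_pct")

toi_column <- function(site) paste0("toi_", site, "_pct")

#' Read a MAP/TOI recording CSV
#'
#' Reads a tidy recording table (columns `animal_id`, `condition`, `drug`,
#' `dose_ug_kg_min`, `t_s`, `map_mmHg`, `toi_cerebral_pct`,
#' `toi_thoracic_pct`, `toi_lumbar_pct`; empty cell = missing) and validates
#' it against a protocol: known condition/drug labels, doses drawn from the
#' protocol's dose levels, positive MAP, TOI inside (0, 100). Structural
#' problems that do not invalidate single cells (short windows, irregular
#' spacing, missing samples inside a present site) are reported by
#' [validate_recordings()] rather than raised here.
#'
#' @param path CSV file path.
#' @param spec a [protocol_spec()].
#' @return a `data.frame` of recording rows with a `protocol` attribute;
#'   class `cordox_recordings`.
#' @export
read_recordings <- function(path, spec = protocol_spec()) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(RECORDING_COLUMNS, names(raw))
  if (length(missing_cols) > 0)
    stop("malformed recording header; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[RECORDING_COLUMNS]
  num_cols <- c("dose_ug_kg_min", "t_s", "map_mmHg", vapply(SITES, toi_column, ""))
  for (col in num_cols) {
    v <- trimws(raw[[col]])
    v[v == ""] <- NA_character_
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad) > 0)
      stop("non-numeric value in column '", col, "' at data row ", bad[1],
           " ('", v[bad[1]], "')")
    raw[[col]] <- parsed
  }
  as_recordings(raw, spec)
}

#' Construct a validated recording table from a data frame
#'
#' @param df data frame with the recording columns (see [read_recordings()]).
#' @param spec a [protocol_spec()].
#' @return a `cordox_recordings` data frame.
#' @export
as_recordings <- function(df, spec = protocol_spec()) {
  stopifnot(inherits(spec, "protocol_spec"))
  missing_cols <- setdiff(RECORDING_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("missing recording column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[RECORDING_COLUMNS]
  bad_cond <- setdiff(unique(df$condition), spec$conditions)
  if (length(bad_cond) > 0)
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "))
  known_drugs <- unique(unlist(spec$drugs_per_condition))
  bad_drug <- setdiff(unique(df$drug), known_drugs)
  if (length(bad_drug) > 0)
    stop("unknown drug label(s): ", paste(bad_drug, collapse = ", "))
  if (!all(dose_match(df$dose_ug_kg_min, spec$dose_levels)))
    stop("dose outside protocol levels {",
         paste(spec$dose_levels, collapse = ", "), "}: ",
         paste(unique(df$dose_ug_kg_min[
           !dose_match(df$dose_ug_kg_min, spec$dose_levels)]), collapse = ", "))
  if (anyNA(df$map_mmHg))
    stop("map_mmHg must be present for every sample")
  if (any(df$t_s < 0)) stop("t_s must be >= 0 (window-relative seconds)")
  # range findings (non-positive MAP, TOI outside (0, 100)) are reported by
  # validate_recordings() rather than rejected at construction
  structure(df, protocol = spec,
            class = c("cordox_recordings", "data.frame"))
}

#' Write a recording table to CSV
#'
#' Numeric columns are written at full precision (17 significant digits) so
#' that a write/read round trip reproduces the values bit-exactly.
#'
#' @param ds a `cordox_recordings` table.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_recordings <- function(ds, path) {
  out <- as.data.frame(ds)[RECORDING_COLUMNS]
  num_cols <- c("dose_ug_kg_min", "t_s", "map_mmHg", vapply(SITES, toi_column, ""))
  for (col in num_cols) {
    v <- out[[col]]
    s <- vapply(v, function(x) if (is.na(x)) "" else format(x, digits = 17), "")
    out[[col]] <- s
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sites recorded for each animal
#'
#' A site is present for an animal when at least one of its TOI samples is
#' non-missing; the all-or-nothing convention models channel loss at the
#' animal level.
#'
#' @param ds a `cordox_recordings` table.
#' @return named list mapping animal id to its character vector of sites.
#' @export
sites_present <- function(ds) {
  animals <- unique(ds$animal_id)
  out <- lapply(animals, function(a) {
    sub <- ds[ds$animal_id == a, , drop = FALSE]
    SITES[vapply(SITES, function(s) any(!is.na(sub[[toi_column(s)]])), logical(1))]
  })
  names(out) <- animals
  out
}

#' Validate a recording table against its protocol
#'
#' Produces a findings report rather than raising errors: per-group sample
#' counts that differ from the protocol window length, irregular or
#' non-increasing time spacing, out-of-range values, and missing TOI samples
#' inside a present site. A conformant dataset yields a zero-row report.
#'
#' @param ds a `cordox_recordings` table.
#' @param spec protocol; defaults to the table's own `protocol` attribute.
#' @return data frame with columns `animal_id`, `condition`, `drug`,
#'   `dose_ug_kg_min`, `issue`, `detail`.
#' @export
validate_recordings <- function(ds, spec = attr(ds, "protocol")) {
  stopifnot(inherits(spec, "protocol_spec"))
  issues <- list()
  add <- function(a, cn, dr, ds_, issue, detail) {
    issues[[length(issues) + 1]] <<- data.frame(
      animal_id = a, condition = cn, drug = dr, dose_ug_kg_min = ds_,
      issue = issue, detail = detail, stringsAsFactors = FALSE)
  }
  n_expect <- samples_per_window(spec)
  present <- sites_present(ds)
  grp <- interaction(ds$animal_id, ds$condition, ds$drug, ds$dose_ug_kg_min,
                     drop = TRUE)
  for (g in split(seq_len(nrow(ds)), grp)) {
    sub <- ds[g, , drop = FALSE]
    a <- sub$animal_id[1]; cn <- sub$condition[1]
    dr <- sub$drug[1]; dose <- sub$dose_ug_kg_min[1]
    if (nrow(sub) != n_expect)
      add(a, cn, dr, dose, "short window",
          sprintf("%d samples, expected %d", nrow(sub), n_expect))
    dt <- diff(sub$t_s)
    if (any(dt <= 0))
      add(a, cn, dr, dose, "non-increasing time", "t_s not strictly increasing")
    else if (any(abs(dt - spec$sampling_interval) > 1e-6))
      add(a, cn, dr, dose, "irregular spacing",
          sprintf("spacing deviates from %g s", spec$sampling_interval))
    for (site in present[[as.character(a)]]) {
      v <- sub[[toi_column(site)]]
      if (anyNA(v))
        add(a, cn, dr, dose, "missing TOI sample",
            sprintf("%s: %d missing of %d", site, sum(is.na(v)), length(v)))
      out_rng <- !is.na(v) & (v <= 0 | v >= 100)
      if (any(out_rng))
        add(a, cn, dr, dose, "TOI out of range",
            sprintf("%s: %d value(s) outside (0, 100)", site, sum(out_rng)))
    }
    if (any(sub$map_mmHg <= 0))
      add(a, cn, dr, dose, "MAP out of range", "non-positive MAP")
  }
  if (length(issues) == 0)
    return(data.frame(animal_id = character(), condition = character(),
                      drug = character(), dose_ug_kg_min = numeric(),
                      issue = character(), detail = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}
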