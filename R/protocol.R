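#' Stepwise-infusion protocol specification
#'
#' Describes the experimental protocol that structures a recording: which
#' volume conditions are visited, which vasoactive drugs are infused under
#' each condition, the ordered dose steps of each infusion arm, and the
#' sampling scheme within a dose step. The default is the five-arm swine
#' protocol: phenylephrine and SNP arms at baseline and after fluid
#' resuscitation, phenylephrine only during hypovolemia (SNP under
#' hypovolemia causes lethal hypotension), doses 0, 0.5, 1, 2 and
#' 5 ug kg-1 min-1, 10-min steps sampled every 10 s so that each dose
#' window holds 60 paired MAP/TOI samples.
#'
#' @param conditions ordered character vector of volume conditions.
#' @param drugs_per_condition named list mapping each condition to the drugs
#'   infused under it.
#' @param dose_levels ordered numeric vector of infusion doses
#'   (ug kg-1 min-1); doses are protocol labels, not measurements.
#' @param step_duration duration of one dose step in seconds.
#' @param sampling_interval sampling interval in seconds.
#' @return an object of class `protocol_spec`.
#' @examples
#' spec <- protocol_spec()
#' samples_per_window(spec)  # 60
#' @export
protocol_spec <- function(conditions = c("baseline", "hypovolemia", "fluid_resuscitation"),
                          drugs_per_condition = list(
                            baseline = c("phenylephrine", "SNP"),
                            hypovolemia = "phenylephrine",
                            fluid_resuscitation = c("phenylephrine", "SNP")
                          ),
                          dose_levels = c(0, 0.5, 1, 2, 5),
                          step_duration = 600,
                          sampling_interval = 10) {
  stopifnot(length(conditions) >= 1, is.character(conditions))
  if (!setequal(names(drugs_per_condition), conditions))
    stop("drugs_per_condition must be named by exactly the protocol conditions")
  stopifnot(is.numeric(dose_levels), length(dose_levels) >= 1,
            !anyDuplicated(dose_levels),
            is.numeric(step_duration), step_duration > 0,
            is.numeric(sampling_interval), sampling_interval > 0)
  if (step_duration %% sampling_interval != 0)
    stop("step_duration must be a whole multiple of sampling_interval")
  structure(
    list(conditions = conditions,
         drugs_per_condition = drugs_per_condition[conditions],
         dose_levels = dose_levels,
         step_duration = step_duration,
         sampling_interval = sampling_interval),
    class = "protocol_spec")
}

#' Number of samples in a protocol-conformant dose window
#' @param spec a [protocol_spec()].
#' @return integer sample count per dose window.
#' @export
samples_per_window <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  as.integer(spec$step_duration / spec$sampling_interval)
}

#' Infusion arms of a protocol
#'
#' One arm is a condition x drug combination; under the default protocol
#' there are five (a "stepwise infusion" in tallies is one arm of one animal).
#'
#' @param spec a [protocol_spec()].
#' @return data frame with columns `condition` and `drug`, in protocol order.
#' @export
protocol_arms <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  arms <- do.call(rbind, lapply(spec$conditions, function(cn) {
    data.frame(condition = cn, drug = spec$drugs_per_condition[[cn]],
               stringsAsFactors = FALSE)
  }))
  rownames(arms) <- NULL
  arms
}

#' Read / write a protocol specification as YAML
#'
#' The on-disk form mirrors the fields of [protocol_spec()]. The packaged
#' file `extdata/protocol_default.yaml` encodes the default five-arm
#' protocol.
#'
#' @param path file path.
#' @return `read_protocol()` returns a `protocol_spec`;
#'   `write_protocol()` invisibly returns `path`.
#' @export
read_protocol <- function(path) {
  cfg <- yaml::read_yaml(path)
  protocol_spec(conditions = as.character(cfg$conditions),
                drugs_per_condition = lapply(cfg$drugs_per_condition, as.character),
                dose_levels = as.numeric(cfg$dose_levels),
                step_duration = as.numeric(cfg$step_duration),
                sampling_interval = as.numeric(cfg$sampling_interval))
}

#' @rdname read_protocol
#' @param spec a `protocol_spec` to serialize.
#' @export
write_protocol <- function(spec, path) {
  stopifnot(inherits(spec, "protocol_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @export
print.protocol_spec <- function(x, ...) {
  arms <- protocol_arms(x)
  cat("Stepwise-infusion protocol:", nrow(arms), "arms,",
      length(x$dose_levels), "dose steps of", x$step_duration, "s sampled every",
      x$sampling_interval, "s (", samples_per_window(x), "samples/window)\n")
  for (i in seq_len(nrow(arms)))
    cat("  -", arms$condition[i], "/", arms$drug[i], "\n")
  invisible(x)
}
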