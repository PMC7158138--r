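# Synthetic hemodynamic experiment generator.
#
# Emulates a stepwise vasoactive-infusion protocol: each animal's MAP walks
# through per-dose targets (defaults taken from the reference dose-response
# envelope) with an animal-level offset, a short ramp after each infusion-
# rate change and AR(1) within-window fluctuation; each site's TOI follows a
# static piecewise-linear (Lassen-type) autoregulation curve plus a
# per-window response regime that couples TOI fluctuations to MAP
# fluctuations with a known slope. Every generated window carries a ground-
# truth regime label, which is what makes the classification pipeline
# testable end to end.

#' Response-regime specification
#'
#' A regime fixes how a window's TOI fluctuations couple to its MAP
#' fluctuations: `intact` autoregulation has (near-)zero slope,
#' `pressure_passive` a positive slope, `paradoxical` a negative slope
#' (oxygenation moving against pressure). `noise_sd` is the stationary SD
#' of the AR(1) TOI observation noise.
#'
#' @param regime one of `"intact"`, `"pressure_passive"`, `"paradoxical"`.
#' @param slope TOI percent per mmHg; sign must match the regime
#'   (`intact` tolerates `|slope| <= intact_epsilon`).
#' @param noise_sd TOI noise SD (percentage points), >= 0.
#' @param ar_coefficient lag-1 autocorrelation of the noise, in [0, 1).
#' @param intact_epsilon slope magnitude still considered intact.
#' @return object of class `regime_spec`.
#' @export
regime_spec <- function(regime, slope, noise_sd = 1, ar_coefficient = 0.5,
                        intact_epsilon = 0.02) {
  regime <- match.arg(regime, c("intact", "pressure_passive", "paradoxical"))
  stopifnot(noise_sd >= 0, ar_coefficient >= 0, ar_coefficient < 1)
  ok <- switch(regime,
               intact = abs(slope) <= intact_epsilon,
               pressure_passive = slope > 0,
               paradoxical = slope < 0)
  if (!ok) stop("slope ", slope, " inconsistent with regime '", regime, "'")
  structure(list(regime = regime, slope = slope, noise_sd = noise_sd,
                 ar_coefficient = ar_coefficient), class = "regime_spec")
}

#' Default regime set
#'
#' Reference coupling strengths: pressure-passive +0.2 and paradoxical
#' -0.2 TOI percent per mmHg with 1 percentage-point AR(1) noise
#' (coefficient 0.5); intact has zero slope.
#'
#' @param slope_magnitude absolute coupling slope of the non-intact regimes.
#' @param noise_sd,ar_coefficient shared noise parameters.
#' @return named list of three [regime_spec()] objects.
#' @export
default_regimes <- function(slope_magnitude = 0.2, noise_sd = 1,
                            ar_coefficient = 0.5) {
  list(
    intact = regime_spec("intact", 0, noise_sd, ar_coefficient),
    pressure_passive = regime_spec("pressure_passive", slope_magnitude,
                                   noise_sd, ar_coefficient),
    paradoxical = regime_spec("paradoxical", -slope_magnitude,
                              noise_sd, ar_coefficient))
}

#' Static autoregulation profile of one measurement site
#'
#' A Lassen-type piecewise-linear curve: TOI sits on a plateau between the
#' lower and upper autoregulatory MAP limits and becomes pressure-dependent
#' outside them. Condition offsets shift the whole curve additively
#' (hypovolemia shifts it down by less than 5% of the plateau).
#'
#' @param site `"cerebral"`, `"thoracic"` or `"lumbar"`.
#' @param plateau_toi plateau TOI (%), in (0, 100).
#' @param lower_limit_map,upper_limit_map autoregulatory MAP limits (mmHg).
#' @param below_limit_slope,above_limit_slope TOI percent per mmHg outside
#'   the plateau (both >= 0).
#' @param condition_offsets named numeric vector of additive TOI shifts
#'   (percentage points) per condition.
#' @return object of class `site_profile`.
#' @export
site_profile <- function(site, plateau_toi,
                         lower_limit_map = 50, upper_limit_map = 110,
                         below_limit_slope = 0.25, above_limit_slope = 0.05,
                         condition_offsets = c(baseline = 0,
                                               hypovolemia = -3,
                                               fluid_resuscitation = -3)) {
  site <- match.arg(site, SITES)
  stopifnot(plateau_toi > 0, plateau_toi < 100,
            lower_limit_map < upper_limit_map,
            below_limit_slope >= 0, above_limit_slope >= 0)
  if (any(abs(condition_offsets) >= 0.05 * plateau_toi))
    stop("condition offsets must stay below 5% of the plateau TOI")
  structure(list(site = site, plateau_toi = plateau_toi,
                 lower_limit_map = lower_limit_map,
                 upper_limit_map = upper_limit_map,
                 below_limit_slope = below_limit_slope,
                 above_limit_slope = above_limit_slope,
                 condition_offsets = condition_offsets),
            class = "site_profile")
}

#' Default site profiles
#'
#' Plateaus of 65% (cerebral), 48% (thoracic) and 53% (lumbar): spinal cord
#' TOI runs roughly 15% (thoracic) and 10% (lumbar) below cerebral TOI at
#' matched MAP, and cerebral > lumbar > thoracic holds at every dose.
#' Hypovolemia (and the post-resuscitation state, which restores volume but
#' not the relationship) shift each curve down by about 3 percentage
#' points, under the 5%-of-plateau cap.
#'
#' @return named list of [site_profile()] objects.
#' @export
default_site_profiles <- function() {
  list(
    cerebral = site_profile("cerebral", plateau_toi = 65,
                            condition_offsets = c(baseline = 0,
                                                  hypovolemia = -3,
                                                  fluid_resuscitation = -3)),
    thoracic = site_profile("thoracic", plateau_toi = 48,
                            condition_offsets = c(baseline = 0,
                                                  hypovolemia = -2,
                                                  fluid_resuscitation = -2)),
    lumbar = site_profile("lumbar", plateau_toi = 53,
                          condition_offsets = c(baseline = 0,
                                                hypovolemia = -2.5,
                                                fluid_resuscitation = -2.5)))
}

#' Evaluate a static autoregulation curve
#'
#' @param map MAP values (mmHg).
#' @param profile a [site_profile()].
#' @return baseline-condition TOI (%) of the curve at `map`.
#' @export
lassen_curve <- function(map, profile) {
  stopifnot(inherits(profile, "site_profile"))
  ifelse(map < profile$lower_limit_map,
         profile$plateau_toi - profile$below_limit_slope *
           (profile$lower_limit_map - map),
         ifelse(map > profile$upper_limit_map,
                profile$plateau_toi + profile$above_limit_slope *
                  (map - profile$upper_limit_map),
                profile$plateau_toi))
}

#' Default per-arm MAP targets
#'
#' The mean MAP of each condition x drug x dose cell of the reference
#' dose-response envelope, so that default simulations land inside the
#' published hemodynamic range.
#'
#' @return data frame with columns `condition`, `drug`, `dose_ug_kg_min`,
#'   `map_mmHg`.
#' @export
default_map_targets <- function() {
  wide <- reference_dose_response()
  data.frame(condition = wide$condition, drug = wide$drug,
             dose_ug_kg_min = wide$dose_ug_kg_min, map_mmHg = wide$map_mean,
             stringsAsFactors = FALSE)
}

#' Default regime mixture per site and drug
#'
#' Loosely mirrors the response-pattern frequencies reported for this kind
#' of experiment: paradoxical responses concentrate in the cerebrum during
#' vasoconstrictor (phenylephrine) infusion and are rare in the spinal
#' cord; vasodilator (SNP) windows are predominantly pressure-passive at
#' all sites.
#'
#' @return data frame with columns `site`, `drug`, `pressure_passive`,
#'   `intact`, `paradoxical` (rows sum to 1).
#' @export
default_regime_probabilities <- function() {
  out <- rbind(
    data.frame(site = "cerebral", drug = "phenylephrine",
               pressure_passive = 0.25, intact = 0.45, paradoxical = 0.30),
    data.frame(site = "cerebral", drug = "SNP",
               pressure_passive = 0.75, intact = 0.25, paradoxical = 0.00),
    data.frame(site = "thoracic", drug = "phenylephrine",
               pressure_passive = 0.50, intact = 0.40, paradoxical = 0.10),
    data.frame(site = "thoracic", drug = "SNP",
               pressure_passive = 0.85, intact = 0.13, paradoxical = 0.02),
    data.frame(site = "lumbar", drug = "phenylephrine",
               pressure_passive = 0.50, intact = 0.40, paradoxical = 0.10),
    data.frame(site = "lumbar", drug = "SNP",
               pressure_passive = 0.85, intact = 0.13, paradoxical = 0.02))
  rownames(out) <- NULL
  out
}

#' Simulation configuration
#'
#' Bundles the protocol, cohort size, MAP trajectory parameters, site
#' profiles, regime mixture and seed of one synthetic experiment. Defaults
#' reproduce the reference study conditions: 10 animals, MAP targets from
#' the reference envelope, 3 mmHg between-animal and 3 mmHg within-window
#' MAP SD, a 2.5-min stabilization ramp after each infusion-rate change
#' (transition fraction 0.25 of the 10-min step), AR(1) coefficient 0.5 for
#' both MAP and TOI fluctuations, regime slopes of magnitude 0.2 percent
#' per mmHg with 1 percentage-point TOI noise, and one animal with a lost
#' lumbar channel.
#'
#' @param n_animals number of animals (>= 1).
#' @param protocol a [protocol_spec()].
#' @param map_targets data frame of per-arm, per-dose mean MAP
#'   (see [default_map_targets()]).
#' @param map_between_animal_sd SD of the animal-level MAP offset (mmHg).
#' @param map_within_window_sd stationary SD of within-window MAP
#'   fluctuation (mmHg).
#' @param map_ar_coefficient lag-1 autocorrelation of MAP fluctuation.
#' @param transition_fraction fraction of each dose step spent ramping from
#'   the previous step's MAP level, in [0, 1).
#' @param site_profiles named list of [site_profile()] objects.
#' @param regimes named list of [regime_spec()] objects
#'   (see [default_regimes()]).
#' @param regime_probabilities data frame as in
#'   [default_regime_probabilities()].
#' @param lumbar_dropout_animal index of the animal whose lumbar channel is
#'   absent (models channel loss), or `NA` for none.
#' @param seed integer RNG seed; identical configurations generate
#'   bit-identical experiments.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_animals = 10,
                       protocol = protocol_spec(),
                       map_targets = default_map_targets(),
                       map_between_animal_sd = 3,
                       map_within_window_sd = 3,
                       map_ar_coefficient = 0.5,
                       transition_fraction = 0.25,
                       site_profiles = default_site_profiles(),
                       regimes = default_regimes(),
                       regime_probabilities = default_regime_probabilities(),
                       lumbar_dropout_animal = 1,
                       seed = 1L) {
  stopifnot(inherits(protocol, "protocol_spec"),
            n_animals >= 1,
            map_between_animal_sd >= 0, map_within_window_sd >= 0,
            map_ar_coefficient >= 0, map_ar_coefficient < 1,
            transition_fraction >= 0, transition_fraction < 1)
  arms <- protocol_arms(protocol)
  for (i in seq_len(nrow(arms))) for (d in protocol$dose_levels) {
    hit <- map_targets$condition == arms$condition[i] &
      map_targets$drug == arms$drug[i] &
      dose_match(map_targets$dose_ug_kg_min, d)
    if (sum(hit) != 1)
      stop("map_targets must have exactly one row for ",
           arms$condition[i], "/", arms$drug[i], " dose ", d)
  }
  psum <- rowSums(regime_probabilities[c("pressure_passive", "intact",
                                         "paradoxical")])
  if (any(abs(psum - 1) > 1e-8))
    stop("regime probabilities must sum to 1 within each (site, drug) row")
  if (any(regime_probabilities[c("pressure_passive", "intact",
                                 "paradoxical")] < 0))
    stop("regime probabilities must be non-negative")
  stopifnot(all(SITES %in% names(site_profiles)),
            all(c("intact", "pressure_passive", "paradoxical") %in%
                  names(regimes)))
  if (!is.na(lumbar_dropout_animal))
    stopifnot(lumbar_dropout_animal >= 1, lumbar_dropout_animal <= n_animals)
  structure(list(n_animals = as.integer(n_animals), protocol = protocol,
                 map_targets = map_targets,
                 map_between_animal_sd = map_between_animal_sd,
                 map_within_window_sd = map_within_window_sd,
                 map_ar_coefficient = map_ar_coefficient,
                 transition_fraction = transition_fraction,
                 site_profiles = site_profiles, regimes = regimes,
                 regime_probabilities = regime_probabilities,
                 lumbar_dropout_animal = lumbar_dropout_animal,
                 seed = as.integer(seed)),
            class = "sim_config")
}

map_target_for <- function(cfg, condition, drug, dose) {
  mt <- cfg$map_targets
  hit <- mt$condition == condition & mt$drug == drug &
    dose_match(mt$dose_ug_kg_min, dose)
  mt$map_mmHg[hit][1]
}

#' Simulate one arm's MAP trajectory
#'
#' For each dose step: 60 (or `step_duration/sampling_interval`) samples at
#' the animal-level target (arm/dose target plus the animal's offset), with
#' the first `transition_fraction` of the step ramping linearly from the
#' previous step's level, plus stationary AR(1) fluctuation. Samples are
#' floored at 20 mmHg (a degenerate-configuration guard; flooring is
#' counted in the `n_floored` attribute).
#'
#' Draws from the current RNG state; seed management belongs to the caller
#' (see [simulate_experiment()]).
#'
#' @param cfg a [sim_config()].
#' @param condition,drug the infusion arm.
#' @param animal_offset this animal's MAP offset (mmHg).
#' @return data frame with columns `dose_ug_kg_min`, `t_s`, `map_mmHg`;
#'   attribute `n_floored`.
#' @export
simulate_map_trajectory <- function(cfg, condition, drug, animal_offset = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  spec <- cfg$protocol
  n <- samples_per_window(spec)
  t_rel <- seq(0, by = spec$sampling_interval, length.out = n)
  n_ramp <- round(cfg$transition_fraction * n)
  prev_level <- NA_real_
  out <- vector("list", length(spec$dose_levels))
  n_floored <- 0L
  for (i in seq_along(spec$dose_levels)) {
    dose <- spec$dose_levels[i]
    target <- map_target_for(cfg, condition, drug, dose) + animal_offset
    if (is.na(prev_level) || n_ramp == 0) {
      level <- target
    } else {
      # targets parameterize the per-dose window mean (the scale on which
      # dose-response tables report MAP); solve the stationary level so the
      # window mean equals the target despite the transition ramp
      a <- n - n_ramp + (n_ramp + 1) / 2
      b <- (n_ramp - 1) / 2
      level <- (n * target - b * prev_level) / a
    }
    base <- rep(level, n)
    if (!is.na(prev_level) && n_ramp > 0)
      base[seq_len(n_ramp)] <-
        seq(prev_level, level, length.out = n_ramp + 1)[-1]
    map <- base + ar1_noise(n, cfg$map_within_window_sd, cfg$map_ar_coefficient)
    low <- map < 20
    if (any(low)) {
      n_floored <- n_floored + sum(low)
      map[low] <- 20
    }
    out[[i]] <- data.frame(dose_ug_kg_min = dose, t_s = t_rel, map_mmHg = map)
    prev_level <- level
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_floored") <- n_floored
  res
}

#' Simulate a TOI series from a MAP series
#'
#' TOI_t = curve(mean MAP) + condition offset
#'         + slope x (MAP_t - mean MAP) + AR(1) noise,
#' where the static curve is the site's [lassen_curve()] evaluated at the
#' window-mean MAP. Values are clipped into (0, 100); clipping is counted
#' in the `n_clipped` attribute. Draws from the current RNG state.
#'
#' @param map_series MAP samples of one window (mmHg).
#' @param profile a [site_profile()].
#' @param regime a [regime_spec()].
#' @param condition condition label (selects the curve offset).
#' @return numeric TOI series with attribute `n_clipped`.
#' @export
simulate_toi_from_map <- function(map_series, profile, regime, condition) {
  stopifnot(inherits(profile, "site_profile"), inherits(regime, "regime_spec"),
            length(map_series) >= 1)
  offset <- profile$condition_offsets[[condition]]
  if (is.null(offset)) stop("profile has no offset for condition ", condition)
  m <- mean(map_series)
  base <- lassen_curve(m, profile) + offset
  toi <- base + regime$slope * (map_series - m) +
    ar1_noise(length(map_series), regime$noise_sd, regime$ar_coefficient)
  clip <- toi <= 0 | toi >= 100
  toi[toi <= 0] <- 0.1
  toi[toi >= 100] <- 99.9
  attr(toi, "n_clipped") <- sum(clip)
  toi
}

#' Simulate a full stepwise-infusion experiment
#'
#' Generates the complete protocol for `cfg$n_animals` animals -- every
#' infusion arm, every dose step, every recorded site -- with one
#' per-window response regime drawn from the configured mixture, and
#' returns both the recording table and the ground-truth regime labels.
#' Output is bit-identical for identical configurations (including seed).
#'
#' @param cfg a [sim_config()].
#' @return list with elements `recordings` (a `cordox_recordings` table),
#'   `truth` (data frame: `animal_id`, `condition`, `drug`,
#'   `dose_ug_kg_min`, `site`, `regime`, `slope`) and `config`.
#' @examples
#' sim <- simulate_experiment(sim_config(n_animals = 2, seed = 7))
#' nrow(sim$truth)
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  spec <- cfg$protocol
  arms <- protocol_arms(spec)
  n_win <- samples_per_window(spec)
  animal_ids <- sprintf("A%02d", seq_len(cfg$n_animals))
  rec_parts <- list()
  truth_parts <- list()
  rp <- cfg$regime_probabilities
  for (ai in seq_len(cfg$n_animals)) {
    aid <- animal_ids[ai]
    a_sites <- SITES
    if (!is.na(cfg$lumbar_dropout_animal) && ai == cfg$lumbar_dropout_animal)
      a_sites <- setdiff(a_sites, "lumbar")
    a_offset <- stats::rnorm(1, 0, cfg$map_between_animal_sd)
    for (j in seq_len(nrow(arms))) {
      cn <- arms$condition[j]; dr <- arms$drug[j]
      traj <- simulate_map_trajectory(cfg, cn, dr, a_offset)
      toi_cols <- list(cerebral = rep(NA_real_, nrow(traj)),
                       thoracic = rep(NA_real_, nrow(traj)),
                       lumbar = rep(NA_real_, nrow(traj)))
      for (site in intersect(SITES, a_sites)) {
        prow <- rp[rp$site == site & rp$drug == dr, , drop = FALSE]
        if (nrow(prow) != 1)
          stop("regime_probabilities needs one row for ", site, "/", dr)
        probs <- as.numeric(prow[c("pressure_passive", "intact",
                                   "paradoxical")])
        for (dose in spec$dose_levels) {
          lab <- sample(c("pressure_passive", "intact", "paradoxical"),
                        1, prob = probs)
          regime <- cfg$regimes[[lab]]
          idx <- which(dose_match(traj$dose_ug_kg_min, dose))
          toi_cols[[site]][idx] <-
            as.numeric(simulate_toi_from_map(traj$map_mmHg[idx],
                                             cfg$site_profiles[[site]],
                                             regime, cn))
          truth_parts[[length(truth_parts) + 1]] <- data.frame(
            animal_id = aid, condition = cn, drug = dr,
            dose_ug_kg_min = dose, site = site, regime = lab,
            slope = regime$slope, stringsAsFactors = FALSE)
        }
      }
      rec_parts[[length(rec_parts) + 1]] <- data.frame(
        animal_id = aid, condition = cn, drug = dr,
        dose_ug_kg_min = traj$dose_ug_kg_min, t_s = traj$t_s,
        map_mmHg = traj$map_mmHg,
        toi_cerebral_pct = toi_cols$cerebral,
        toi_thoracic_pct = toi_cols$thoracic,
        toi_lumbar_pct = toi_cols$lumbar, stringsAsFactors = FALSE)
    }
  }
  recordings <- as_recordings(do.call(rbind, rec_parts), spec)
  truth <- do.call(rbind, truth_parts)
  rownames(truth) <- NULL
  list(recordings = recordings, truth = truth, config = cfg)
}
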