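# Programmatic fixtures shared across test files.

# A minimal conformant recording: one animal, one arm, chosen doses,
# cerebral (and optionally thoracic/lumbar) TOI.
make_recording <- function(doses = 0, n = 60, map_fun = NULL,
                           toi_fun = NULL, sites = "cerebral",
                           animal = "A01", condition = "baseline",
                           drug = "phenylephrine") {
  if (is.null(map_fun)) map_fun <- function(dose, t) 60 + 0 * t
  if (is.null(toi_fun)) toi_fun <- function(dose, t, site) 64 + 0 * t
  empty <- data.frame(animal_id = character(), condition = character(),
                      drug = character(), dose_ug_kg_min = numeric(),
                      t_s = numeric(), map_mmHg = numeric(),
                      toi_cerebral_pct = numeric(), toi_thoracic_pct = numeric(),
                      toi_lumbar_pct = numeric(), stringsAsFactors = FALSE)
  if (length(doses) == 0) return(as_recordings(empty))
  rows <- do.call(rbind, lapply(doses, function(d) {
    t_s <- seq(0, by = 10, length.out = n)
    df <- data.frame(animal_id = animal, condition = condition, drug = drug,
                     dose_ug_kg_min = d, t_s = t_s,
                     map_mmHg = map_fun(d, t_s),
                     toi_cerebral_pct = NA_real_,
                     toi_thoracic_pct = NA_real_,
                     toi_lumbar_pct = NA_real_,
                     stringsAsFactors = FALSE)
    for (s in sites) df[[paste0("toi_", s, "_pct")]] <- toi_fun(d, t_s, s)
    df
  }))
  as_recordings(rows)
}

# Independent Spearman oracle: Pearson correlation of mid-ranks via cor().
spearman_oracle <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# Textbook no-ties Spearman: 1 - 6 sum(d^2) / (n (n^2 - 1)).
spearman_d2_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# A small noise-free simulation config used in several pipeline tests.
noise_free_config <- function(slope = 0.2, n_animals = 1, seed = 1) {
  regimes <- list(
    intact = regime_spec("intact", 0, noise_sd = 0, ar_coefficient = 0),
    pressure_passive = regime_spec("pressure_passive", slope, noise_sd = 0,
                                   ar_coefficient = 0),
    paradoxical = regime_spec("paradoxical", -slope, noise_sd = 0,
                              ar_coefficient = 0))
  sim_config(n_animals = n_animals, map_between_animal_sd = 0,
             map_within_window_sd = 0, transition_fraction = 0,
             regimes = regimes, lumbar_dropout_animal = NA, seed = seed)
}

# Force a single regime for every (site, drug).
single_regime_probs <- function(regime) {
  rp <- default_regime_probabilities()
  rp$pressure_passive <- as.numeric(regime == "pressure_passive")
  rp$intact <- as.numeric(regime == "intact")
  rp$paradoxical <- as.numeric(regime == "paradoxical")
  rp
}
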